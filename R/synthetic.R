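# seeded synthetic-data generators
#
# These stand in for restricted-access patient data and define the study
# conditions under which the pipeline is exercised: heavy-tailed clone sizes
# with rare dominant clones, epitope-specific CDR3 sets sharing planted
# motifs across subjects, cohorts differing in aggregate motif-bearing clone
# frequency, longitudinal pairs with planted expansions and novel clones,
# and clustered single-cell expression with specificity-linked enrichment.
# Every generator is a pure function of its config, including the seed.

#' Synthetic-repertoire generator configuration
#'
#' @param seed integer master seed.
#' @param n_clones clones per repertoire (default 500).
#' @param depth total reads per repertoire (default 1e4).
#' @param clone_size_model `list(type = "lognormal", mu, sigma)` (default
#'   mu 0, sigma 2: rare dominant clones) or `list(type = "power_law",
#'   alpha)`.
#' @param cdr3_length_range full CDR3 length range, inclusive (default 8-20;
#'   generated CDR3s are `C` + interior + `F`).
#' @param aa_composition 20 probabilities over the standard residues for the
#'   interior (default uniform; must sum to 1).
#' @param motif `list(kmer, prob, position)`: k-mer to plant, planting
#'   probability in `[0, 1]`, and position policy `"center"` or
#'   `"uniform_interior"`.
#' @param v_genes,j_genes gene-label pools.
#' @return a validated config list.
#' @export
syntheticConfig <- function(seed = 1L, n_clones = 500L, depth = 10000L,
                            clone_size_model = list(type = "lognormal", mu = 0, sigma = 2),
                            cdr3_length_range = c(8L, 20L),
                            aa_composition = rep(1 / 20, 20),
                            motif = list(kmer = NULL, prob = 0, position = "center"),
                            v_genes = paste0("TRBV", 1:20),
                            j_genes = paste0("TRBJ", rep(1:2, c(6, 7)), "-",
                                             c(1:6, 1:7))) {
  if (abs(sum(aa_composition) - 1) > 1e-8 || any(aa_composition < 0)) {
    stop("aa_composition must be non-negative and sum to 1")
  }
  if (!is.null(motif$kmer)) {
    if (!grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", motif$kmer)) {
      stop("motif contains non-standard residues")
    }
    if (nchar(motif$kmer) >= cdr3_length_range[1] - 2L) {
      stop("motif length must be below the minimum CDR3 interior length")
    }
  }
  if (is.null(motif$prob)) motif$prob <- 0
  if (motif$prob < 0 || motif$prob > 1) stop("planting probability must be in [0, 1]")
  if (is.null(motif$position)) motif$position <- "center"
  list(seed = as.integer(seed), n_clones = as.integer(n_clones),
       depth = as.integer(depth), clone_size_model = clone_size_model,
       cdr3_length_range = as.integer(cdr3_length_range),
       aa_composition = aa_composition, motif = motif,
       v_genes = v_genes, j_genes = j_genes)
}

# raw clone-size weights under the configured model
.cloneWeights <- function(model, n) {
  if (model$type == "lognormal") {
    stats::rlnorm(n, meanlog = model$mu, sdlog = model$sigma)
  } else if (model$type == "power_law") {
    stats::runif(n)^(-1 / (model$alpha - 1))
  } else stop(sprintf("unknown clone_size_model type '%s'", model$type))
}

# one CDR3 with an optionally planted motif (RNG comes from the caller)
.oneCdr3 <- function(cfg) {
  lens <- seq(cfg$cdr3_length_range[1], cfg$cdr3_length_range[2])
  len <- lens[sample.int(length(lens), 1L)]
  ilen <- len - 2L
  inner <- sample(AA_STANDARD, ilen, replace = TRUE, prob = cfg$aa_composition)
  m <- cfg$motif
  if (!is.null(m$kmer) && m$prob > 0 && stats::runif(1) < m$prob) {
    k <- nchar(m$kmer)
    start <- if (identical(m$position, "center")) {
      floor((ilen - k) / 2) + 1L
    } else {
      sample(seq_len(ilen - k + 1L), 1L)
    }
    inner[start + seq_len(k) - 1L] <- strsplit(m$kmer, "")[[1]]
  }
  paste0("C", paste(inner, collapse = ""), "F")
}

#' Generate synthetic CDR3 sequences
#'
#' The core sequence primitive used by all repertoire generators: CDR3s of
#' the form `C` + random interior + `F`, lengths uniform over the configured
#' range, residues from the configured composition, with the configured
#' motif planted at its probability and position policy. Deterministic per
#' seed (taken from `cfg$seed` unless overridden).
#'
#' @param cfg a [syntheticConfig()].
#' @param n number of sequences.
#' @param seed optional seed override.
#' @return character vector of length `n`.
#' @export
generateCdr3s <- function(cfg, n, seed = cfg$seed) {
  withSeed(seed, vapply(seq_len(n), function(i) .oneCdr3(cfg), ""))
}

#' Generate a background repertoire
#'
#' `cfg$n_clones` random CDR3s with clone counts drawn from the configured
#' clone-size model and multinomially sampled to `cfg$depth` reads; clones
#' drawn zero times are dropped, so richness is at most `n_clones`.
#'
#' @param cfg a [syntheticConfig()].
#' @param sampleId sample identifier.
#' @param metadata sample metadata list.
#' @return a [Repertoire-class].
#' @export
generateBackgroundRepertoire <- function(cfg, sampleId = "synthetic",
                                         metadata = list()) {
  df <- withSeed(cfg$seed, {
    seqs <- vapply(seq_len(cfg$n_clones), function(i) .oneCdr3(cfg), "")
    w <- .cloneWeights(cfg$clone_size_model, cfg$n_clones)
    counts <- drop(stats::rmultinom(1L, cfg$depth, w))
    data.frame(cdr3aa = seqs,
               v_gene = sample(cfg$v_genes, cfg$n_clones, replace = TRUE),
               j_gene = sample(cfg$j_genes, cfg$n_clones, replace = TRUE),
               count = counts, stringsAsFactors = FALSE)
  })
  df <- df[df$count > 0L, , drop = FALSE]
  aggregateDuplicates(Repertoire(df, sampleId = sampleId, metadata = metadata))
}

#' Generate an epitope-specific training set
#'
#' Positives carry the motif with the given planting probability at the
#' configured position policy; subject IDs are assigned round-robin so the
#' leave-one-subject-out scheme is exercisable (subject sizes differ by at
#' most one).
#'
#' @param cfg a [syntheticConfig()].
#' @param motif `list(kmer, prob, position)`; overrides `cfg$motif`.
#' @param nPositives number of positive CDR3s.
#' @param subjects number of synthetic subjects.
#' @param epitope epitope name for the returned [TrainingSet-class].
#' @return a `TrainingSet` (background left empty; draw one from a pool at
#'   training time).
#' @export
generateEpitopeRepertoire <- function(cfg, motif, nPositives, subjects = 1L,
                                      epitope = "SYNTHETIC_EPITOPE") {
  cfg$motif <- motif
  cfg <- syntheticConfig(seed = cfg$seed, n_clones = cfg$n_clones,
                         depth = cfg$depth, clone_size_model = cfg$clone_size_model,
                         cdr3_length_range = cfg$cdr3_length_range,
                         aa_composition = cfg$aa_composition, motif = motif,
                         v_genes = cfg$v_genes, j_genes = cfg$j_genes)
  seqs <- generateCdr3s(cfg, nPositives)
  TrainingSet(epitope = epitope, positives = seqs,
              subjects = paste0("S", rep_len(seq_len(subjects), nPositives)))
}

#' Generate a case/control cohort with planted biomarker frequencies
#'
#' Each sample is a background repertoire into which motif-bearing clones
#' are injected so that their aggregate read frequency matches the group's
#' target (within a 10% relative tolerance by construction); controls with
#' target 0 receive no motif-bearing clones. Ages are drawn uniformly over
#' 30-80 years so age-matching is exercisable.
#'
#' @param cfg a [syntheticConfig()] whose `motif$kmer` defines the planted
#'   motif (planting probability 1 is used for injected clones).
#' @param nCases,nControls cohort sizes.
#' @param caseTargetFreq,controlTargetFreq aggregate motif-clone frequency
#'   targets in `[0, 1)`.
#' @param nInject motif-bearing clones injected per positive sample
#'   (default 10).
#' @return list with `repertoires` (list of [Repertoire-class]) and `truth`
#'   (data.frame: `sample_id`, `group`, `target_frequency`,
#'   `realized_frequency`, `n_target_clones`, `age`).
#' @export
generateCohort <- function(cfg, nCases, nControls, caseTargetFreq,
                           controlTargetFreq, nInject = 10L) {
  if (caseTargetFreq >= 1 || controlTargetFreq >= 1 ||
      caseTargetFreq < 0 || controlTargetFreq < 0) {
    stop("target frequencies must lie in [0, 1)")
  }
  if (is.null(cfg$motif$kmer)) stop("cfg$motif$kmer must be set for a cohort")
  n <- nCases + nControls
  seeds <- deriveSeeds(cfg$seed, 2L * n + 1L)
  ages <- withSeed(seeds[2L * n + 1L], stats::runif(n, 30, 80))
  groups <- rep(c("case", "control"), c(nCases, nControls))
  targets <- ifelse(groups == "case", caseTargetFreq, controlTargetFreq)
  motifCfg <- cfg; motifCfg$motif$prob <- 1
  bgCfg <- cfg; bgCfg$motif$prob <- 0
  reps <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    sid <- sprintf("%s%02d", ifelse(groups[i] == "case", "CASE", "CTRL"),
                   i - ifelse(groups[i] == "case", 0L, nCases))
    bgCfg$seed <- seeds[2L * i - 1L]
    r <- generateBackgroundRepertoire(bgCfg, sampleId = sid,
                                      metadata = list(group = groups[i],
                                                      age = ages[i]))
    f <- targets[i]
    if (f > 0) {
      injectReads <- round(f * cfg$depth / (1 - f))
      motifCfg$seed <- seeds[2L * i]
      mseqs <- generateCdr3s(motifCfg, nInject)
      counts <- withSeed(seeds[2L * i],
        drop(stats::rmultinom(1L, injectReads,
                              .cloneWeights(cfg$clone_size_model, nInject))))
      add <- data.frame(cdr3aa = mseqs,
                        v_gene = rep_len(cfg$v_genes, nInject),
                        j_gene = rep_len(cfg$j_genes, nInject),
                        count = counts, stringsAsFactors = FALSE)
      add <- add[add$count > 0L, , drop = FALSE]
      r <- Repertoire(rbind(r@clonotypes[, c("cdr3aa", "v_gene", "j_gene", "count")], add),
                      sampleId = sid, metadata = r@metadata)
    }
    hit <- grepl(cfg$motif$kmer, r@clonotypes$cdr3aa, fixed = TRUE)
    reps[[i]] <- r
    truth[[i]] <- data.frame(sample_id = sid, group = groups[i],
                             target_frequency = f,
                             realized_frequency = sum(r@clonotypes$frequency[hit]),
                             n_target_clones = sum(hit), age = ages[i],
                             stringsAsFactors = FALSE)
  }
  list(repertoires = reps, truth = do.call(rbind, truth))
}

#' Generate a longitudinal pre/post pair with planted dynamics
#'
#' Post-therapy frequencies equal the pre-therapy frequencies with
#' `nExpanded` planted clones multiplied by `fold` (then renormalised), and
#' novel clones injected to `replacingFraction` of the post-sample mass;
#' both samples are then multinomially sampled to `cfg$depth` reads. Planted
#' expansions are seeded into clones whose pre-therapy expected count is at
#' least 20 reads, since an expansion of a clone invisible at the sequencing
#' depth is operationally undefined. With `replacingFraction = 0` exactly
#' zero novel clones are injected.
#'
#' @param cfg a [syntheticConfig()].
#' @param nExpanded planted expansions (must be < `n_clones`).
#' @param fold expansion factor (> 1).
#' @param replacingFraction post-sample mass of novel clones, in `[0, 1)`.
#' @return list with `pre`, `post` ([Repertoire-class]) and `truth`
#'   (`expanded_keys`, `replacing_keys`, under the `cdr3_v` key).
#' @export
generateLongitudinalPair <- function(cfg, nExpanded, fold, replacingFraction = 0) {
  if (fold <= 1) stop("fold must exceed 1")
  if (nExpanded >= cfg$n_clones) stop("nExpanded must be below n_clones")
  if (replacingFraction < 0 || replacingFraction >= 1) {
    stop("replacingFraction must lie in [0, 1)")
  }
  out <- withSeed(cfg$seed, {
    n <- cfg$n_clones
    seqs <- vapply(seq_len(n), function(i) .oneCdr3(cfg), "")
    v <- sample(cfg$v_genes, n, replace = TRUE)
    j <- sample(cfg$j_genes, n, replace = TRUE)
    w <- .cloneWeights(cfg$clone_size_model, n)
    w <- w / sum(w)
    eligible <- which(w >= 20 / cfg$depth)
    if (length(eligible) < nExpanded) {
      eligible <- order(w, decreasing = TRUE)[seq_len(nExpanded)]
    }
    planted <- eligible[sample.int(length(eligible), nExpanded)]
    wPost <- w
    wPost[planted] <- wPost[planted] * fold
    wPost <- wPost / sum(wPost)
    nNovel <- round(replacingFraction * n)
    if (nNovel > 0L) {
      novelSeqs <- vapply(seq_len(nNovel), function(i) .oneCdr3(cfg), "")
      novelW <- .cloneWeights(cfg$clone_size_model, nNovel)
      novelW <- novelW / sum(novelW) * replacingFraction
      wPost <- c(wPost * (1 - replacingFraction), novelW)
      seqsPost <- c(seqs, novelSeqs)
      vPost <- c(v, sample(cfg$v_genes, nNovel, replace = TRUE))
      jPost <- c(j, sample(cfg$j_genes, nNovel, replace = TRUE))
    } else {
      seqsPost <- seqs; vPost <- v; jPost <- j
    }
    cPre <- drop(stats::rmultinom(1L, cfg$depth, w))
    cPost <- drop(stats::rmultinom(1L, cfg$depth, wPost))
    list(seqs = seqs, v = v, j = j, cPre = cPre,
         seqsPost = seqsPost, vPost = vPost, jPost = jPost, cPost = cPost,
         planted = planted, nNovel = nNovel)
  })
  mkRep <- function(seqs, v, j, counts, id, tp) {
    keep <- counts > 0L
    aggregateDuplicates(Repertoire(
      data.frame(cdr3aa = seqs[keep], v_gene = v[keep], j_gene = j[keep],
                 count = counts[keep], stringsAsFactors = FALSE),
      sampleId = id, metadata = list(timepoint = tp)))
  }
  pre <- mkRep(out$seqs, out$v, out$j, out$cPre, "pre", "pre")
  post <- mkRep(out$seqsPost, out$vPost, out$jPost, out$cPost, "post", "post")
  expandedKeys <- paste(out$seqs[out$planted], out$v[out$planted], sep = "|")
  replacingKeys <- if (out$nNovel > 0L) {
    idx <- length(out$seqs) + seq_len(out$nNovel)
    setdiff(paste(out$seqsPost[idx], out$vPost[idx], sep = "|"),
            paste(out$seqs, out$v, sep = "|"))
  } else character()
  list(pre = pre, post = post,
       truth = list(expanded_keys = expandedKeys,
                    replacing_keys = intersect(replacingKeys,
                                               cloneKey(post@clonotypes, "cdr3_v"))))
}

#' Generate a clustered single-cell dataset with planted effects
#'
#' Negative-binomial counts (dispersion `dispersion`, cluster-specific
#' means) for `nGenes` genes over `sum(clusterSizes)` cells; planted
#' effects: specificity labels enriched in one cluster at the configured
#' odds, a differential-expression shift for chosen genes in one cluster,
#' and ligand-receptor co-expression between two clusters. Cells carry
#' unique clonotypes (a fraction have none, emulating dropout of TCR
#' recovery).
#'
#' @param cfg a [syntheticConfig()] (seed and CDR3 model reused for
#'   clonotypes).
#' @param clusterSizes named integer vector of cells per cluster.
#' @param nGenes number of genes (default 60; ligand/receptor and DE genes
#'   are added if absent).
#' @param enrichment `list(specificity, cluster, odds, base_prob)` or `NULL`.
#' @param de `list(gene, cluster, log2_shift)` or `NULL`.
#' @param lr `list(ligand, receptor, cluster_a, cluster_b, strength)` or
#'   `NULL`.
#' @param dispersion NB dispersion (default 0.5; variance = mu + 0.5 mu^2).
#' @param tcrRecovery fraction of cells with a recovered clonotype
#'   (default 0.9).
#' @return list with `sce` (counts assay + cell metadata), `cells`
#'   (data.frame) and `truth`.
#' @export
generateScDataset <- function(cfg, clusterSizes, nGenes = 60L,
                              enrichment = NULL, de = NULL, lr = NULL,
                              dispersion = 0.5, tcrRecovery = 0.9) {
  if (is.null(names(clusterSizes))) {
    names(clusterSizes) <- paste0("cluster", seq_along(clusterSizes))
  }
  nCells <- sum(clusterSizes)
  genes <- paste0("GENE", seq_len(nGenes))
  extra <- setdiff(c(de$gene, lr$ligand, lr$receptor), genes)
  genes <- c(genes, extra)
  G <- length(genes)
  clusters <- rep(names(clusterSizes), clusterSizes)
  out <- withSeed(cfg$seed, {
    mu <- matrix(stats::rlnorm(G, meanlog = log(0.5), sdlog = 0.7),
                 G, length(clusterSizes),
                 dimnames = list(genes, names(clusterSizes)))
    if (!is.null(de)) {
      mu[de$gene, de$cluster] <- mu[de$gene, de$cluster] * 2^de$log2_shift
    }
    if (!is.null(lr)) {
      mu[lr$ligand, lr$cluster_a] <- mu[lr$ligand, lr$cluster_a] * lr$strength
      mu[lr$receptor, lr$cluster_b] <- mu[lr$receptor, lr$cluster_b] * lr$strength
    }
    counts <- matrix(0L, G, nCells, dimnames = list(genes, NULL))
    for (cl in names(clusterSizes)) {
      idx <- which(clusters == cl)
      counts[, idx] <- stats::rnbinom(G * length(idx), size = 1 / dispersion,
                                      mu = mu[, cl])
    }
    # guard against all-zero cells at tiny sizes
    empty <- which(colSums(counts) == 0L)
    if (length(empty)) counts[1L, empty] <- 1L
    hasTcr <- stats::runif(nCells) < tcrRecovery
    cdr3 <- rep(NA_character_, nCells)
    cdr3[hasTcr] <- vapply(seq_len(sum(hasTcr)), function(i) .oneCdr3(cfg), "")
    spec <- rep("none", nCells)
    if (!is.null(enrichment)) {
      p0 <- if (is.null(enrichment$base_prob)) 0.1 else enrichment$base_prob
      odds0 <- p0 / (1 - p0)
      odds1 <- odds0 * enrichment$odds
      p1 <- odds1 / (1 + odds1)
      pLab <- ifelse(clusters == enrichment$cluster, p1, p0)
      lab <- stats::runif(nCells) < pLab & hasTcr
      spec[lab] <- enrichment$specificity
    }
    list(counts = counts, cdr3 = cdr3, spec = spec)
  })
  cells <- data.frame(cell_id = sprintf("cell%05d", seq_len(nCells)),
                      cluster = clusters, cdr3aa = out$cdr3,
                      v_gene = ifelse(is.na(out$cdr3), NA_character_,
                                      rep_len(cfg$v_genes, nCells)),
                      specificity = out$spec,
                      sample_id = "S1", timepoint = "none",
                      stringsAsFactors = FALSE)
  list(sce = makeScExperiment(out$counts, cells), cells = cells,
       truth = list(enrichment = enrichment, de = de, lr = lr,
                    cluster_sizes = clusterSizes))
}
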