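# single-cell layer: clonotype-linked phenotype analyses on a
# SingleCellExperiment (clustering is an input, not computed here)

#' Assemble a SingleCellExperiment from counts and a cell table
#'
#' @param counts genes x cells matrix (dense or sparse) of non-negative
#'   counts with gene rownames.
#' @param cells data.frame with one row per cell; recognised columns:
#'   `cell_id`, `cluster`, `cdr3aa`, `v_gene`, `sample_id`, `timepoint`,
#'   `response`, `specificity`.
#' @return a [SingleCellExperiment::SingleCellExperiment] with a `counts`
#'   assay and the cell table as `colData`.
#' @export
makeScExperiment <- function(counts, cells) {
  stopifnot(ncol(counts) == nrow(cells))
  if (!is.null(cells$cell_id)) colnames(counts) <- cells$cell_id
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(cells))
}

#' Read a genes x cells expression matrix
#'
#' Reads either an MTX triplet (`matrix.mtx`, `genes.tsv`, `barcodes.tsv`)
#' via [Matrix::readMM()] or a dense tab-separated table with gene rownames.
#'
#' @param path path to `matrix.mtx` or to a dense TSV.
#' @param genesPath,barcodesPath companion files for the MTX layout
#'   (defaults: `genes.tsv` / `barcodes.tsv` next to the matrix).
#' @return a sparse or dense matrix with dimnames.
#' @export
readExpressionMatrix <- function(path, genesPath = NULL, barcodesPath = NULL) {
  if (grepl("\\.mtx$", path)) {
    dir <- dirname(path)
    if (is.null(genesPath)) genesPath <- file.path(dir, "genes.tsv")
    if (is.null(barcodesPath)) barcodesPath <- file.path(dir, "barcodes.tsv")
    m <- Matrix::readMM(path)
    rownames(m) <- utils::read.delim(genesPath, header = FALSE)[[1]]
    colnames(m) <- utils::read.delim(barcodesPath, header = FALSE)[[1]]
    m
  } else {
    as.matrix(utils::read.delim(path, row.names = 1L, check.names = FALSE))
  }
}

#' Log-normalise single-cell counts
#'
#' Scales each cell to `scaleFactor` (default 10,000) total counts and
#' applies `ln(1 + x)`, stored as a `lognorm` assay. Applying it to an
#' object that already carries a `lognorm` assay is a state error, as is an
#' all-zero cell (reported by ID).
#'
#' @param sce a [SingleCellExperiment::SingleCellExperiment] with a `counts`
#'   assay.
#' @param scaleFactor per-cell library-size target (default 1e4).
#' @return the object with a `lognorm` assay added.
#' @export
logNormalize <- function(sce, scaleFactor = 1e4) {
  if ("lognorm" %in% SummarizedExperiment::assayNames(sce)) {
    stop("object already carries a lognorm assay; refusing to re-normalise")
  }
  counts <- SummarizedExperiment::assay(sce, "counts")
  tot <- Matrix::colSums(counts)
  if (any(tot == 0)) {
    stop(sprintf("all-zero cell(s): %s",
                 paste(colnames(counts)[tot == 0], collapse = ", ")))
  }
  ln <- log1p(t(t(as.matrix(counts)) / tot * scaleFactor))
  SummarizedExperiment::assay(sce, "lognorm") <- ln
  sce
}

# specificity-test universe: cells with a recovered clonotype
.specUniverse <- function(cells) {
  if (!is.null(cells$cdr3aa)) {
    cells[!is.na(cells$cdr3aa) & cells$cdr3aa != "", , drop = FALSE]
  } else cells
}

#' Cluster enrichment of a specificity label
#'
#' Per cluster, a one-sided (greater) Fisher exact test of the 2x2 table
#' (group cells in cluster / elsewhere vs other cells in cluster /
#' elsewhere), BH-adjusted across clusters. Cells without a recovered TCR
#' are excluded; `"both"`-labelled cells count for every group.
#'
#' @param cells data.frame of cell records (`cluster`, `specificity`,
#'   optionally `cdr3aa`).
#' @param group specificity label to test (e.g. `"MAA"`).
#' @return data.frame with `cluster`, `n_group`, `n_cluster`, `p_value`,
#'   `p_adjusted`, ordered by cluster.
#' @export
clusterEnrichment <- function(cells, group) {
  cells <- .specUniverse(as.data.frame(cells))
  clusters <- sort(unique(cells$cluster))
  if (length(clusters) < 2L) stop("cluster enrichment requires >= 2 clusters")
  g <- cells$specificity %in% c(group, "both")
  if (!any(g)) stop(sprintf("no cells carry the label '%s'", group))
  res <- do.call(rbind, lapply(clusters, function(cl) {
    inC <- cells$cluster == cl
    a <- sum(g & inC); b <- sum(g & !inC)
    c_ <- sum(!g & inC); d <- sum(!g & !inC)
    data.frame(cluster = cl, n_group = a, n_cluster = sum(inC),
               p_value = stats::phyper(a - 1, a + b, c_ + d, a + c_,
                                       lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  res$p_adjusted <- bhAdjust(res$p_value)
  res
}

# row variances of a dense matrix
.rowVars <- function(x) {
  n <- ncol(x)
  if (n < 2L) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  (rowSums(x^2) - n * m^2) / (n - 1)
}

#' Per-gene differential expression between two cell groups
#'
#' Welch two-sided t-test per gene on log-normalised values, Bonferroni
#' correction over the tested genes, and log2 fold change of group means
#' (pseudocount 1e-9). Genes with zero variance in both groups get p = 1.
#'
#' @param sce a [SingleCellExperiment::SingleCellExperiment] with a
#'   `lognorm` assay, or a plain lognorm matrix.
#' @param cellsA,cellsB column indices or names of the two groups.
#' @param minCells minimum group size (default 10).
#' @return data.frame with `gene`, `mean_a`, `mean_b`, `log2_fc`,
#'   `t_statistic`, `p_value`, `p_adjusted`.
#' @export
differentialExpression <- function(sce, cellsA, cellsB, minCells = 10L) {
  x <- if (methods::is(sce, "SummarizedExperiment")) {
    as.matrix(SummarizedExperiment::assay(sce, "lognorm"))
  } else as.matrix(sce)
  if (length(cellsA) < minCells || length(cellsB) < minCells) {
    stop(sprintf("both groups need at least %d cells", minCells))
  }
  A <- x[, cellsA, drop = FALSE]; B <- x[, cellsB, drop = FALSE]
  nA <- ncol(A); nB <- ncol(B)
  mA <- rowMeans(A); mB <- rowMeans(B)
  vA <- .rowVars(A); vB <- .rowVars(B)
  se2 <- vA / nA + vB / nB
  tstat <- ifelse(se2 > 0, (mA - mB) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1)), 1)
  p <- ifelse(se2 > 0, 2 * stats::pt(-abs(tstat), df), 1)
  data.frame(gene = rownames(x), mean_a = mA, mean_b = mB,
             log2_fc = log2((mA + 1e-9) / (mB + 1e-9)),
             t_statistic = tstat, p_value = p,
             p_adjusted = pmin(1, p * nrow(x)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Paired change in a phenotype-cluster fraction across therapy
#'
#' For each patient with group-labelled cells at both timepoints, computes
#' the fraction of those cells occupying the phenotype cluster (e.g. an
#' exhausted-cell cluster) before and after therapy, then compares the
#' paired fractions with the Wilcoxon signed-rank test. Patients lacking
#' group cells at either timepoint are excluded with a message.
#'
#' @param cells data.frame of cell records with `sample_id` (patient),
#'   `timepoint` (`"pre"`/`"post"`), `cluster`, `specificity`.
#' @param phenotypeCluster cluster label whose occupancy is compared.
#' @param group specificity label defining the cell population.
#' @param minPairs minimum complete pre/post pairs (default 5).
#' @return list with `test` (a [TestResult()]) and `fractions` (per-patient
#'   pre/post fractions).
#' @export
exhaustionFractionChange <- function(cells, phenotypeCluster, group,
                                     minPairs = 5L) {
  cells <- .specUniverse(as.data.frame(cells))
  g <- cells[cells$specificity %in% c(group, "both"), , drop = FALSE]
  patients <- unique(g$sample_id)
  frac <- do.call(rbind, lapply(patients, function(p) {
    gp <- g[g$sample_id == p, , drop = FALSE]
    pre <- gp[gp$timepoint == "pre", , drop = FALSE]
    post <- gp[gp$timepoint == "post", , drop = FALSE]
    if (!nrow(pre) || !nrow(post)) return(NULL)
    data.frame(sample_id = p,
               pre = mean(pre$cluster == phenotypeCluster),
               post = mean(post$cluster == phenotypeCluster),
               stringsAsFactors = FALSE)
  }))
  nExcluded <- length(patients) - (if (is.null(frac)) 0L else nrow(frac))
  if (nExcluded > 0L) {
    message(sprintf("excluded %d patient(s) lacking %s cells at one timepoint",
                    nExcluded, group))
  }
  if (is.null(frac) || nrow(frac) < minPairs) {
    stop(sprintf("insufficient complete pre/post pairs (%d; need >= %d)",
                 if (is.null(frac)) 0L else nrow(frac), minPairs))
  }
  list(test = wilcoxonSignedRank(frac$pre, frac$post), fractions = frac)
}

#' Ligand-receptor interaction permutation test
#'
#' For every ordered pair of distinct clusters with at least `minCells`
#' cells each (smaller clusters are skipped with a message; the larger
#' cluster is subsampled to the smaller, seeded, so cell numbers are
#' normalised across phenotypes), scores each ligand-receptor pair as
#' `(mean ligand expression in A + mean receptor expression in B) / 2` on
#' log-normalised values and compares it with `nPerm` cluster-label shuffles
#' of the pooled cells: `p = (1 + #(null >= observed)) / (nPerm + 1)`. Pairs
#' whose ligand or receptor mean is zero on either side's assigned gene are
#' reported as non-expressed with `NA` p.
#'
#' @param sce a [SingleCellExperiment::SingleCellExperiment] with `lognorm`
#'   assay and a `cluster` column in `colData`, or a lognorm matrix plus
#'   `clusters`.
#' @param lrPairs data.frame with columns `ligand` and `receptor` (gene
#'   names); see [defaultLigandReceptorPairs()].
#' @param clusters cluster labels per cell (taken from `colData` when
#'   missing).
#' @param nPerm permutations (default 1000).
#' @param minCells minimum cells per cluster (default 50).
#' @param seed integer seed.
#' @return data.frame with `ligand`, `receptor`, `cluster_a`, `cluster_b`,
#'   `score`, `p_value`, `expressed`.
#' @export
interactionTest <- function(sce, lrPairs, clusters = NULL, nPerm = 1000L,
                            minCells = 50L, seed = 1L) {
  if (methods::is(sce, "SummarizedExperiment")) {
    if (is.null(clusters)) clusters <- SummarizedExperiment::colData(sce)$cluster
    x <- as.matrix(SummarizedExperiment::assay(sce, "lognorm"))
  } else x <- as.matrix(sce)
  stopifnot(!is.null(clusters), length(clusters) == ncol(x))
  miss <- setdiff(unique(c(lrPairs$ligand, lrPairs$receptor)), rownames(x))
  if (length(miss)) {
    stop(sprintf("gene(s) absent from the matrix: %s", paste(miss, collapse = ", ")))
  }
  sizes <- table(clusters)
  use <- names(sizes)[sizes >= minCells]
  skip <- setdiff(names(sizes), use)
  if (length(skip)) {
    message(sprintf("skipped cluster(s) below %d cells: %s", minCells,
                    paste(skip, collapse = ", ")))
  }
  if (length(use) < 2L) stop("fewer than two clusters meet the cell minimum")
  seeds <- deriveSeeds(seed, length(use)^2)
  res <- list(); si <- 0L
  for (a in use) for (b in use) {
    if (a == b) next
    si <- si + 1L
    ia <- which(clusters == a); ib <- which(clusters == b)
    m <- min(length(ia), length(ib))
    withSeed(seeds[si], {
      if (length(ia) > m) ia <- sample(ia, m)
      if (length(ib) > m) ib <- sample(ib, m)
      pool <- c(ia, ib)
      permIdx <- replicate(nPerm, sample(pool))
    })
    for (r in seq_len(nrow(lrPairs))) {
      lig <- x[lrPairs$ligand[r], ]; rec <- x[lrPairs$receptor[r], ]
      mlig <- mean(lig[ia]); mrec <- mean(rec[ib])
      if (mlig == 0 || mrec == 0) {
        res[[length(res) + 1L]] <- data.frame(
          ligand = lrPairs$ligand[r], receptor = lrPairs$receptor[r],
          cluster_a = a, cluster_b = b, score = NA_real_,
          p_value = NA_real_, expressed = FALSE, stringsAsFactors = FALSE)
        next
      }
      obs <- (mlig + mrec) / 2
      nullA <- colMeans(matrix(lig[permIdx[seq_len(m), ]], m))
      nullB <- colMeans(matrix(rec[permIdx[m + seq_len(m), ]], m))
      null <- (nullA + nullB) / 2
      res[[length(res) + 1L]] <- data.frame(
        ligand = lrPairs$ligand[r], receptor = lrPairs$receptor[r],
        cluster_a = a, cluster_b = b, score = obs,
        p_value = (1 + sum(null >= obs)) / (nPerm + 1),
        expressed = TRUE, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}

#' Fold change of significant interaction counts between two conditions
#'
#' Counts, per partner cluster (`cluster_b`), the ligand-receptor pairs
#' significant at `alpha` in each of two [interactionTest()] results (same
#' pair list required) and returns `log2((n_a + 1) / (n_b + 1))`.
#'
#' @param resultsA,resultsB [interactionTest()] outputs over identical pair
#'   lists.
#' @param alpha significance level (default 0.05).
#' @return data.frame with `partner`, `n_sig_a`, `n_sig_b`, `log2_fc`.
#' @export
interactionCountFoldchange <- function(resultsA, resultsB, alpha = 0.05) {
  idA <- paste(resultsA$ligand, resultsA$receptor)
  idB <- paste(resultsB$ligand, resultsB$receptor)
  if (!setequal(unique(idA), unique(idB))) {
    stop("the two results were computed over different ligand-receptor lists")
  }
  partners <- sort(unique(c(resultsA$cluster_b, resultsB$cluster_b)))
  cnt <- function(res, p) {
    sum(res$cluster_b == p & !is.na(res$p_value) & res$p_value < alpha)
  }
  do.call(rbind, lapply(partners, function(p) {
    na <- cnt(resultsA, p); nb <- cnt(resultsB, p)
    data.frame(partner = p, n_sig_a = na, n_sig_b = nb,
               log2_fc = log2((na + 1) / (nb + 1)), stringsAsFactors = FALSE)
  }))
}

#' Default ligand-receptor pair list
#'
#' A small curated list of co-stimulatory and co-inhibitory axes (including
#' LGALS9-HAVCR2, PVR-TIGIT and PVR-CD96) shipped as a plain-text data file
#' for use with [interactionTest()].
#'
#' @return data.frame with `ligand`, `receptor`, `class`.
#' @export
defaultLigandReceptorPairs <- function() {
  utils::read.delim(system.file("extdata", "lr_pairs_default.tsv",
                                package = "tcrscope"),
                    stringsAsFactors = FALSE)
}
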