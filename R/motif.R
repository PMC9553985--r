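# CDR3 k-mer motif enrichment, sharing and rank correlation
#
# A transparent stand-in for specificity-group algorithms: local k-mer motifs
# from the CDR3 core (germline-proximal termini trimmed), tested one-sidedly
# against a reference repertoire with an exact hypergeometric (Fisher) tail.

#' Extract contiguous k-mers from a CDR3 core
#'
#' Trims `trim` residues from each end of the sequence and enumerates all
#' contiguous k-mers of the remaining core, in order, duplicates retained. A
#' sequence whose core is shorter than `k` yields an empty vector (not an
#' error).
#'
#' @param cdr3aa a single CDR3 amino-acid sequence.
#' @param k k-mer length (>= 2).
#' @param trim residues removed from each end before enumeration (>= 0).
#' @return character vector of k-mers (possibly empty).
#' @export
extractKmers <- function(cdr3aa, k = 3L, trim = 3L) {
  stopifnot(length(cdr3aa) == 1L, k >= 2L, trim >= 0L)
  inner <- nchar(cdr3aa) - 2L * trim
  if (inner < k) return(character())
  core <- substr(cdr3aa, trim + 1L, nchar(cdr3aa) - trim)
  starts <- seq_len(inner - k + 1L)
  substring(core, starts, starts + k - 1L)
}

# unique k-mers per sequence (presence/absence: one vote per TCR per motif)
.kmerSets <- function(seqs, k, trim) {
  lapply(seqs, function(s) unique(extractKmers(s, k = k, trim = trim)))
}

# one-sided (greater) Fisher p for the 2x2 table
#   [ nT, NT - nT ; nR, NR - nR ]
# == upper hypergeometric tail P[X >= nT], X ~ Hyper(nT+nR draws of NT from NT+NR)
.fisherGreaterP <- function(nT, NT, nR, NR) {
  stats::phyper(nT - 1, nT + nR, (NT - nT) + (NR - nR), NT, lower.tail = FALSE)
}

#' k-mer motif enrichment of a target repertoire versus a reference
#'
#' For every k-mer occurring in the target's CDR3 cores, tests whether the
#' fraction of target TCRs containing the motif exceeds the reference
#' fraction with a one-sided Fisher exact test (each TCR contributes at most
#' once per motif), adjusts with Benjamini-Hochberg across all tested motifs,
#' and retains motifs with adjusted p below `alpha` and fold enrichment of at
#' least `minFold`. Fold is computed on pseudocounted fractions
#' `((n + 0.5)/(N + 0.5))`. Retained motifs are ranked by the number of
#' target TCRs sharing them (rank 1 = most shared; ties broken
#' lexicographically by motif string).
#'
#' @param target,reference QC-passing [Repertoire-class] objects; a reference
#'   below 100 clonotypes triggers a warning.
#' @param k,trim see [extractKmers()].
#' @param minFold minimum fold enrichment retained (default 2).
#' @param alpha BH-adjusted significance level (default 0.05).
#' @return a `data.frame` of class `MotifTable` with columns `motif`,
#'   `n_target`, `n_reference`, `fold`, `p_value`, `p_adjusted`, `rank`;
#'   attributes `k`, `trim`, `n_target_total`, `target_seqs`.
#' @export
motifEnrichment <- function(target, reference, k = 3L, trim = 3L,
                            minFold = 2, alpha = 0.05) {
  assertRepertoire(target); assertRepertoire(reference)
  tseq <- target@clonotypes$cdr3aa
  rseq <- reference@clonotypes$cdr3aa
  if (length(rseq) < 100L) {
    warning(sprintf("reference has only %d clonotypes; >= 100 recommended", length(rseq)))
  }
  tsets <- .kmerSets(tseq, k, trim)
  if (!length(unlist(tsets))) {
    stop("no k-mers extractable from target with this k/trim")
  }
  rsets <- .kmerSets(rseq, k, trim)
  NT <- length(tseq); NR <- length(rseq)
  tTab <- table(unlist(tsets))
  rAll <- unlist(rsets)
  rTab <- table(factor(rAll, levels = names(tTab)))
  nT <- as.integer(tTab)
  nR <- as.integer(rTab)
  motifs <- names(tTab)
  p <- .fisherGreaterP(nT, NT, nR, NR)
  padj <- bhAdjust(p)
  fold <- ((nT + 0.5) / (NT + 0.5)) / ((nR + 0.5) / (NR + 0.5))
  keep <- padj < alpha & fold >= minFold
  out <- data.frame(motif = motifs, n_target = nT, n_reference = nR,
                    fold = fold, p_value = p, p_adjusted = padj,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  out <- out[order(-out$n_target, out$motif), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("MotifTable", "data.frame")
  attr(out, "k") <- as.integer(k)
  attr(out, "trim") <- as.integer(trim)
  attr(out, "n_target_total") <- NT
  attr(out, "target_seqs") <- tseq
  out
}

#' Shared motifs between two motif tables
#'
#' Intersects the retained motifs of two [motifEnrichment()] tables and
#' reports, per shared motif, the number of target TCRs sharing it on each
#' side, plus the "resolved public" count: how many of table A's target TCRs
#' contain at least one shared motif.
#'
#' @param tableA,tableB non-empty `MotifTable` objects.
#' @return list with `shared` (data.frame `motif`, `n_target_a`,
#'   `n_target_b`), `n_shared`, and `n_resolved_a`.
#' @export
motifSharing <- function(tableA, tableB) {
  stopifnot(inherits(tableA, "MotifTable"), inherits(tableB, "MotifTable"))
  shared <- intersect(tableA$motif, tableB$motif)
  df <- data.frame(
    motif = shared,
    n_target_a = tableA$n_target[match(shared, tableA$motif)],
    n_target_b = tableB$n_target[match(shared, tableB$motif)],
    stringsAsFactors = FALSE)
  resolved <- 0L
  if (length(shared)) {
    sets <- .kmerSets(attr(tableA, "target_seqs"), attr(tableA, "k"), attr(tableA, "trim"))
    resolved <- sum(vapply(sets, function(s) any(s %in% shared), logical(1)))
  }
  list(shared = df, n_shared = length(shared), n_resolved_a = resolved)
}

#' Spearman rank correlation of shared motifs between two tables
#'
#' Correlates, over the motifs retained in both tables, each table's
#' sharing-rank (rank by number of target TCRs containing the motif) with
#' two-sided Spearman's rank correlation. Both rho and rho-squared are
#' reported. Symmetric in its arguments.
#'
#' @param tableA,tableB `MotifTable` objects with at least 5 shared motifs.
#' @return a [TestResult()] with fields `rho`, `rho_squared`, `n_shared`.
#' @export
motifRankCorrelation <- function(tableA, tableB) {
  stopifnot(inherits(tableA, "MotifTable"), inherits(tableB, "MotifTable"))
  shared <- intersect(tableA$motif, tableB$motif)
  if (length(shared) < 5L) {
    stop(sprintf("insufficient overlap: %d shared motifs (need >= 5)", length(shared)))
  }
  ra <- tableA$rank[match(shared, tableA$motif)]
  rb <- tableB$rank[match(shared, tableB$motif)]
  ct <- suppressWarnings(stats::cor.test(ra, rb, method = "spearman",
                                         alternative = "two.sided", exact = FALSE))
  TestResult(statistic = unname(ct$estimate), p.value = ct$p.value,
             alternative = "two.sided", method = "Spearman rank correlation",
             rho = unname(ct$estimate), rho_squared = unname(ct$estimate)^2,
             n_shared = length(shared))
}
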