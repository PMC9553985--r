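# diversity / clonality indices, public-clonotype sharing, nonparametric tests

#' Diversity and clonality indices
#'
#' `shannonIndex` returns the Shannon-Wiener entropy H = -sum p_i log p_i in
#' nats; `simpsonIndex` returns the Simpson dominance sum p_i^2 (the
#' diversity form 1 - sum p_i^2 is available via `form = "diversity"`);
#' `clonality` returns 1 - H / log(richness), the normalised-Shannon
#' clonality in `[0, 1]` (0 for a perfectly even repertoire, approaching 1
#' under single-clone dominance). All three are invariant under clone
#' reordering and rescaling of counts by a common factor.
#'
#' @param rep a non-empty [Repertoire-class].
#' @return a single numeric value.
#' @export
shannonIndex <- function(rep) {
  assertRepertoire(rep)
  p <- rep@clonotypes$frequency
  p <- p[p > 0]
  -sum(p * log(p))
}

#' @rdname shannonIndex
#' @param form `"dominance"` (sum p^2, default) or `"diversity"` (1 - sum p^2).
#' @export
simpsonIndex <- function(rep, form = c("dominance", "diversity")) {
  form <- match.arg(form)
  assertRepertoire(rep)
  s <- sum(rep@clonotypes$frequency^2)
  if (form == "dominance") s else 1 - s
}

#' @rdname shannonIndex
#' @export
clonality <- function(rep) {
  assertRepertoire(rep)
  R <- nrow(rep@clonotypes)
  if (R < 2L) stop("clonality undefined for richness < 2")
  1 - shannonIndex(rep) / log(R)
}

#' One-sample diversity report
#'
#' Computes richness, Shannon, Simpson (dominance) and clonality for a
#' repertoire, optionally after seeded subsampling to a fixed depth so that
#' samples of unequal depth are comparable.
#'
#' @param rep a [Repertoire-class].
#' @param subsampleDepth optional read depth; when given the indices are
#'   computed on [subsampleRepertoire()] output.
#' @param seed seed for the subsampling draw.
#' @return one-row `data.frame`: `sample_id`, `richness`, `shannon`,
#'   `simpson`, `clonality`, `subsample_depth`.
#' @export
diversityReport <- function(rep, subsampleDepth = NULL, seed = 1L) {
  assertRepertoire(rep)
  r <- if (is.null(subsampleDepth)) rep else subsampleRepertoire(rep, subsampleDepth, seed)
  data.frame(
    sample_id = r@sampleId,
    richness = nrow(r@clonotypes),
    shannon = shannonIndex(r),
    simpson = simpsonIndex(r),
    clonality = if (nrow(r@clonotypes) >= 2L) clonality(r) else NA_real_,
    subsample_depth = if (is.null(subsampleDepth)) NA_integer_ else as.integer(subsampleDepth),
    stringsAsFactors = FALSE
  )
}

#' Public clonotype overlap between two repertoires
#'
#' Exact-match intersection of clone identity keys, with a Jaccard-style
#' shared fraction `n_shared / (n_a + n_b - n_shared)`.
#'
#' @param repA,repB non-empty [Repertoire-class] objects.
#' @param key clone identity key (see [aggregateDuplicates()]).
#' @return list with `n_shared`, `n_a`, `n_b`, `fraction_shared`,
#'   `shared_keys`.
#' @export
publicOverlap <- function(repA, repB, key = c("cdr3_v", "cdr3")) {
  key <- match.arg(key)
  assertRepertoire(repA); assertRepertoire(repB)
  ka <- unique(cloneKey(repA@clonotypes, key))
  kb <- unique(cloneKey(repB@clonotypes, key))
  shared <- intersect(ka, kb)
  n <- length(shared)
  list(n_shared = n, n_a = length(ka), n_b = length(kb),
       fraction_shared = n / (length(ka) + length(kb) - n),
       shared_keys = shared)
}

#' Pairwise sharing matrix
#'
#' Symmetric matrix of pairwise shared-clonotype counts across a list of
#' repertoires; the diagonal holds each sample's own richness (unique keys).
#'
#' @param reps list of at least two [Repertoire-class] objects.
#' @inheritParams publicOverlap
#' @return integer matrix with sample IDs as dimnames.
#' @export
overlapMatrix <- function(reps, key = c("cdr3_v", "cdr3")) {
  key <- match.arg(key)
  if (length(reps) < 2L) stop("overlapMatrix needs at least 2 repertoires")
  keys <- lapply(reps, function(r) unique(cloneKey(r@clonotypes, key)))
  n <- length(reps)
  m <- matrix(0L, n, n, dimnames = list(vapply(reps, sampleId, ""),
                                        vapply(reps, sampleId, "")))
  for (i in seq_len(n)) {
    m[i, i] <- length(keys[[i]])
    for (j in seq_len(n)) if (j > i) {
      m[i, j] <- m[j, i] <- length(intersect(keys[[i]], keys[[j]]))
    }
  }
  m
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Wraps [stats::wilcox.test()]: the exact null distribution is used when the
#' product of group sizes is at most 400 and there are no ties; otherwise the
#' tie-corrected normal approximation with continuity correction. Two groups
#' that are identical constants return p = 1.
#'
#' @param groupA,groupB numeric vectors (each non-empty).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return a [TestResult()] with the U statistic.
#' @export
mannWhitneyU <- function(groupA, groupB, alternative = "two.sided") {
  if (!length(groupA) || !length(groupB)) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(groupA, groupB)) > 0L
  if (length(unique(c(groupA, groupB))) == 1L) {
    return(TestResult(statistic = length(groupA) * length(groupB) / 2,
                      p.value = 1, alternative = alternative,
                      method = "Mann-Whitney U"))
  }
  exact <- !ties && length(groupA) * length(groupB) <= 400
  wt <- suppressWarnings(stats::wilcox.test(groupA, groupB,
                                            alternative = alternative,
                                            exact = exact, correct = TRUE))
  TestResult(statistic = wt$statistic, p.value = wt$p.value,
             alternative = alternative, method = "Mann-Whitney U",
             exact = exact)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Paired test on `post - pre` differences; zero differences are dropped
#' (signed-rank convention). Exact when at most 20 non-zero differences with
#' no tied magnitudes, else the normal approximation. Degenerate input (all
#' differences zero, or fewer than one non-zero pair) returns p = 1.
#'
#' @param preValues,postValues equal-length numeric vectors.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return a [TestResult()] with the signed-rank statistic V and the number
#'   of non-zero pairs used (`n_used`).
#' @export
wilcoxonSignedRank <- function(preValues, postValues, alternative = "two.sided") {
  if (length(preValues) != length(postValues)) {
    stop("pre and post vectors must have equal length")
  }
  d <- postValues - preValues
  nz <- d[d != 0]
  if (!length(nz)) {
    return(TestResult(statistic = 0, p.value = 1, alternative = alternative,
                      method = "Wilcoxon signed-rank", n_used = 0L))
  }
  exact <- length(nz) <= 20L && !anyDuplicated(abs(nz))
  wt <- suppressWarnings(stats::wilcox.test(nz, alternative = alternative,
                                            exact = exact, correct = TRUE))
  TestResult(statistic = wt$statistic, p.value = wt$p.value,
             alternative = alternative, method = "Wilcoxon signed-rank",
             n_used = length(nz), exact = exact)
}
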