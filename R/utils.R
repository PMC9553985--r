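# shared internals: keys, frequency bookkeeping, p-value adjustment, TestResult

recomputeFrequencies <- function(cl) {
  tot <- sum(cl$count)
  cl$frequency <- if (tot > 0) cl$count / tot else rep(0, nrow(cl))
  cl
}

# clone identity keys; missing genes carry an explicit sentinel that never
# collides with a named gene
cloneKey <- function(cl, key = c("cdr3_v", "cdr3")) {
  key <- match.arg(key)
  if (key == "cdr3") return(cl$cdr3aa)
  v <- ifelse(is.na(cl$v_gene), "<missing>", cl$v_gene)
  paste(cl$cdr3aa, v, sep = "|")
}

assertRepertoire <- function(rep, nonempty = TRUE) {
  if (!methods::is(rep, "Repertoire")) stop("expected a Repertoire object")
  if (nonempty && nrow(rep@clonotypes) == 0L) {
    stop("empty repertoire: no clonotypes")
  }
  invisible(rep)
}

#' Benjamini-Hochberg and Bonferroni adjustment
#'
#' Thin named wrappers over [stats::p.adjust()], the multiplicity corrections
#' used throughout: BH everywhere except single-cell differential expression
#' (Bonferroni).
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values, same length and order as `p`.
#' @export
bhAdjust <- function(p) stats::p.adjust(p, method = "BH")

#' @rdname bhAdjust
#' @export
bonferroniAdjust <- function(p) stats::p.adjust(p, method = "bonferroni")

#' Construct a hypothesis-test result record
#'
#' A lightweight S3 container (`TestResult`) used by all test-returning
#' operations: statistic, p-value, optional adjusted p, alternative and method
#' name, plus any extra fields (e.g. estimates).
#'
#' @param statistic numeric test statistic.
#' @param p.value p-value in `[0, 1]`.
#' @param alternative one of `"two.sided"`, `"greater"`, `"less"`.
#' @param method human-readable method name.
#' @param p.adjusted optional adjusted p-value.
#' @param ... further named fields stored on the result.
#' @return a list of class `TestResult`.
#' @export
TestResult <- function(statistic, p.value, alternative = "two.sided",
                       method = "test", p.adjusted = NULL, ...) {
  stopifnot(p.value >= 0, p.value <= 1 + 1e-12)
  out <- list(statistic = unname(statistic), p.value = min(1, unname(p.value)),
              p.adjusted = if (is.null(p.adjusted)) NA_real_ else min(1, p.adjusted),
              alternative = alternative, method = method, ...)
  class(out) <- "TestResult"
  out
}

#' @export
print.TestResult <- function(x, ...) {
  cat(sprintf("%s (%s): statistic = %.6g, p = %.4g%s\n", x$method, x$alternative,
              x$statistic, x$p.value,
              if (!is.na(x$p.adjusted)) sprintf(", p.adj = %.4g", x$p.adjusted) else ""))
  invisible(x)
}

# run expr with a locally-set RNG state, restoring the caller's state
withSeed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# derive a stream of sub-seeds from one master seed (all < 2^31)
deriveSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Median split of a continuous covariate
#'
#' Dichotomises a continuous vector at its median (values strictly above the
#' median form the `"high"` stratum), the convention used for stratifying
#' survival analyses on continuous markers.
#'
#' @param x numeric vector.
#' @param labels two labels, low then high.
#' @return character vector of stratum labels.
#' @export
medianSplit <- function(x, labels = c("low", "high")) {
  stopifnot(length(labels) == 2L)
  m <- stats::median(x, na.rm = TRUE)
  ifelse(x > m, labels[2L], labels[1L])
}
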