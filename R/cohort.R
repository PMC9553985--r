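# cohort-level biomarker analyses: target frequency, cross-validated logistic
# AUROC, age matching, dominant-clone flag, Kaplan-Meier / log-rank

#' Aggregate frequency of group-labelled clonotypes
#'
#' Sums the read frequencies of clonotypes carrying the group label (clones
#' labelled `"both"` count for every group) and reports their number. The
#' unique-clonotype fraction is returned alongside, since "abundance" can be
#' read either way.
#'
#' @param labeledRep a [Repertoire-class] labelled by [classifyRepertoire()].
#' @param group group label (e.g. `"MAA"`).
#' @return list with `frequency`, `n_clones`, `clone_fraction`.
#' @export
targetFrequency <- function(labeledRep, group) {
  assertRepertoire(labeledRep)
  cl <- labeledRep@clonotypes
  if (is.null(cl$specificity)) {
    stop("repertoire has no specificity labels; run classifyRepertoire() first")
  }
  hit <- cl$specificity %in% c(group, "both")
  list(frequency = sum(cl$frequency[hit]), n_clones = sum(hit),
       clone_fraction = sum(hit) / nrow(cl))
}

#' Cross-validated cohort AUROC of a frequency biomarker
#'
#' Fits a single-feature logistic regression of case/control status on
#' `target_frequency` under stratified k-fold cross-validation and pools the
#' out-of-fold predicted probabilities into one AUROC (concordant-pair
#' computation). With one monotone feature this measures how well the
#' biomarker separates the cohorts out-of-sample.
#'
#' @param table data.frame with columns `group` (`"case"`/`"control"`) and
#'   `target_frequency`; at least 10 of each group.
#' @param folds number of folds (default 10).
#' @param seed fold-assignment seed.
#' @return list with `auroc`, `fold_auroc` (per-fold AUROCs, `NA` where a
#'   fold lacks a class), `scores`.
#' @export
cohortAuroc <- function(table, folds = 10L, seed = 1L) {
  stopifnot(all(c("group", "target_frequency") %in% colnames(table)))
  y <- table$group == "case"
  if (sum(y) < 10L || sum(!y) < 10L) {
    stop("need at least 10 cases and 10 controls")
  }
  fold <- .stratifiedFolds(ifelse(y, 1, -1), folds, seed)
  if (any(vapply(split(y, fold), function(v) length(unique(v)) < 2L, TRUE))) {
    stop("stratification failed: a fold contains a single class")
  }
  scores <- rep(NA_real_, nrow(table))
  for (fd in seq_len(folds)) {
    test <- fold == fd
    dat <- data.frame(y = y[!test], x = table$target_frequency[!test])
    fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial(), data = dat))
    scores[test] <- suppressWarnings(
      stats::predict(fit, data.frame(x = table$target_frequency[test]),
                     type = "response"))
  }
  fold_auroc <- vapply(seq_len(folds), function(fd) {
    i <- fold == fd
    if (length(unique(y[i])) < 2L) return(NA_real_)
    aurocPairs(scores[i], y[i])
  }, numeric(1))
  list(auroc = aurocPairs(scores, y), fold_auroc = fold_auroc, scores = scores)
}

#' Age-matched control subsampling
#'
#' Greedy nearest-age matching without replacement: cases are visited in a
#' seeded random order and each receives `ratio` controls closest in age
#' within the caliper (ties broken by the seeded shuffle of the control
#' order). Errors naming the first case that cannot be fully matched.
#'
#' @param table data.frame with columns `sample_id`, `group`
#'   (`"case"`/`"control"`) and `age`.
#' @param ratio controls per case (default 2).
#' @param caliper maximum |age difference| in years.
#' @param seed integer seed for tie-breaking.
#' @return the subsetted table (all cases plus matched controls).
#' @export
ageMatchedSubsample <- function(table, ratio = 2L, caliper = 5, seed = 1L) {
  stopifnot(all(c("sample_id", "group", "age") %in% colnames(table)))
  if (anyNA(table$age)) stop("ages must be present for matching")
  cases <- which(table$group == "case")
  controls <- which(table$group == "control")
  withSeed(seed, {
    cases <- cases[sample.int(length(cases))]
    controls <- controls[sample.int(length(controls))]
  })
  taken <- integer()
  for (i in cases) {
    d <- abs(table$age[controls] - table$age[i])
    ok <- controls[d <= caliper]
    ok <- setdiff(ok[order(abs(table$age[ok] - table$age[i]))], taken)
    if (length(ok) < ratio) {
      stop(sprintf("matching error: case '%s' has %d eligible control(s), needs %d",
                   table$sample_id[i], length(ok), ratio))
    }
    taken <- c(taken, ok[seq_len(ratio)])
  }
  out <- table[sort(c(cases, taken)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Dominant labelled clone flag
#'
#' `TRUE` iff any *single* clonotype carrying the group label exceeds the
#' frequency threshold (default 1% of reads); a per-clone rule, not a sum.
#'
#' @param labeledRep a labelled [Repertoire-class].
#' @param group group label.
#' @param threshold frequency threshold (default 0.01, strict inequality).
#' @return logical flag.
#' @export
dominantCloneFlag <- function(labeledRep, group, threshold = 0.01) {
  assertRepertoire(labeledRep)
  cl <- labeledRep@clonotypes
  if (is.null(cl$specificity)) {
    stop("repertoire has no specificity labels; run classifyRepertoire() first")
  }
  hit <- cl$specificity %in% c(group, "both")
  any(cl$frequency[hit] > threshold)
}

#' Kaplan-Meier product-limit estimate
#'
#' Wraps [survival::survfit()]; returns the step function as a data.frame.
#'
#' @param records data.frame with columns `time` (non-negative) and `event`
#'   (1 = event, 0 = censored).
#' @return data.frame with `time`, `n_risk`, `n_event`, `survival`.
#' @export
kmEstimate <- function(records) {
  stopifnot(all(c("time", "event") %in% colnames(records)), nrow(records) >= 1L)
  if (any(records$time < 0)) stop("negative survival time")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
             survival = sf$surv)
}

#' Log-rank test between two strata
#'
#' Wraps [survival::survdiff()] (rho = 0): chi-square on observed minus
#' expected events across distinct event times; two-sided p on 1 df.
#'
#' @param records data.frame with `time`, `event` and a stratum column.
#' @param stratumCol name of the binary stratum column (default
#'   `"stratum"`).
#' @return a [TestResult()] with the chi-square statistic and the per-stratum
#'   observed/expected counts.
#' @export
logrankTest <- function(records, stratumCol = "stratum") {
  stopifnot(all(c("time", "event", stratumCol) %in% colnames(records)))
  strata <- unique(records[[stratumCol]])
  if (length(strata) != 2L) stop("log-rank test requires exactly two strata")
  records$.s <- records[[stratumCol]]
  sd <- survival::survdiff(survival::Surv(time, event) ~ .s, data = records)
  TestResult(statistic = sd$chisq,
             p.value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
             alternative = "two.sided", method = "log-rank",
             observed = sd$obs, expected = sd$exp)
}
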