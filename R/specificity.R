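# the in-silico multimer sorter: training, cross-validation, FPR-calibrated
# thresholds, panel combination and panel-level FPR

defaultModelConfig <- function(max_len = 22L, trim = 0L, d = 6L,
                               sigma2 = 1, jitter = 1e-6) {
  list(max_len = as.integer(max_len), trim = as.integer(trim), d = as.integer(d),
       sigma2 = sigma2, jitter = jitter, lengthscale = NULL)
}

#' Build a training set
#'
#' @param epitope epitope name.
#' @param positives character vector of positive CDR3s.
#' @param subjects optional subject IDs parallel to `positives`.
#' @param background optional character vector of background CDR3s; when
#'   supplied with `balanced = TRUE` its size must equal the positives'.
#' @param balanced logical; the classifier's 1:1 construction.
#' @return a [TrainingSet-class]
#' @export
TrainingSet <- function(epitope, positives, subjects = NULL,
                        background = character(), balanced = TRUE) {
  pos <- data.frame(cdr3aa = as.character(positives),
                    subject = if (is.null(subjects)) NA_character_
                              else as.character(subjects),
                    stringsAsFactors = FALSE)
  methods::new("TrainingSet", epitope = epitope, positives = pos,
               background = as.character(background), balanced = balanced)
}

# draw a balanced background (seeded) from a pool, excluding positives
.balancedBackground <- function(ts, backgroundPool, seed) {
  if (length(ts@background)) return(ts@background)
  if (is.null(backgroundPool)) {
    stop("training set has no background and no backgroundPool was supplied")
  }
  pool <- setdiff(unique(backgroundPool), ts@positives$cdr3aa)
  n <- nrow(ts@positives)
  if (length(pool) < n) stop("background pool smaller than the positive set")
  withSeed(seed, sample(pool, n))
}

.fitCore <- function(X, y, config) {
  ls <- config$lengthscale
  if (is.null(ls)) ls <- medianLengthscale(X)
  K <- seKernel(X, X, ls, config$sigma2)
  diag(K) <- diag(K) + config$jitter
  fit <- gpLaplaceFit(K, y)
  method <- "gp_laplace"
  if (is.null(fit)) {
    fit <- klogisticFit(K, y)
    method <- "kernel_logistic"
  }
  list(fit = fit, method = method, lengthscale = ls)
}

#' Train an epitope-specificity model
#'
#' Fits a Laplace-approximate Gaussian-process classifier (squared-exponential
#' kernel over [encodeCdr3()] embeddings, deterministic jitter) on the
#' positives versus an equal-sized background; when the Newton iteration
#' fails, a regularised kernel-logistic fit is used instead and recorded in
#' the model. The kernel length-scale defaults to the median pairwise
#' training distance. Deterministic for a fixed seed (the seed is used only
#' for the background draw from `backgroundPool`).
#'
#' @param ts a [TrainingSet-class] with at least 20 positives.
#' @param config list from `defaultModelConfig()`.
#' @param seed integer seed.
#' @param backgroundPool character vector to draw a balanced background from
#'   when `ts` carries none.
#' @return an [EpitopeModel-class]
#' @export
trainEpitopeModel <- function(ts, config = defaultModelConfig(), seed = 1L,
                              backgroundPool = NULL) {
  stopifnot(methods::is(ts, "TrainingSet"))
  if (nrow(ts@positives) < 20L) {
    stop(sprintf("too few positives (%d); at least 20 required", nrow(ts@positives)))
  }
  bg <- .balancedBackground(ts, backgroundPool, seed)
  seqs <- c(ts@positives$cdr3aa, bg)
  y <- c(rep(1, nrow(ts@positives)), rep(-1, length(bg)))
  X <- encodeCdr3(seqs, config$max_len, config$trim, config$d)
  core <- .fitCore(X, y, config)
  cfg <- config
  cfg$lengthscale <- core$lengthscale
  methods::new("EpitopeModel", epitope = ts@epitope, config = cfg,
               fit = list(X = X, y = y, sequences = seqs, method = core$method,
                          core = core$fit),
               seed = as.integer(seed))
}

#' Predict epitope-specificity probabilities for CDR3 sequences
#'
#' Returns one probability per sequence, deterministic and independent of
#' input order or batching. Sequences that cannot be encoded (non-standard
#' residues, too long for the model frame) get `NA` with a message.
#'
#' @param model a trained [EpitopeModel-class].
#' @param sequences character vector of CDR3s.
#' @return numeric vector of probabilities in `[0, 1]` (`NA` where
#'   un-encodable).
#' @export
predictScores <- function(model, sequences) {
  stopifnot(methods::is(model, "EpitopeModel"), length(model@fit) > 0)
  cfg <- model@config
  ok <- encodableCdr3(sequences, cfg$max_len, cfg$trim)
  if (any(!ok)) {
    message(sprintf("%d sequence(s) could not be encoded; scores set to NA", sum(!ok)))
  }
  out <- rep(NA_real_, length(sequences))
  if (!any(ok)) return(out)
  Xs <- encodeCdr3(sequences[ok], cfg$max_len, cfg$trim, cfg$d)
  Kstar <- seKernel(Xs, model@fit$X, cfg$lengthscale, cfg$sigma2)
  out[ok] <- gpPredict(model@fit$core, NULL, Kstar,
                       rep(cfg$sigma2 + cfg$jitter, nrow(Xs)), model@fit$method)
  out
}

# stratified fold assignment (deterministic per seed)
.stratifiedFolds <- function(y, k, seed) {
  folds <- integer(length(y))
  withSeed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      folds[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
    }
  })
  folds
}

#' Cross-validate an epitope training set
#'
#' Evaluates the classifier with the scheme used in the study: `"auto"`
#' selects leave-one-out when there are fewer than 100 positives and 20-fold
#' cross-validation otherwise; `"leave_one_subject_out"` holds out all
#' positives of one subject per fold (requires subject IDs) together with a
#' matched share of background. Folds are stratified by class; out-of-fold
#' scores are pooled into a single ROC with trapezoid AUROC and a
#' precision-recall curve with average precision, evaluated on the balanced
#' 1:1 design.
#'
#' @param ts a [TrainingSet-class].
#' @param config model configuration (see [trainEpitopeModel()]).
#' @param scheme `"auto"`, `"kfold20"`, `"loo"` or `"leave_one_subject_out"`.
#' @param seed integer seed (background draw and fold shuffling).
#' @param backgroundPool as in [trainEpitopeModel()].
#' @return list (ROC report): `scheme`, `scores`, `labels`, `fold`, `fpr`,
#'   `tpr`, `auroc`, `precision`, `recall`, `average_precision`.
#' @export
crossValidate <- function(ts, config = defaultModelConfig(),
                          scheme = c("auto", "kfold20", "loo", "leave_one_subject_out"),
                          seed = 1L, backgroundPool = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(methods::is(ts, "TrainingSet"))
  nPos <- nrow(ts@positives)
  if (scheme == "auto") scheme <- if (nPos < 100L) "loo" else "kfold20"
  if (scheme == "leave_one_subject_out" && all(is.na(ts@positives$subject))) {
    stop("leave_one_subject_out requires subject IDs on the positives")
  }
  bg <- .balancedBackground(ts, backgroundPool, seed)
  seqs <- c(ts@positives$cdr3aa, bg)
  y <- c(rep(1, nPos), rep(-1, length(bg)))
  X <- encodeCdr3(seqs, config$max_len, config$trim, config$d)
  n <- length(y)
  folds <- switch(scheme,
    loo = seq_len(n),
    kfold20 = .stratifiedFolds(y, 20L, seed),
    leave_one_subject_out = {
      subj <- c(ts@positives$subject, rep(NA_character_, length(bg)))
      subjects <- unique(stats::na.omit(subj))
      f <- integer(n)
      f[seq_len(nPos)] <- match(subj[seq_len(nPos)], subjects)
      # spread background across subject folds, stratified, seeded
      f[nPos + seq_along(bg)] <- withSeed(seed,
        sample(rep(seq_along(subjects), length.out = length(bg))))
      f
    })
  # a single length-scale from the full design keeps folds comparable
  ls <- config$lengthscale
  if (is.null(ls)) ls <- medianLengthscale(X)
  cfg <- config; cfg$lengthscale <- ls
  Kfull <- seKernel(X, X, ls, cfg$sigma2)
  scores <- rep(NA_real_, n)
  for (fd in sort(unique(folds))) {
    test <- folds == fd
    K <- Kfull[!test, !test, drop = FALSE]
    diag(K) <- diag(K) + cfg$jitter
    fit <- gpLaplaceFit(K, y[!test])
    method <- "gp_laplace"
    if (is.null(fit)) { fit <- klogisticFit(K, y[!test]); method <- "kernel_logistic" }
    Kstar <- Kfull[test, !test, drop = FALSE]
    scores[test] <- gpPredict(fit, NULL, Kstar,
                              rep(cfg$sigma2 + cfg$jitter, sum(test)), method)
  }
  roc <- rocCurve(scores, y > 0)
  pr <- prCurve(scores, y > 0)
  list(scheme = scheme, scores = scores, labels = y > 0, fold = folds,
       fpr = roc$fpr, tpr = roc$tpr, auroc = roc$auroc,
       precision = pr$precision, recall = pr$recall,
       average_precision = pr$average_precision)
}

#' Calibrate a model's decision threshold to a target false-positive rate
#'
#' Chooses the smallest threshold `t` such that the fraction of background
#' scores strictly greater than `t` is at most `targetFpr` (the study's 5%
#' rule); a positive call is a score strictly greater than `t`. Degenerate
#' constant backgrounds yield `t = max(score)` with a warning.
#'
#' @param model an [EpitopeModel-class].
#' @param backgroundScores numeric scores of background sequences under this
#'   model (at least 100 recommended; fewer triggers a warning).
#' @param targetFpr target FPR in `[0, 1]` (default 0.05).
#' @return the model with its `threshold` slot set.
#' @export
calibrateThreshold <- function(model, backgroundScores, targetFpr = 0.05) {
  stopifnot(methods::is(model, "EpitopeModel"))
  s <- backgroundScores[!is.na(backgroundScores)]
  if (length(s) < 100L) {
    warning(sprintf("only %d background scores; >= 100 recommended", length(s)))
  }
  if (length(unique(s)) == 1L) {
    warning("degenerate constant background scores; threshold set to their maximum")
    model@threshold <- s[1L]
    return(model)
  }
  sd <- sort(s, decreasing = TRUE)
  k <- floor(targetFpr * length(sd))
  model@threshold <- if (k == 0L) sd[1L] else sd[k + 1L]
  methods::validObject(model)
  model
}

#' Assemble a model panel
#'
#' @param models named list of calibrated [EpitopeModel-class] objects (names
#'   = epitopes); unnamed lists are named from the models' epitopes.
#' @param groups named list mapping group labels (e.g. `"MAA"`, `"VIRAL"`)
#'   to epitope name vectors.
#' @return a [ModelPanel-class]
#' @export
ModelPanel <- function(models, groups) {
  if (is.null(names(models))) {
    names(models) <- vapply(models, function(m) m@epitope, "")
  }
  methods::new("ModelPanel", models = models, groups = groups)
}

#' Label a repertoire's clonotypes with predicted specificities
#'
#' Scores every clonotype's CDR3 under every panel model and flags it for an
#' epitope when the score strictly exceeds that model's calibrated threshold.
#' The group label follows the union rule: a clone positive for any epitope
#' of a group carries that group's label; clones positive in more than one
#' group are labelled `"both"` (and count towards each group's frequency);
#' clones with no positive call are `"none"`.
#'
#' @param panel a [ModelPanel-class] whose grouped models all carry
#'   calibrated thresholds.
#' @param rep a [Repertoire-class].
#' @return the repertoire with one logical column per epitope
#'   (`pred_<epitope>`) and a `specificity` column added to its clonotype
#'   table.
#' @export
classifyRepertoire <- function(panel, rep) {
  stopifnot(methods::is(panel, "ModelPanel"))
  assertRepertoire(rep)
  grouped <- unique(unlist(panel@groups))
  for (e in grouped) {
    if (is.na(panel@models[[e]]@threshold)) {
      stop(sprintf("model '%s' has no calibrated threshold", e))
    }
  }
  cl <- rep@clonotypes
  flags <- matrix(FALSE, nrow(cl), length(panel@models),
                  dimnames = list(NULL, names(panel@models)))
  for (e in names(panel@models)) {
    m <- panel@models[[e]]
    sc <- predictScores(m, cl$cdr3aa)
    flags[, e] <- !is.na(sc) & !is.na(m@threshold) & sc > m@threshold
    cl[[paste0("pred_", e)]] <- flags[, e]
  }
  groupHit <- vapply(names(panel@groups), function(g) {
    rowSums(flags[, panel@groups[[g]], drop = FALSE]) > 0
  }, logical(nrow(cl)))
  if (nrow(cl) == 1L) groupHit <- matrix(groupHit, nrow = 1L,
                                         dimnames = list(NULL, names(panel@groups)))
  nHit <- rowSums(groupHit)
  lab <- rep("none", nrow(cl))
  for (g in colnames(groupHit)) lab[groupHit[, g] & nHit == 1L] <- g
  lab[nHit > 1L] <- "both"
  cl$specificity <- lab
  methods::initialize(rep, clonotypes = cl)
}

#' Panel-level false-positive rate on negative sequences
#'
#' Fraction of negative sequences called positive by *any* model of the
#' group — the union construction whose FPR exceeds the per-model 5% (near
#' `1 - 0.95^m` when the models' errors are independent).
#'
#' @param panel a calibrated [ModelPanel-class].
#' @param group group name in the panel.
#' @param negativeSequences character vector of negative CDR3s (>= 1000
#'   recommended; fewer triggers a warning).
#' @return a single fraction in `[0, 1]`.
#' @export
estimatePanelFpr <- function(panel, group, negativeSequences) {
  stopifnot(methods::is(panel, "ModelPanel"), group %in% names(panel@groups))
  if (!length(negativeSequences)) stop("no negative sequences supplied")
  if (length(negativeSequences) < 1000L) {
    warning(sprintf("only %d negatives; >= 1000 recommended", length(negativeSequences)))
  }
  hit <- rep(FALSE, length(negativeSequences))
  for (e in panel@groups[[group]]) {
    m <- panel@models[[e]]
    if (is.na(m@threshold)) stop(sprintf("model '%s' has no calibrated threshold", e))
    sc <- predictScores(m, negativeSequences)
    hit <- hit | (!is.na(sc) & sc > m@threshold)
  }
  mean(hit)
}
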