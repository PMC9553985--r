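# shared fixtures for the classifier tests (moderate sizes keep fits fast)
lenRange <- c(10, 18)
bgPool <- generateCdr3s(syntheticConfig(seed = 990, cdr3_length_range = lenRange), 3000)
plantedTs <- generateEpitopeRepertoire(
  syntheticConfig(seed = 7, cdr3_length_range = lenRange),
  list(kmer = "WGQG", prob = 0.9, position = "center"),
  nPositives = 120, subjects = 6, epitope = "SYN_WGQG")

test_that("training requires enough positives and records its method", {
  tiny <- TrainingSet("E", generateCdr3s(syntheticConfig(seed = 1), 10))
  expect_error(trainEpitopeModel(tiny, backgroundPool = bgPool), "too few positives")
  m <- trainEpitopeModel(plantedTs, seed = 3, backgroundPool = bgPool)
  expect_s4_class(m, "EpitopeModel")
  expect_true(m@fit$method %in% c("gp_laplace", "kernel_logistic"))
  expect_equal(length(m@fit$y), 240L)  # balanced 1:1
})

test_that("predictions are probabilities, deterministic, order- and batch-invariant", {
  m <- trainEpitopeModel(plantedTs, seed = 3, backgroundPool = bgPool)
  m2 <- trainEpitopeModel(plantedTs, seed = 3, backgroundPool = bgPool)
  test <- bgPool[1:40]
  s <- predictScores(m, test)
  expect_true(all(s >= 0 & s <= 1))
  expect_identical(s, predictScores(m2, test))
  expect_equal(s, rev(predictScores(m, rev(test))))
  expect_equal(s, vapply(test, function(x) predictScores(m, x), 0, USE.NAMES = FALSE))
  # training positives score above training background on average
  expect_gt(mean(predictScores(m, positives(plantedTs)$cdr3aa)),
            mean(predictScores(m, m@fit$sequences[m@fit$y < 0])))
  # un-encodable sequences yield NA with a message
  expect_message(sNA <- predictScores(m, c("CASSF", strrep("A", 30))), "NA")
  expect_true(is.na(sNA[2]) && !is.na(sNA[1]))
})

test_that("cross-validation separates planted signal and follows the scheme rule", {
  cv <- crossValidate(plantedTs, scheme = "kfold20", seed = 3, backgroundPool = bgPool)
  expect_gte(cv$auroc, 0.85)
  expect_equal(rocCurve(cv$scores, cv$labels)$auroc, cv$auroc)
  expect_equal(aurocPairs(cv$scores, cv$labels), cv$auroc, tolerance = 1e-9)
  # auto rule: below 100 positives -> LOO
  small <- generateEpitopeRepertoire(
    syntheticConfig(seed = 8, cdr3_length_range = lenRange),
    list(kmer = "WGQG", prob = 0.9, position = "center"), 30, subjects = 3)
  cvS <- crossValidate(small, scheme = "auto", seed = 3, backgroundPool = bgPool)
  expect_equal(cvS$scheme, "loo")
  big <- generateEpitopeRepertoire(
    syntheticConfig(seed = 9, cdr3_length_range = lenRange),
    list(kmer = "WGQG", prob = 0.9, position = "center"), 120, subjects = 6)
  cvB <- crossValidate(big, scheme = "auto", seed = 3, backgroundPool = bgPool)
  expect_equal(cvB$scheme, "kfold20")
  # leave-one-subject-out needs subjects and yields one fold per subject
  cvL <- crossValidate(small, scheme = "leave_one_subject_out", seed = 3,
                       backgroundPool = bgPool)
  expect_equal(length(unique(cvL$fold)), 3L)
  noSubj <- TrainingSet("E", positives(small)$cdr3aa)
  expect_error(crossValidate(noSubj, scheme = "leave_one_subject_out",
                             backgroundPool = bgPool), "subject IDs")
})

test_that("label-permuted training data gives chance-level AUROC", {
  null <- generateEpitopeRepertoire(
    syntheticConfig(seed = 10, cdr3_length_range = lenRange),
    list(kmer = "WGQG", prob = 0, position = "center"), 120, subjects = 6)
  cv <- crossValidate(null, scheme = "kfold20", seed = 3, backgroundPool = bgPool)
  expect_gte(cv$auroc, 0.35)
  expect_lte(cv$auroc, 0.65)
})

test_that("threshold calibration implements the smallest-threshold FPR rule", {
  m <- trainEpitopeModel(plantedTs, seed = 3, backgroundPool = bgPool)
  m1 <- calibrateThreshold(m, seq(0.01, 1, by = 0.01), targetFpr = 0.05)
  expect_equal(modelThreshold(m1), 0.95)
  expect_equal(mean(seq(0.01, 1, by = 0.01) > modelThreshold(m1)), 0.05)
  m0 <- calibrateThreshold(m, seq(0.01, 1, by = 0.01), targetFpr = 0)
  expect_equal(modelThreshold(m0), 1)
  expect_warning(md <- calibrateThreshold(m, rep(0.4, 200)), "degenerate")
  expect_equal(modelThreshold(md), 0.4)
  expect_warning(calibrateThreshold(m, runif(50)), "recommended")
})

test_that("a calibrated threshold transfers to fresh background at the nominal rate", {
  m <- trainEpitopeModel(plantedTs, seed = 3, backgroundPool = bgPool)
  calib <- generateCdr3s(syntheticConfig(seed = 991, cdr3_length_range = lenRange), 1500)
  m <- calibrateThreshold(m, predictScores(m, calib))
  held <- generateCdr3s(syntheticConfig(seed = 992, cdr3_length_range = lenRange), 5000)
  fpr <- mean(predictScores(m, held) > modelThreshold(m))
  expect_gte(fpr, 0.03)
  expect_lte(fpr, 0.07)
})

test_that("panel classification applies the per-group union rule", {
  cfgA <- syntheticConfig(seed = 61, cdr3_length_range = lenRange)
  tsA <- generateEpitopeRepertoire(cfgA, list(kmer = "WGQG", prob = 1, position = "center"),
                                   60, epitope = "EPI_A")
  tsB <- generateEpitopeRepertoire(syntheticConfig(seed = 62, cdr3_length_range = lenRange),
                                   list(kmer = "HDMW", prob = 1, position = "center"),
                                   60, epitope = "EPI_B")
  calib <- generateCdr3s(syntheticConfig(seed = 63, cdr3_length_range = lenRange), 800)
  mA <- trainEpitopeModel(tsA, seed = 5, backgroundPool = bgPool)
  mB <- trainEpitopeModel(tsB, seed = 5, backgroundPool = bgPool)
  mA <- calibrateThreshold(mA, predictScores(mA, calib))
  mB <- calibrateThreshold(mB, predictScores(mB, calib))
  panel <- ModelPanel(list(mA, mB), groups = list(MAA = c("EPI_A", "EPI_B")))

  rep <- Repertoire(data.frame(
    cdr3aa = c(positives(tsA)$cdr3aa[1], positives(tsB)$cdr3aa[1], bgPool[1]),
    count = c(5L, 5L, 5L)))
  lab <- classifyRepertoire(panel, rep)
  cl <- clonotypes(lab)
  # each epitope's strong positive is caught by its own model; union labels both
  expect_true(cl$pred_EPI_A[1])
  expect_true(cl$pred_EPI_B[2])
  expect_equal(cl$specificity[1], "MAA")
  expect_equal(cl$specificity[2], "MAA")

  # a clone positive in two groups is labelled "both"
  panel2 <- ModelPanel(list(mA, mB), groups = list(MAA = "EPI_A", VIRAL = "EPI_B"))
  lab2 <- classifyRepertoire(panel2, rep)
  expect_true(all(clonotypes(lab2)$specificity[1] %in% c("MAA", "both")))

  # thresholds at the top of the probability scale silence every model
  mA@threshold <- 1; mB@threshold <- 1
  panelOff <- ModelPanel(list(mA, mB), groups = list(MAA = c("EPI_A", "EPI_B")))
  expect_true(all(clonotypes(classifyRepertoire(panelOff, rep))$specificity == "none"))

  # uncalibrated model in a group is a state error
  mU <- trainEpitopeModel(tsA, seed = 5, backgroundPool = bgPool)
  expect_error(classifyRepertoire(ModelPanel(list(mU), groups = list(MAA = "EPI_A")), rep),
               "threshold")
})

test_that("panel FPR is the union rate over the group's models", {
  cfg <- syntheticConfig(seed = 70, cdr3_length_range = lenRange)
  motifs <- c("WGQG", "HDMW", "KPLE")
  models <- lapply(seq_along(motifs), function(i) {
    ts <- generateEpitopeRepertoire(syntheticConfig(seed = 70 + i,
                                                    cdr3_length_range = lenRange),
                                    list(kmer = motifs[i], prob = 1, position = "center"),
                                    60, epitope = paste0("E", i))
    m <- trainEpitopeModel(ts, seed = 5, backgroundPool = bgPool)
    calib <- generateCdr3s(syntheticConfig(seed = 170 + i, cdr3_length_range = lenRange), 800)
    calibrateThreshold(m, predictScores(m, calib))
  })
  panel <- ModelPanel(models, groups = list(MAA = paste0("E", 1:3)))
  negatives <- generateCdr3s(syntheticConfig(seed = 270, cdr3_length_range = lenRange), 1500)
  fprPanel <- estimatePanelFpr(panel, "MAA", negatives)
  single <- vapply(models, function(m) {
    mean(predictScores(m, negatives) > modelThreshold(m))
  }, 0)
  expect_gte(fprPanel, max(single))
  expect_lte(fprPanel, sum(single))
  expect_error(estimatePanelFpr(panel, "MAA", character()), "no negative")
})
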