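test_that("log-normalisation follows the 10,000-scale formula", {
  counts <- matrix(c(5L, 0L, 2L, 2L), 2, 2,
                   dimnames = list(c("G1", "G2"), c("c1", "c2")))
  sce <- makeScExperiment(counts, data.frame(cell_id = c("c1", "c2"),
                                             cluster = "A"))
  sce <- logNormalize(sce)
  ln <- SummarizedExperiment::assay(sce, "lognorm")
  expect_equal(ln["G1", "c1"], log(1 + 10000))
  expect_equal(ln["G2", "c1"], 0)                     # zeros stay zero
  expect_equal(ln["G1", "c2"], log(1 + 5000))
  # doubling a cell's counts leaves its lognorm column unchanged
  sce2 <- makeScExperiment(counts * 2L, data.frame(cell_id = c("c1", "c2"),
                                                   cluster = "A"))
  expect_equal(SummarizedExperiment::assay(logNormalize(sce2), "lognorm"), ln)
  # re-normalising is a state error
  expect_error(logNormalize(sce), "already")
  # all-zero cells are reported by ID
  bad <- makeScExperiment(matrix(c(1L, 0L), 1, 2,
                                 dimnames = list("G1", NULL)),
                          data.frame(cell_id = c("ok", "empty"), cluster = "A"))
  expect_error(logNormalize(bad), "empty")
})

test_that("cluster enrichment matches the hypergeometric tail and excludes TCR-less cells", {
  cells <- data.frame(
    cell_id = sprintf("c%03d", 1:100),
    cluster = rep(c("A", "B"), c(10, 90)),
    cdr3aa = "CASSWGQGF",
    specificity = c(rep("MAA", 10), rep("none", 90)))
  res <- clusterEnrichment(cells, "MAA")
  a <- res[res$cluster == "A", ]
  expect_equal(a$p_value, oracleFisherGreater(10, 10, 0, 90), tolerance = 1e-10)
  expect_equal(a$p_value, 1 / choose(100, 10), tolerance = 1e-12)
  # cells without a recovered TCR do not enter the table
  cells2 <- rbind(cells, data.frame(cell_id = "x1", cluster = "A",
                                    cdr3aa = NA, specificity = "none"))
  expect_equal(clusterEnrichment(cells2, "MAA")$p_value, res$p_value)
  expect_error(clusterEnrichment(cells[cells$cluster == "A", ], "MAA"), "2 clusters")
})

test_that("enrichment p decreases monotonically as the overlap grows", {
  pFor <- function(k) {
    cells <- data.frame(cluster = rep(c("A", "B"), c(40, 60)),
                        cdr3aa = "CASSWGQGF",
                        specificity = c(rep("MAA", k), rep("none", 100 - k)))
    res <- clusterEnrichment(cells, "MAA")
    res$p_value[res$cluster == "A"]
  }
  ps <- vapply(c(5, 15, 30, 40), pFor, 0)
  expect_true(all(diff(ps) < 0))
})

test_that("labels assigned independently of clusters rarely reach significance", {
  hits <- vapply(deriveSeeds(88, 50), function(s) {
    set.seed(s)
    cells <- data.frame(cluster = sample(c("A", "B", "C"), 150, TRUE),
                        cdr3aa = "CASSWGQGF",
                        specificity = sample(c("MAA", "none"), 150, TRUE,
                                             prob = c(0.2, 0.8)))
    min(clusterEnrichment(cells, "MAA")$p_adjusted) < 0.05
  }, logical(1))
  expect_lte(mean(hits), 0.10)
})

test_that("differential expression is a Welch t-test with exact Bonferroni", {
  set.seed(6)
  x <- matrix(rnorm(100 * 100, 1, 1), 100, 100,
              dimnames = list(paste0("G", 1:100), paste0("c", 1:100)))
  x[x < 0] <- 0
  x["G7", 51:100] <- x["G7", 51:100] + 2   # planted +2 lognorm shift
  de <- differentialExpression(x, 1:50, 51:100)
  expect_equal(de$gene[which.min(de$p_value)], "G7")
  # closed-form Welch evaluation for one gene
  g <- "G13"
  a <- x[g, 1:50]; b <- x[g, 51:100]
  tstat <- (mean(a) - mean(b)) / sqrt(var(a) / 50 + var(b) / 50)
  df <- (var(a) / 50 + var(b) / 50)^2 /
    ((var(a) / 50)^2 / 49 + (var(b) / 50)^2 / 49)
  expect_equal(de$t_statistic[de$gene == g], tstat, tolerance = 1e-12)
  expect_equal(de$p_value[de$gene == g], 2 * pt(-abs(tstat), df), tolerance = 1e-12)
  expect_equal(de$p_adjusted, pmin(1, de$p_value * 100))
  # identical groups: zero fold change, p ~ 1
  deSame <- differentialExpression(x, 1:50, 1:50)
  expect_true(all(abs(deSame$log2_fc) < 1e-12))
  expect_true(all(deSame$p_value > 0.999))
  expect_error(differentialExpression(x, 1:5, 6:100), "at least 10")
})

test_that("permuted-label differential expression rarely yields Bonferroni hits", {
  hits <- vapply(deriveSeeds(60, 50), function(s) {
    set.seed(s)
    x <- matrix(rnorm(60 * 80, 1, 1), 60, 80,
                dimnames = list(paste0("G", 1:60), NULL))
    idx <- sample(80)
    de <- differentialExpression(x, idx[1:40], idx[41:80])
    any(de$p_adjusted < 0.05)
  }, logical(1))
  expect_lte(mean(hits), 0.08)
})

test_that("exhaustion-fraction change pairs patients and applies the signed-rank test", {
  mkCells <- function(fracPre, fracPost, nPer = 20L) {
    do.call(rbind, lapply(seq_along(fracPre), function(i) {
      rbind(
        data.frame(sample_id = paste0("P", i), timepoint = "pre",
                   cluster = rep(c("exhausted", "other"),
                                 c(round(nPer * fracPre[i]),
                                   nPer - round(nPer * fracPre[i]))),
                   cdr3aa = "CASSWGQGF", specificity = "MAA"),
        data.frame(sample_id = paste0("P", i), timepoint = "post",
                   cluster = rep(c("exhausted", "other"),
                                 c(round(nPer * fracPost[i]),
                                   nPer - round(nPer * fracPost[i]))),
                   cdr3aa = "CASSWGQGF", specificity = "MAA"))
    }))
  }
  same <- mkCells(seq(0.1, 0.8, 0.1), seq(0.1, 0.8, 0.1))
  resSame <- exhaustionFractionChange(same, "exhausted", "MAA")
  expect_equal(resSame$test$p.value, 1)
  # 8 patients, all fractions strictly decreasing: p = 2 / 2^8
  dec <- mkCells(seq(0.45, 0.80, 0.05), seq(0.45, 0.80, 0.05) - seq(0.05, 0.40, 0.05))
  resDec <- exhaustionFractionChange(dec, "exhausted", "MAA")
  expect_equal(resDec$test$p.value, 2 / 2^8)
  expect_equal(nrow(resDec$fractions), 8L)
  # patients lacking post cells are excluded with a message
  partial <- rbind(dec, data.frame(sample_id = "P9", timepoint = "pre",
                                   cluster = "exhausted", cdr3aa = "CASSWGQGF",
                                   specificity = "MAA"))
  expect_message(resP <- exhaustionFractionChange(partial, "exhausted", "MAA"),
                 "excluded 1")
  expect_equal(nrow(resP$fractions), 8L)
  few <- mkCells(c(0.2, 0.3), c(0.1, 0.2))
  expect_error(exhaustionFractionChange(few, "exhausted", "MAA"), "insufficient")
})

test_that("interaction test finds a planted axis at the permutation floor", {
  sd <- generateScDataset(syntheticConfig(seed = 9), c(A = 80, B = 80),
                          lr = list(ligand = "LGALS9", receptor = "HAVCR2",
                                    cluster_a = "A", cluster_b = "B",
                                    strength = 15))
  sce <- logNormalize(sd$sce)
  pairs <- data.frame(ligand = "LGALS9", receptor = "HAVCR2")
  res <- interactionTest(sce, pairs, nPerm = 499L, minCells = 50L, seed = 4L)
  ab <- res[res$cluster_a == "A" & res$cluster_b == "B", ]
  expect_equal(ab$p_value, 1 / 500)
  expect_true(all(res$p_value > 0, na.rm = TRUE))
  # clusters below the cell minimum are skipped with a message
  expect_message(
    interactionTest(sce, pairs, clusters = rep(c("A", "B", "tiny"), c(75, 75, 10)),
                    nPerm = 99L, seed = 4L),
    "skipped")
})

test_that("interaction p-values are invariant to pair order and flag non-expression", {
  sd <- generateScDataset(syntheticConfig(seed = 12), c(A = 60, B = 60), nGenes = 30L)
  sce <- logNormalize(sd$sce)
  x <- SummarizedExperiment::assay(sce, "lognorm")
  zeroGene <- rbind(x, DEADGENE = 0)
  pairs <- data.frame(ligand = c("GENE1", "GENE2"), receptor = c("GENE3", "GENE4"))
  r1 <- interactionTest(zeroGene, pairs, clusters = sd$cells$cluster,
                        nPerm = 199L, seed = 4L)
  r2 <- interactionTest(zeroGene, pairs[2:1, ], clusters = sd$cells$cluster,
                        nPerm = 199L, seed = 4L)
  key <- function(r) paste(r$ligand, r$cluster_a, r$cluster_b)
  expect_equal(r1$p_value[order(key(r1))], r2$p_value[order(key(r2))])
  dead <- interactionTest(zeroGene, data.frame(ligand = "DEADGENE", receptor = "GENE3"),
                          clusters = sd$cells$cluster, nPerm = 99L, seed = 4L)
  expect_true(all(!dead$expressed))
  expect_true(all(is.na(dead$p_value)))
})

test_that("interaction-count fold changes use the +1 pseudocount and antisymmetry", {
  mk <- function(p) data.frame(ligand = paste0("L", 1:3), receptor = paste0("R", 1:3),
                               cluster_a = "A", cluster_b = "B",
                               score = 1, p_value = p, expressed = TRUE)
  a <- mk(c(0.001, 0.001, 0.001)); b <- mk(c(0.5, 0.5, 0.5))
  fc <- interactionCountFoldchange(a, b)
  expect_equal(fc$log2_fc, 2)   # log2((3+1)/(0+1))
  expect_equal(interactionCountFoldchange(b, a)$log2_fc, -fc$log2_fc)
  expect_equal(interactionCountFoldchange(a, a)$log2_fc, 0)
  expect_error(interactionCountFoldchange(a, mk(0.5)[1:2, ]), "different")
})
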