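test_that("simple dialect reads, recomputes frequencies, round-trips", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("cdr3aa\tv_gene\tj_gene\tcount",
               "CASSF\tTRBV9\tTRBJ2-1\t10",
               "CASSY\tTRBV9\tTRBJ2-7\t30"), f)
  r <- readClonotypeTable(f, "simple")
  expect_equal(clonotypes(r)$frequency, c(0.25, 0.75))
  expect_equal(sum(clonotypes(r)$count), 40L)

  g <- withr::local_tempfile(fileext = ".tsv")
  writeClonotypeTable(r, g, "simple")
  r2 <- readClonotypeTable(g, "simple", sampleId = sampleId(r))
  expect_equal(clonotypes(r2), clonotypes(r))

  h <- withr::local_tempfile(fileext = ".tsv")
  writeClonotypeTable(r, h, "airr")
  hdr <- strsplit(readLines(h, n = 1L), "\t")[[1]]
  expect_setequal(hdr, c("junction_aa", "v_call", "j_call", "duplicate_count"))
  r3 <- readClonotypeTable(h, "airr", sampleId = sampleId(r))
  expect_equal(clonotypes(r3), clonotypes(r))
})

test_that("missing mandatory columns raise format errors naming the column", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("junction_aa\tv_call\tj_call", "CASSF\tTRBV9\tTRBJ2-1"), f)
  expect_error(readClonotypeTable(f, "airr"), "duplicate_count")
  expect_error(readClonotypeTable(f, "simple"), "cdr3aa")
})

test_that("immunoseq dialect matches synonyms case-insensitively and drops out-of-frame rows", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("aminoAcid\tvGeneName\tjGeneName\tTemplates\tsequenceStatus",
               "CASSF\tTRBV9\tTRBJ2-1\t10\tIn",
               "CASSY\tTRBV9\tTRBJ2-7\t30\tOut",
               "CASSW\tTRBV5\tTRBJ1-1\t10\tIn"), f)
  expect_message(r <- readClonotypeTable(f, "immunoseq"), "not marked in-frame")
  expect_equal(nrow(clonotypes(r)), 2L)
  expect_equal(clonotypes(r)$frequency, c(0.5, 0.5))
})

test_that("rows with empty CDR3 are dropped with a logged count", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("cdr3aa\tv_gene\tj_gene\tcount",
               "\tTRBV9\tTRBJ2-1\t5",
               "CASSY\tTRBV9\tTRBJ2-7\t5"), f)
  expect_message(r <- readClonotypeTable(f, "simple"), "empty CDR3")
  expect_equal(nrow(clonotypes(r)), 1L)
})

test_that("filterFunctional removes stops, frameshifts, short and lowercase CDR3s", {
  r <- Repertoire(data.frame(
    cdr3aa = c("CASSF*QETQYF", "CASSLGETQYF", "CAS_F", "CAS#F", "casslgetqyf", "CAS"),
    count = c(5L, 5L, 3L, 2L, 2L, 1L)))
  expect_message(f <- filterFunctional(r), "removed 5")
  expect_equal(clonotypes(f)$cdr3aa, "CASSLGETQYF")
  expect_equal(clonotypes(f)$frequency, 1)
  # idempotent, and identity on clean input
  expect_equal(clonotypes(filterFunctional(f)), clonotypes(f))
  # all removed -> empty-repertoire error
  bad <- Repertoire(data.frame(cdr3aa = "CAS_F", count = 3L))
  expect_error(filterFunctional(bad), "empty repertoire")
})

test_that("aggregateDuplicates merges under the chosen key", {
  r <- Repertoire(data.frame(cdr3aa = c("CASSF", "CASSF"),
                             v_gene = c("TRBV9", "TRBV9"),
                             count = c(2L, 3L)))
  a <- aggregateDuplicates(r, "cdr3_v")
  expect_equal(nrow(clonotypes(a)), 1L)
  expect_equal(clonotypes(a)$count, 5L)

  r2 <- Repertoire(data.frame(cdr3aa = c("CASSF", "CASSF"),
                              v_gene = c("TRBV9", "TRBV5"),
                              count = c(2L, 3L)))
  expect_equal(nrow(clonotypes(aggregateDuplicates(r2, "cdr3"))), 1L)
  expect_equal(nrow(clonotypes(aggregateDuplicates(r2, "cdr3_v"))), 2L)
  # already-unique table unchanged
  u <- makeRep(c(1L, 2L, 3L))
  expect_equal(clonotypes(aggregateDuplicates(u)), clonotypes(u))
})

test_that("missing V genes merge with each other but never with named genes", {
  r <- Repertoire(data.frame(cdr3aa = c("CASSF", "CASSF", "CASSF"),
                             v_gene = c(NA, NA, "TRBV9"),
                             count = c(1L, 2L, 4L)))
  a <- aggregateDuplicates(r, "cdr3_v")
  expect_equal(nrow(clonotypes(a)), 2L)
  expect_setequal(clonotypes(a)$count, c(3L, 4L))
})

test_that("poolRepertoires unions clonotypes and renormalises", {
  a <- makeRep(10L, cdr3 = "CASSXF", id = "A")
  b <- Repertoire(data.frame(cdr3aa = c("CASSXF", "CASSYF"),
                             v_gene = "TRBV9", j_gene = "TRBJ2-1",
                             count = c(10L, 20L)), sampleId = "B")
  p <- poolRepertoires(list(a, b), "pool")
  cl <- clonotypes(p)[order(clonotypes(p)$cdr3aa), ]
  expect_equal(cl$count, c(20L, 20L))
  expect_equal(cl$frequency, c(0.5, 0.5))
  expect_equal(sampleId(p), "pool")
  # single repertoire: same table, new id
  p1 <- poolRepertoires(list(b), "solo")
  expect_equal(clonotypes(p1)[, 1:4], clonotypes(b)[, 1:4])
  # disjoint union size
  d1 <- makeRep(1:3, id = "d1")
  d2 <- makeRep(1:4, cdr3 = paste0("CASSW", AA[1:4], "EQYF"), id = "d2")
  expect_equal(nrow(clonotypes(poolRepertoires(list(d1, d2)))), 7L)
  expect_error(poolRepertoires(list()), "empty")
})

test_that("subsampleRepertoire is an exact, seeded hypergeometric draw", {
  r <- makeRep(c(100L, 50L, 25L, 25L))
  expect_equal(clonotypes(subsampleRepertoire(r, 200L, 1L))$count,
               clonotypes(r)$count)
  one <- makeRep(100L)
  expect_equal(clonotypes(subsampleRepertoire(one, 10L, 1L))$count, 10L)
  s1 <- subsampleRepertoire(r, 60L, 7L)
  s2 <- subsampleRepertoire(r, 60L, 7L)
  expect_identical(clonotypes(s1), clonotypes(s2))
  expect_equal(sum(clonotypes(s1)$count), 60L)
  expect_error(subsampleRepertoire(r, 500L, 1L), "exceeds")
  big <- makeRep(rep(10L, 100L))
  expect_false(identical(clonotypes(subsampleRepertoire(big, 300L, 1L)),
                         clonotypes(subsampleRepertoire(big, 300L, 2L))))
})

test_that("subsampled per-clone counts match depth x frequency in expectation", {
  r <- makeRep(c(60L, 25L, 10L, 5L))
  depth <- 40L
  draws <- vapply(1:1000, function(s) {
    cl <- clonotypes(subsampleRepertoire(r, depth, s))
    full <- clonotypes(r)
    cl$count[match(full$cdr3aa, cl$cdr3aa)]
  }, numeric(4))
  draws[is.na(draws)] <- 0
  expected <- depth * clonotypes(r)$frequency
  se <- apply(draws, 1, stats::sd) / sqrt(ncol(draws))
  expect_true(all(abs(rowMeans(draws) - expected) <= 3 * pmax(se, 1e-9)))
})

test_that("every operation leaves frequencies summing to one", {
  r <- makeRep(c(7L, 3L, 90L))
  for (obj in list(filterFunctional(r), aggregateDuplicates(r),
                   poolRepertoires(list(r, r)), subsampleRepertoire(r, 50L, 3L))) {
    expect_lt(abs(sum(clonotypes(obj)$frequency) - 1), 1e-9)
  }
  expect_error(writeClonotypeTable(
    methods::new("Repertoire", sampleId = "e",
                 clonotypes = clonotypes(r)[0, ], metadata = list()),
    withr::local_tempfile(), "simple"), "empty")
})
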