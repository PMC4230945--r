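# Reading, writing and replicate handling of the expression / Ct tables.

write_lines <- function(lines, path) writeLines(lines, path)

test_that("expression matrix round-trips through TSV with its design", {
  tr <- defaultSimTruth(seed = 11)
  ex <- simulateExpression(tr)
  mp <- withr::local_tempfile(fileext = ".tsv")
  dp <- withr::local_tempfile(fileext = ".tsv")
  writeExpressionTable(ex, mp, dp)
  ex2 <- readExpressionTable(mp, dp)
  expect_identical(rownames(ex2), rownames(ex))
  expect_identical(colnames(ex2), colnames(ex))
  expect_equal(SummarizedExperiment::assay(ex2), SummarizedExperiment::assay(ex),
               tolerance = 1e-12)
  expect_identical(designTable(ex2)$organ, designTable(ex)$organ)
})

test_that("expression reader reports malformed inputs with coordinates", {
  dp <- withr::local_tempfile(fileext = ".tsv")
  write_lines(c("sample_id\torgan\tstage\treplicate",
                "s1\troot\tLP\t1", "s2\troot\tFS\t1"), dp)
  mp <- withr::local_tempfile(fileext = ".tsv")

  write_lines("gene\ts1\ts2", mp)
  expect_error(readExpressionTable(mp, dp), "no genes")

  write_lines(c("gene\ts1\ts2", "g1\t1\t2", "g1\t3\t4", "g2\t5\t6"), mp)
  expect_error(readExpressionTable(mp, dp), "duplicate gene.*g1")

  write_lines(c("gene\ts1\ts2", "g1\t1\tabc"), mp)
  expect_error(readExpressionTable(mp, dp), "non-numeric.*abc.*g1.*s2")

  write_lines(c("gene\ts1\ts2\ts3", "g1\t1\t2\t3"), mp)
  expect_error(readExpressionTable(mp, dp), "s3")
})

test_that("Ct reader handles wide and long layouts, defaults E = 2", {
  dp <- withr::local_tempfile(fileext = ".tsv")
  write_lines(c("sample_id\torgan\tstage\treplicate",
                "s1\troot\tLP\t1", "s2\troot\tFS\t1", "s3\tstem\tLP\t1"), dp)
  long <- withr::local_tempfile(fileext = ".tsv")
  rows <- expand.grid(gene = c("g1", "g2"), sample_id = c("s1", "s2", "s3"),
                      replicate = 1:3)
  rows$ct <- 20 + seq_len(nrow(rows)) / 10
  write_lines(c("gene\tsample_id\treplicate\tct",
                sprintf("%s\t%s\t%d\t%.2f", rows$gene, rows$sample_id,
                        rows$replicate, rows$ct)), long)
  ct <- readCtTable(long, dp)
  expect_s4_class(ct, "CtTable")
  expect_identical(dim(ct), c(2L, 9L))
  expect_equal(unname(efficiencies(ct)), c(2, 2))

  ep <- withr::local_tempfile(fileext = ".tsv")
  write_lines(c("gene\tefficiency", "g2\t1.9"), ep)
  ct2 <- readCtTable(long, dp, ep)
  expect_equal(unname(efficiencies(ct2)), c(2, 1.9))

  wide <- withr::local_tempfile(fileext = ".tsv")
  write_lines(c("gene\ts1.1\ts1.2\ts2.1", "g1\t20\t20.4\t21",
                "g2\t22\tNA\t23"), wide)
  ct3 <- readCtTable(wide, dp)
  expect_identical(dim(ct3), c(2L, 3L))
  expect_true(is.na(SummarizedExperiment::assay(ct3)["g2", "s1.2"]))
})

test_that("Ct bounds and duplicate wells are rejected with coordinates", {
  dp <- withr::local_tempfile(fileext = ".tsv")
  write_lines(c("sample_id\torgan\tstage\treplicate", "s1\troot\tLP\t1"), dp)
  bad <- withr::local_tempfile(fileext = ".tsv")
  write_lines(c("gene\ts1.1", "g1\t-1"), bad)
  expect_error(readCtTable(bad, dp), "outside \\(0, 50\\).*g1.*s1\\.1")

  dup <- withr::local_tempfile(fileext = ".tsv")
  write_lines(c("gene\tsample_id\treplicate\tct",
                "g1\ts1\t1\t20", "g1\ts1\t1\t21"), dup)
  expect_error(readCtTable(dup, dp), "duplicate well.*g1")
})

test_that("collapseReplicates averages per sample and is idempotent", {
  d <- tiny_design(2)
  m <- matrix(c(20.0, 20.2, 20.4, 20.0, 20.0, 35.0), nrow = 1,
              dimnames = list("g1", c("s1.1", "s1.2", "s1.3",
                                      "s2.1", "s2.2", "s2.3")))
  ct <- CtTable(m, d)
  mean_c <- collapseReplicates(ct, "mean")
  expect_equal(unname(SummarizedExperiment::assay(mean_c)["g1", ]),
               c(20.2, 25.0))
  med_c <- collapseReplicates(ct, "median")
  expect_equal(unname(SummarizedExperiment::assay(med_c)["g1", "s2"]), 20.0)

  # single replicate: identity under both rules
  single <- CtTable(matrix(21.3, 1, 1, dimnames = list("g1", "s1")),
                    tiny_design(1))
  for (meth in c("mean", "median"))
    expect_equal(unname(SummarizedExperiment::assay(
      collapseReplicates(single, meth))[1, 1]), 21.3)

  twice <- collapseReplicates(mean_c, "mean")
  expect_equal(SummarizedExperiment::assay(twice),
               SummarizedExperiment::assay(mean_c))
})

test_that("missing cells stay missing through collapse; Ct round-trip", {
  d <- tiny_design(2)
  m <- matrix(c(NA, NA, 20, 21), nrow = 1,
              dimnames = list("g1", c("s1.1", "s1.2", "s2.1", "s2.2")))
  ct <- CtTable(m, d)
  cc <- collapseReplicates(ct)
  expect_true(is.na(SummarizedExperiment::assay(cc)["g1", "s1"]))
  expect_equal(unname(SummarizedExperiment::assay(cc)["g1", "s2"]), 20.5)

  mp <- withr::local_tempfile(fileext = ".tsv")
  dp <- withr::local_tempfile(fileext = ".tsv")
  ep <- withr::local_tempfile(fileext = ".tsv")
  writeCtTable(ct, mp, dp, ep)
  ct2 <- readCtTable(mp, dp, ep)
  expect_equal(SummarizedExperiment::assay(ct2),
               SummarizedExperiment::assay(ct), tolerance = 1e-12)
})

test_that("CtTable validity enforces efficiency range and design match", {
  d <- tiny_design(2)
  m <- matrix(c(20, 21), 1, dimnames = list("g1", c("s1", "s2")))
  expect_error(CtTable(m, d, efficiency = 1.0), "efficiency")
  expect_error(CtTable(m, d, efficiency = 2.5), "efficiency")
  expect_error(CtTable(m, d[1, ], efficiency = 2), "absent from design")
  expect_error(ExpressionTable(matrix(-1, 1, 1,
                                      dimnames = list("g1", "s1")),
                               tiny_design(1)), "non-negative")
})
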