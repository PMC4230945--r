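# NormFinder-style model: sample centering, bias-corrected intra-group
# variances, zero-sum inter-group differences with shrinkage, stability.

test_that("sampleCenter subtracts column means and needs >= 3 genes", {
  y <- cbind(c(20, 22, 24), c(5, 5, 5))
  z <- sampleCenter(y)
  expect_equal(z[, 1], c(-2, 0, 2))
  expect_equal(z[, 2], c(0, 0, 0))
  set.seed(8)
  z2 <- sampleCenter(matrix(rnorm(40), 5, 8))
  expect_equal(unname(colSums(z2)), rep(0, 8), tolerance = 1e-12)
  expect_error(sampleCenter(matrix(1, 2, 4)), "at least 3 genes")
})

test_that("intra-group variance estimator: degenerate and constant cases", {
  z <- sampleCenter(matrix(rep(c(1, 2, 3), 4), 3, 4))
  g2 <- intragroupVariances(z, rep("a", 4))
  expect_equal(unname(g2[, 1]), rep(0, 3))
  expect_error(intragroupVariances(matrix(0, 2, 4), rep("a", 4)),
               "at least 3 genes")
  expect_error(intragroupVariances(sampleCenter(matrix(rnorm(9), 3, 3)),
                                   c("a", "a", "b")),
               "fewer than 2 samples")
})

test_that("variance estimator is unbiased under the generating model", {
  # n = 3 genes with equal true variance sigma^2: the centering-bias
  # correction must recover sigma^2 in expectation (Monte Carlo)
  set.seed(123)
  sigma2 <- 0.04
  reps <- 10000
  est <- numeric(reps)
  for (i in seq_len(reps)) {
    y <- matrix(rnorm(3 * 6, 0, sqrt(sigma2)), 3, 6)
    g2 <- intragroupVariances(sampleCenter(y), rep("a", 6), floor = FALSE)
    est[i] <- mean(g2)
  }
  expect_lt(abs(mean(est) - sigma2) / sigma2, 0.02)
  # the floored (reported) version can only sit above the raw estimate
  yy <- matrix(rnorm(3 * 6, 0, sqrt(sigma2)), 3, 6)
  expect_true(all(intragroupVariances(sampleCenter(yy), rep("a", 6)) >=
                    intragroupVariances(sampleCenter(yy), rep("a", 6),
                                        floor = FALSE)))
})

test_that("inter-group differences are zero-sum and shrink sensibly", {
  set.seed(21)
  n <- 8; K <- 20
  groups <- rep(c("A", "B", "C"), each = K)
  y <- matrix(rnorm(n * 3 * K, 0, 0.1), n, 3 * K)
  y[1, groups == "A"] <- y[1, groups == "A"] + 0.5   # planted offset
  z <- sampleCenter(y)
  ig <- intergroupVariation(z, groups)
  expect_equal(unname(rowSums(ig$d_hat)), rep(0, n), tolerance = 1e-10)
  # offset gene's difference pattern ~ (2/3, -1/3, -1/3) * 0.5 * (1 - 1/n)
  expect_equal(unname(ig$d_hat[1, "A"]), 0.5 * (1 - 1/n) * 2/3,
               tolerance = 0.05)
  # identical group means -> d = 0 (both raw and shrunk)
  z0 <- sampleCenter(matrix(rep(c(1, 2, 3, 4), 6), 4, 6))
  ig0 <- intergroupVariation(z0, rep(c("A", "B"), each = 3))
  expect_equal(unname(ig0$d_hat), matrix(0, 4, 2), ignore_attr = TRUE)
  expect_equal(ig0$d_tilde, ig0$d_hat)
  expect_error(intergroupVariation(z0, rep("A", 6)), "at least 2 groups")
})

test_that("no shrinkage when intra-group variance is zero", {
  # deterministic rows: within-group variance 0, clear group separation
  y <- rbind(g1 = c(0, 0, 0, 1, 1, 1),
             g2 = c(2, 2, 2, 2, 2, 2),
             g3 = c(1, 1, 1, 0, 0, 0))
  z <- sampleCenter(y)
  ig <- intergroupVariation(z, rep(c("A", "B"), each = 3))
  expect_equal(ig$d_tilde, ig$d_hat, tolerance = 1e-12)
})

test_that("stability: proportional genes score 0; shifts change nothing", {
  y <- rbind(g1 = c(20, 21, 22, 23), g2 = c(18, 19, 20, 21),
             g3 = c(25, 26, 27, 28))
  nf <- normFinder(y)
  expect_equal(unname(stability(nf)), rep(0, 3), tolerance = 1e-12)

  set.seed(31)
  y2 <- matrix(rnorm(5 * 12, 20, 0.3), 5, 12,
               dimnames = list(paste0("g", 1:5), NULL))
  shifted <- y2; shifted[3, ] <- shifted[3, ] + 3.7
  a <- normFinder(y2, groups = rep(c("A", "B"), each = 6))
  b <- normFinder(shifted, groups = rep(c("A", "B"), each = 6))
  expect_equal(stability(a), stability(b), tolerance = 1e-10)
  expect_identical(geneRanking(a), geneRanking(b))
})

test_that("grouped and ungrouped modes expose the documented fields", {
  tr <- defaultSimTruth(seed = 12)
  ct <- collapseReplicates(simulateCt(tr))
  g <- normFinder(ct, groups = "organ")
  expect_identical(g@mode, "grouped")
  expect_identical(colnames(g@gamma2), c("leaf", "root", "stem"))
  expect_equal(unname(rowSums(g@dHat)), rep(0, nrow(ct)), tolerance = 1e-10)
  expect_true(all(g@gamma2 >= 0))
  u <- normFinder(ct)
  expect_identical(u@mode, "ungrouped")
  expect_identical(dim(u@dHat), c(0L, 0L))
  expect_true(all(stability(u) >= 0))
})

test_that("planted gamma^2 grid is recovered with small median bias", {
  set.seed(77)
  for (g2 in c(0.1, 0.5)) {
    rel <- numeric(60)
    for (i in seq_len(60)) {
      y <- matrix(rnorm(10 * 50, 0, sqrt(g2)), 10, 50)
      est <- intragroupVariances(sampleCenter(y), rep("a", 50))
      rel[i] <- median(est / g2 - 1)
    }
    expect_lt(abs(median(rel)), 0.05)
  }
})

test_that("rank agreement with geNorm on a clear stability gradient", {
  set.seed(55)
  gamma <- seq(0.05, 0.6, length.out = 8)
  tr <- simTruth(paste0("g", 1:8), log2SD = gamma, sampleSD = 0.05,
                 repSD = 0.05, seed = 55)
  ct <- collapseReplicates(simulateCt(tr))
  gn_rank <- match(paste0("g", 1:8), geNorm(ct)@ranking)
  nf_rank <- match(paste0("g", 1:8), normFinder(ct)@ranking)
  expect_gte(cor(gn_rank, nf_rank, method = "spearman"), 0.8)
})
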