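# geNorm: Ct -> quantity transform, pairwise stability, M values,
# stepwise exclusion, normalization factors and the V(n/n+1) series.

test_that("ctToQuantity applies Q = E^(minCt - Ct) and flags bad input", {
  ct <- make_ct(matrix(c(20, 21, 23), 1,
                       dimnames = list("g1", c("s1", "s2", "s3"))))
  expect_equal(unname(quantities(ctToQuantity(ct))[1, ]), c(1, 0.5, 0.125))

  ct19 <- make_ct(matrix(c(20, 21), 1, dimnames = list("g1", NULL)),
                  efficiency = 1.9)
  expect_equal(unname(quantities(ctToQuantity(ct19))[1, ]),
               c(1, 1 / 1.9), tolerance = 1e-9)

  const <- make_ct(matrix(22, 1, 4))
  expect_equal(unname(quantities(ctToQuantity(const))[1, ]), rep(1, 4))

  # incomplete genes are dropped with a warning; all-missing is an error
  m <- matrix(c(20, NA, 21, 22, 20, 21), 3, 2, byrow = TRUE)
  expect_warning(q <- ctToQuantity(make_ct(m)), "missing")
  expect_identical(rownames(quantities(q)), c("g2", "g3"))
  m[1, ] <- NA
  expect_warning(expect_error(ctToQuantity(make_ct(m)), "no Ct values"), NA)
})

test_that("pairwise stability and M values match the worked 3-gene case", {
  # g1 = (1,2,4), g2 = 2*g1 (proportional), g3 constant
  q <- make_q(matrix(c(1, 2, 4, 2, 4, 8, 1, 1, 1), 3, byrow = TRUE))
  V <- pairwiseStability(q)
  expect_equal(V["g1", "g2"], 0)
  expect_equal(V["g1", "g3"], 1)        # SD(0, 1, 2)
  expect_equal(V, t(V))
  expect_equal(unname(diag(V)), rep(0, 3))
  expect_equal(unname(mValues(q)), c(0.5, 0.5, 1.0))
  # with two active genes both M equal their pairwise V
  expect_equal(unname(mValues(q, c("g1", "g3"))), c(1, 1))
  expect_error(mValues(q, "g1"), "at least 2")
})

test_that("M is invariant to per-gene rescaling and Ct shifts", {
  set.seed(10)
  m <- matrix(20 + rnorm(20, 0, 0.5), 4, 5)
  ct <- make_ct(m)
  m_shift <- m
  m_shift[2, ] <- m_shift[2, ] + 3.7
  ct2 <- make_ct(m_shift)
  expect_equal(mValues(ctToQuantity(ct)), mValues(ctToQuantity(ct2)),
               tolerance = 1e-10)
  g1 <- geNorm(ct)
  g2 <- geNorm(ct2)
  expect_identical(g1@ranking, g2@ranking)
  expect_equal(g1@vSeries$v, g2@vSeries$v, tolerance = 1e-10)
})

test_that("stepwise exclusion removes the noisy gene first", {
  set.seed(1)
  wins <- 0
  for (i in 1:50) {
    base <- 20 + rnorm(8, 0, 0.05)
    m <- rbind(g1 = base, g2 = base + 1, g3 = base - 2,
               g4 = base + rnorm(8, 0, 1))
    res <- geNorm(make_ct(m))
    if (res@exclusionOrder[1] == "g4") wins <- wins + 1
    expect_true(all(res@stablePair %in% c("g1", "g2", "g3")))
    # exclusion order is a permutation; final pair shares its M
    expect_setequal(c(res@exclusionOrder, res@stablePair), rownames(m))
    expect_equal(res@stability[res@stablePair[1]],
                 res@stability[res@stablePair[2]], ignore_attr = TRUE)
  }
  expect_gte(wins, 48)
})

test_that("proportional genes give all-zero M and V with tie-break order", {
  base <- c(20, 21, 22, 23)
  m <- rbind(g1 = base, g2 = base + 1, g3 = base - 0.5)
  res <- geNorm(make_ct(m))
  expect_equal(unname(res@stability), rep(0, 3))
  expect_equal(res@vSeries$v, 0)
  # tie-break: later input order excluded first
  expect_identical(res@exclusionOrder, "g3")
  expect_identical(res@stablePair, c("g1", "g2"))
})

test_that("normalization factors follow the geometric-mean definition", {
  q <- make_q(matrix(c(1, 0.5, 1, 0.125, 0.25, 1), 3, 2, byrow = TRUE,
                     dimnames = list(c("g1", "g2", "g3"), c("s1", "s2"))))
  expect_equal(normalizationFactor(q, "g1"), quantities(q)["g1", ])
  # pair (1, 4) in quantity space -> geometric mean 2 (up to rescale: here
  # quantities 1 and 0.25 give sqrt(0.25) = 0.5)
  expect_equal(unname(normalizationFactor(q, c("g1", "g3"))[1]),
               sqrt(1 * 0.25))
  expect_equal(normalizationFactor(q, c("g1", "g2", "g1")),
               normalizationFactor(q, c("g1", "g2")))
})

test_that("V series: proportional third gene gives V2/3 = 0", {
  set.seed(4)
  base <- c(20, 21, 19, 22)
  m <- rbind(g1 = base, g2 = base + 2, g3 = base - 1,
             g4 = base + rnorm(4, 0, 0.3))
  res <- geNorm(make_ct(m))
  expect_equal(res@vSeries$v[1], 0, tolerance = 1e-12)
  expect_identical(res@recommendedN, 2L)
})

test_that("M, NF and V match the brute-force oracle on random cases", {
  set.seed(2024)
  for (i in 1:60) {
    G <- sample(3:6, 1)
    S <- sample(3:8, 1)
    ct <- make_ct(matrix(20 + rnorm(G * S, 0, 0.8), G, S))
    q <- ctToQuantity(ct)
    Q <- quantities(q)
    expect_equal(mValues(q), oracle_m_values(Q), tolerance = 1e-10)
    res <- geNorm(ct)
    ref <- oracle_stepwise(Q)
    expect_identical(res@exclusionOrder, ref$excluded)
    expect_setequal(res@stablePair, ref$pair)
    expect_equal(res@vSeries$v, oracle_v_series(Q, res@ranking),
                 tolerance = 1e-10)
    genes <- sample(rownames(Q), sample(2:G, 1))
    expect_equal(unname(normalizationFactor(q, genes)),
                 oracle_nf(Q, genes), tolerance = 1e-10)
  }
})

test_that("each round's removed gene had the maximal M of that round", {
  set.seed(99)
  ct <- make_ct(matrix(20 + rnorm(6 * 8, 0, 0.6), 6, 8))
  q <- ctToQuantity(ct)
  res <- geNorm(ct)
  active <- rownames(quantities(q))
  for (g in res@exclusionOrder) {
    M <- oracle_m_values(quantities(q), active)
    expect_equal(unname(M[g]), max(M), tolerance = 1e-12)
    active <- setdiff(active, g)
  }
})
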