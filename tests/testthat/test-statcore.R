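test_that("welchTTest agrees with the reference t-distribution oracle", {
  # hand-checked case: equal variances 0.01, se = sqrt(0.02/3), df = 4
  r <- welchTTest(c(0.1, 0.2, 0.3), c(0.5, 0.6, 0.7))
  expect_equal(r$t_stat, -0.4 / sqrt(0.02 / 3), tolerance = 1e-12)
  expect_equal(r$df, 4, tolerance = 1e-12)
  expect_equal(r$p_value, 2 * pt(-abs(r$t_stat), 4), tolerance = 1e-12)
  expect_equal(r$delta, r$mean_a - r$mean_b)

  set.seed(11)
  for (i in 1:200) {
    na <- sample(2:15, 1); nb <- sample(2:15, 1)
    a <- rnorm(na, sd = runif(1, 0.1, 3))
    b <- rnorm(nb, mean = runif(1, -1, 1), sd = runif(1, 0.1, 3))
    r <- welchTTest(a, b)
    ref <- t.test(a, b)
    expect_equal(r$t_stat, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(r$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(r$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("welchTTest symmetry, degenerate groups and input errors", {
  a <- c(0.1, 0.4, 0.9, 0.3); b <- c(0.2, 0.25, 0.5)
  r1 <- welchTTest(a, b); r2 <- welchTTest(b, a)
  expect_equal(r1$t_stat, -r2$t_stat)
  expect_equal(r1$delta, -r2$delta)
  expect_equal(r1$p_value, r2$p_value)

  # equal constant groups: no evidence, never NaN
  r <- welchTTest(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5))
  expect_equal(r$t_stat, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$delta, 0)
  # distinct constant groups: infinite evidence in the zero-variance limit
  r <- welchTTest(c(1, 1), c(2, 2))
  expect_true(is.infinite(r$t_stat) && r$t_stat < 0)
  expect_equal(r$p_value, 0)

  # Welch reduces to Student under equal n and equal variance
  a <- rnorm(8); b <- a + 0.7
  expect_equal(welchTTest(a, b)$t_stat,
               unname(t.test(a, b, var.equal = TRUE)$statistic),
               tolerance = 1e-10)

  expect_error(welchTTest(1, c(1, 2)), "at least 2")
  expect_error(welchTTest(c(1, NA, 2), c(1, 2)), "missing")
})

test_that("bhAdjust reproduces step-up q-values and is permutation-equivariant", {
  expect_equal(bhAdjust(0.05), 0.05)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(c(1, 1)), c(1, 1))
  set.seed(3)
  p <- runif(50)^2
  perm <- sample(50)
  expect_equal(bhAdjust(p)[perm], bhAdjust(p[perm]))
  expect_equal(max(bhAdjust(p)), max(p))
  expect_true(all(bhAdjust(p) >= 0 & bhAdjust(p) <= 1))
  expect_error(bhAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bhAdjust(c(-0.1)), "\\[0, 1\\]")
})

test_that("hypergeomUpperTail equals brute-force enumeration and is monotone", {
  expect_equal(hypergeomUpperTail(10, 5, 5, 0), 1)
  expect_equal(hypergeomUpperTail(10, 5, 5, 5), 1 / 252, tolerance = 1e-12)
  set.seed(7)
  for (i in 1:300) {
    N <- sample(1:30, 1)
    K <- sample(0:N, 1)
    m <- sample(0:N, 1)
    k <- sample(0:min(K, m), 1)
    expect_equal(hypergeomUpperTail(N, K, m, k), bruteUpperTail(N, K, m, k),
                 tolerance = 1e-12)
  }
  p7 <- hypergeomUpperTail(17450, 89, 366, 7)
  p6 <- hypergeomUpperTail(17450, 89, 366, 6)
  expect_true(p7 > 0 && p7 < 1 && p7 < p6)
  expect_error(hypergeomUpperTail(10, 11, 5, 2))
  expect_error(hypergeomUpperTail(10, 5, 5, 6))
})

test_that("fold enrichment is cross-consistent over the published pathway table", {
  # background size implied by the rheumatoid-arthritis pathway row
  rows <- data.frame(k = c(7, 13, 16, 6, 10),
                     K = c(89, 129, 248, 67, 139),
                     fold = c(3.75, 4.80, 3.08, 4.27, 3.43))
  m <- 366
  N_ra <- rows$fold[1] * rows$K[1] * m / rows$k[1]
  expect_equal(round(N_ra), 17450)
  for (i in 2:5)
    expect_equal(round(foldEnrichment(round(N_ra), rows$K[i], m, rows$k[i]), 2),
                 rows$fold[i])
  # anchoring on the cell-adhesion row instead recovers the first row's fold
  N_cam <- rows$fold[2] * rows$K[2] * m / rows$k[2]
  expect_equal(round(foldEnrichment(round(N_cam), rows$K[1], m, rows$k[1]), 2),
               rows$fold[1])

  expect_equal(foldEnrichment(100, 10, 20, 2), 1)  # k/m == K/N
  expect_error(foldEnrichment(100, 0, 20, 0), "positive")
})
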