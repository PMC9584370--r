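test_that("median and quartiles match the order-statistic oracle", {
  m <- median_iqr(c(1, 2, 3, 4, 5))
  expect_equal(c(m$median, m$q1, m$q3), c(3, 2, 4))
  m1 <- median_iqr(7.3)
  expect_equal(c(m1$median, m1$q1, m1$q3), rep(7.3, 3))

  set.seed(19)
  x <- rlnorm(1000, log(900), 0.4)
  m2 <- median_iqr(x)
  o <- oracle_quartiles(x)
  expect_equal(m2$q1, unname(o["q1"]))
  expect_equal(m2$median, unname(o["med"]))
  expect_equal(m2$q3, unname(o["q3"]))

  expect_error(median_iqr(numeric(0)), class = "bq_input")
  expect_error(median_iqr(c(NA, NaN)), class = "bq_input")
})

test_that("Mann-Whitney p equals full enumeration on small tie-free samples", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p, 2 / 6)
  expect_identical(r$method, "exact")

  set.seed(23)
  for (case in 1:8) {
    na <- sample(2:5, 1)
    nb <- sample(2:4, 1)
    vals <- sample(100, na + nb)   # no ties
    a <- vals[1:na]; b <- vals[-(1:na)]
    expect_equal(mann_whitney(a, b)$p, oracle_mw_p(a, b), tolerance = 1e-12)
  }

  expect_warning(rd <- mann_whitney(rep(2, 4), rep(2, 5)), "identical")
  expect_equal(rd$p, 1)
  # identical samples (with internal spread): no separation, p = 1
  same <- c(1, 5, 9)
  expect_equal(mann_whitney(same, same)$p, 1)
  expect_error(mann_whitney(numeric(0), 1:3), class = "bq_input")
})

test_that("Fisher exact p equals hypergeometric enumeration and respects symmetry", {
  tab <- matrix(c(10, 6, 2, 12), 2)  # restriction counts by group
  r <- fisher_exact(tab)
  expect_equal(r$p, oracle_fisher_p(tab), tolerance = 1e-12)
  expect_lt(r$p, 0.05)

  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2))$p, 1)

  set.seed(31)
  for (case in 1:6) {
    t2 <- matrix(rpois(4, 6), 2)
    p0 <- fisher_exact(t2)$p
    expect_equal(p0, oracle_fisher_p(t2), tolerance = 1e-12)
    expect_equal(fisher_exact(t2[2:1, ])$p, p0, tolerance = 1e-12)
    expect_equal(fisher_exact(t2[, 2:1])$p, p0, tolerance = 1e-12)
  }
  expect_error(fisher_exact(matrix(c(-1, 2, 3, 4), 2)), class = "bq_input")
})

test_that("t-test behaves at the null, detects separation, validates input", {
  r0 <- unpaired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)

  set.seed(37)
  r1 <- unpaired_t(c(0, 0) + rnorm(2, sd = 1e-6), c(1, 1) + rnorm(2, sd = 1e-6))
  expect_lt(r1$p, 0.05)

  # oracle: closed-form pooled t CDF
  a <- c(4.1, 5.2, 6.3, 3.9)
  b <- c(7.7, 8.1, 6.9)
  r2 <- unpaired_t(a, b)
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  tman <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  expect_equal(r2$t, tman)
  expect_equal(r2$p, 2 * pt(-abs(tman), length(a) + length(b) - 2))

  expect_error(unpaired_t(rep(1, 3), rep(2, 3)), class = "bq_degenerate")
  expect_error(unpaired_t(1, 1:3), class = "bq_input")
})

test_that("Spearman rho and exact small-n p match the permutation oracle", {
  r <- spearman_cor(1:6, c(2, 4, 5, 7, 10, 11))
  expect_equal(r$rho, 1)

  # binary group against continuous outcome: positive direction
  x <- c(rep(1, 5), rep(0, 6))
  y <- c(10, 12, 9, 14, 11, 3, 5, 2, 4, 6, 1)
  expect_gt(spearman_cor(x, y)$rho, 0)

  set.seed(41)
  xs <- rnorm(7); ys <- rnorm(7)
  r7 <- spearman_cor(xs, ys)
  expect_identical(r7$method, "exact_permutation")
  expect_equal(r7$p, oracle_spearman_p(xs, ys), tolerance = 1e-12)

  # ties present: permutation null still valid and matches oracle
  xt <- c(1, 1, 2, 3, 3, 4)
  yt <- rnorm(6)
  expect_equal(spearman_cor(xt, yt)$p, oracle_spearman_p(xt, yt),
               tolerance = 1e-12)

  expect_error(spearman_cor(rep(1, 5), rnorm(5)), class = "bq_degenerate")
  expect_error(spearman_cor(1:4, 1:5), class = "bq_input")
})
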