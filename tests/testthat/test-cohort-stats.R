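test_that("pooled t works from summaries and from raw data alike", {
  set.seed(1)
  x <- rnorm(15, 1)
  y <- rnorm(12, 0)
  raw <- pooled_t(x, y)
  summ <- pooled_t(mean1 = mean(x), sd1 = sd(x), n1 = 15,
                   mean2 = mean(y), sd2 = sd(y), n2 = 12)
  expect_equal(raw$t, summ$t)
  expect_equal(raw$df, 25)
  expect_equal(raw$t, hand_pooled_t(mean(x), sd(x), 15, mean(y), sd(y), 12))
  # agrees with the standard equal-variance t test
  expect_equal(raw$p, t.test(x, y, var.equal = TRUE)$p.value)
  same <- pooled_t(mean1 = 2, sd1 = 1, n1 = 10, mean2 = 2, sd2 = 1, n2 = 10)
  expect_equal(same$t, 0)
  expect_error(pooled_t(mean1 = 1, sd1 = 1, n1 = 1,
                        mean2 = 0, sd2 = 1, n2 = 5), "at least 2")
})

test_that("Mann-Whitney U matches all-pairs counting and handles ties", {
  set.seed(2)
  for (i in 1:10) {
    x <- sample(0:5, sample(3:8, 1), replace = TRUE)
    y <- sample(0:5, sample(3:8, 1), replace = TRUE)
    res <- mann_whitney_u(x, y)
    expect_equal(res$U, all_pairs_u(x, y))
    expect_equal(res$U1 + res$U2, length(x) * length(y))
  }
  tied <- mann_whitney_u(rep(3, 4), rep(3, 5))
  expect_equal(tied$U, 4 * 5 / 2)
  # exact p agrees with the reference implementation when tie-free
  x <- c(1.2, 3.4, 2.2, 5.1)
  y <- c(0.4, 2.9, 1.9, 4.4, 6.0)
  expect_equal(mann_whitney_u(x, y)$p,
               wilcox.test(x, y, exact = TRUE)$p.value)
  # complete separation pins U at zero
  expect_equal(mann_whitney_u(rep(5, 23),
                              c(rep(0, 5), rep(1, 3), rep(2, 3), 3, 4))$U, 0)
})

test_that("partial correlation reduces correctly in degenerate cases", {
  set.seed(3)
  x <- rnorm(40)
  y <- 0.5 * x + rnorm(40, 0, 0.5)
  z <- rnorm(40)
  expect_equal(partial_corr(x, x, z)$estimate, 1)
  # constant covariate changes nothing but the df bookkeeping
  simple <- partial_corr(x, y)
  noop <- partial_corr(x, y, covariates = rep(2, 40))
  expect_equal(noop$estimate, simple$estimate)
  expect_equal(simple$df, 38)
  expect_equal(noop$df, 37)
  expect_error(partial_corr(rep(1, 40), y, z), "constant")
  expect_error(partial_corr(x[1:3], y[1:3], cbind(z[1:3], z[1:3])), "covariates")
})

test_that("partial correlation recovers the closed-form Gaussian value", {
  rxz <- 0.6; ryz <- 0.5; rxy <- 0.62
  sig <- matrix(c(1, rxy, rxz, rxy, 1, ryz, rxz, ryz, 1), 3)
  truth <- closed_form_partial(rxy, rxz, ryz)
  set.seed(4)
  d <- MASS::mvrnorm(5000, rep(0, 3), sig)
  est <- partial_corr(d[, 1], d[, 2], d[, 3])$estimate
  expect_lt(abs(est - truth), 0.03)
})

test_that("rank-based partial correlation ignores monotone transforms", {
  set.seed(5)
  sig <- matrix(c(1, 0.5, 0.3, 0.5, 1, 0.4, 0.3, 0.4, 1), 3)
  d <- MASS::mvrnorm(300, rep(0, 3), sig)
  a <- partial_corr(d[, 1], d[, 2], d[, 3], method = "spearman")
  b <- partial_corr(exp(d[, 1]), d[, 2]^3, d[, 3], method = "spearman")
  expect_equal(a$estimate, b$estimate)
  expect_true(abs(a$estimate) <= 1)
})

test_that("one-tailed p splits the two-tailed value directionally", {
  set.seed(6)
  x <- rnorm(30)
  y <- x + rnorm(30)
  z <- rnorm(30)
  two <- partial_corr(x, y, z)
  gt <- partial_corr(x, y, z, alternative = "greater")
  lt <- partial_corr(x, y, z, alternative = "less")
  expect_equal(gt$p.value + lt$p.value, 1)
  expect_equal(min(gt$p.value, lt$p.value) * 2, two$p.value)
})

test_that("normality routing sends clean Gaussians to the t test", {
  set.seed(7)
  r <- route_test(rnorm(60), rnorm(60))
  expect_equal(r$route, "parametric")
  # heavy skew at n = 50 is reliably caught
  nonpar <- sum(vapply(1:30, function(i) {
    route_test(rexp(50), rexp(50))$route == "nonparametric"
  }, logical(1)))
  expect_gte(nonpar, 29)
  tiny <- route_test(c(1, 2), rnorm(10))
  expect_equal(tiny$route, "nonparametric")
  expect_false(is.na(tiny$flag))
})

test_that("2x2 chi-square follows the standard formula without correction", {
  prop <- matrix(c(10, 20, 5, 10), 2)  # proportional rows
  expect_equal(chi_square_2x2(prop)$chisq, 0)
  tab <- matrix(c(10, 8, 13, 7), 2, byrow = FALSE)
  # hand computation: N (ad-bc)^2 / (row and column marginals)
  byhand <- 38 * (10 * 7 - 13 * 8)^2 / (23 * 15 * 18 * 20)
  res <- chi_square_2x2(tab)
  expect_equal(res$chisq, byhand)
  expect_equal(res$df, 1)
  expect_equal(chi_square_2x2(tab[2:1, ])$chisq, res$chisq)
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2)), "marginal")
})

test_that("stepwise regression honours exact and dominant relationships", {
  set.seed(8)
  n <- 120
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
  dat <- data.frame(y = x1, x1 = x1, x2 = x2, x3 = x3)
  # an exact fit makes lm's summary warn about perfect residuals; expected here
  fit <- suppressWarnings(stepwise_forward(dat, "y", c("x1", "x2", "x3")))
  expect_equal(fit$selected, "x1")
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$coefficients$beta_std, 1)

  dat2 <- data.frame(y = 0.8 * x1 + rnorm(n, 0, 0.5),
                     x1 = x1, x2 = x2, x3 = x3, x4 = rnorm(n))
  fit2 <- stepwise_forward(dat2, "y", c("x1", "x2", "x3", "x4"))
  expect_true("x1" %in% fit2$selected)
  expect_equal(nrow(fit2$excluded) + nrow(fit2$coefficients), 4)
  expect_true(all(fit2$excluded$term != "x1"))
})

test_that("stepwise rejects collinear candidate sets by name", {
  set.seed(9)
  x <- rnorm(50)
  dat <- data.frame(y = rnorm(50), a = x, b = x, c = rnorm(50))
  expect_error(stepwise_forward(dat, "y", c("a", "b", "c")), "a and b")
})

test_that("pure-noise candidates rarely enter the model", {
  set.seed(10)
  hits <- vapply(1:60, function(i) {
    dat <- data.frame(y = rnorm(100), a = rnorm(100), b = rnorm(100))
    length(stepwise_forward(dat, "y", c("a", "b"))$selected) > 0
  }, logical(1))
  # each candidate enters with prob ~ entry_p; two candidates -> ~10 %
  expect_lt(mean(hits), 0.35)
})
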