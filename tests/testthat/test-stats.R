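# Statistical layer: scaling, NB regression, LRT, nonparametric tests,
# eCDF comparison and the cross-correlation screen.

test_that("min-max scaling maps to [0,1] and rejects constants", {
  expect_equal(minmax_scale(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(minmax_scale(c(0, 1)), c(0, 1))
  expect_error(minmax_scale(c(5, 5, 5), "rsa"), "rsa")
})

test_that("intercept-only NB fit recovers the sample mean", {
  set.seed(1)
  y <- rnbinom(400, mu = 6, size = 1.3)
  fit <- fit_negative_binomial(data.frame(x = numeric(400))[, 0], y)
  expect_equal(unname(exp(fit$coefficients[1])), mean(y), tolerance = 1e-6)
  expect_error(fit_negative_binomial(data.frame(x = runif(5)), rep(0, 5)),
               "all scores are zero")
  expect_error(fit_negative_binomial(data.frame(x = runif(5)),
                                     c(1.5, 2, 1, 0, 3)), "integers")
})

test_that("simulated covariate effects are recovered within Wald bands", {
  set.seed(101)
  n <- 2000
  x <- runif(n)
  y <- rnbinom(n, mu = exp(0.5 + 2 * x), size = 1.5)
  fit <- fit_negative_binomial(data.frame(x = x), y)
  est <- fit$coefficients["x"]; se <- fit$standard_errors["x"]
  expect_lt(abs(est - 2), 1.96 * se)
  expect_equal(unname(fit$dispersion), 1.5, tolerance = 0.25)
  expect_lt(fit$lrt_p, 1e-6)
})

test_that("likelihood-ratio test reduces to the chi-square tail", {
  expect_equal(pchisq(3.84, df = 1, lower.tail = FALSE), 0.05,
               tolerance = 0.005)
  set.seed(7)
  y <- rnbinom(300, mu = 5, size = 1)
  x <- runif(300)  # no effect: statistic ~ chi-square_1, p well above 0
  fit <- fit_negative_binomial(data.frame(x = x), y)
  expect_gte(fit$loglik, fit$loglik_null)
  expect_equal(likelihood_ratio_test(fit),
               pchisq(2 * (fit$loglik - fit$loglik_null), 1,
                      lower.tail = FALSE))
})

test_that("Kruskal-Wallis handles identical groups, separation and ties", {
  expect_equal(kruskal_wallis(list(c(2, 2), c(2, 2)))$H, 0)
  expect_equal(kruskal_wallis(list(c(2, 2), c(2, 2)))$p, 1)
  sep <- kruskal_wallis(list(c(1, 2, 3), c(101, 102, 103)))
  # maximum separation for n = 6, k = 2: H = 12/(n(n+1)) * sep - 3(n+1)
  expect_equal(sep$H, oracle_kw_H(list(c(1, 2, 3), c(101, 102, 103))))
  set.seed(13)
  for (r in 1:10) {
    g <- list(sample(1:5, 7, TRUE), sample(1:5, 9, TRUE),
              sample(1:5, 6, TRUE))
    if (length(unique(unlist(g))) == 1L) next
    expect_equal(kruskal_wallis(g)$H, oracle_kw_H(g), tolerance = 1e-10)
  }
})

test_that("Mann-Whitney exact p matches full enumeration on tiny samples", {
  expect_equal(mann_whitney(c(1, 2), c(3, 4)), 1 / 3, tolerance = 1e-10)
  expect_equal(mann_whitney(c(1, 2), c(3, 4)),
               oracle_mwu_exact(c(1, 2), c(3, 4)))
  set.seed(19)
  for (r in 1:10) {
    a <- runif(sample(2:5, 1)); b <- runif(sample(2:5, 1))
    expect_equal(mann_whitney(a, b), oracle_mwu_exact(a, b),
                 tolerance = 1e-10)
  }
  # identical groups in the pairwise matrix give p = 1
  p <- mann_whitney_pairwise(list(g1 = c(1, 2, 3), g2 = c(1, 2, 3)))
  expect_equal(p["g1", "g2"], 1)
  expect_lt(mann_whitney(rnorm(50), rnorm(50) + 10), 1e-15)
})

test_that("pairwise matrix is symmetric with unit diagonal", {
  set.seed(23)
  g <- list(a = rnorm(12), b = rnorm(10) + 1, c = rnorm(15) - 1)
  p <- mann_whitney_pairwise(g)
  expect_equal(p, t(p))
  expect_equal(diag(p), c(a = 1, b = 1, c = 1))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("eCDF correlation uses the union grid", {
  expect_equal(ecdf_correlation(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(ecdf(c(1, 2, 3))(2), 2 / 3)
  r <- ecdf_correlation(c(1, 2, 3), c(101, 102, 103))
  grid <- c(1, 2, 3, 101, 102, 103)
  ref <- cor(ecdf(c(1, 2, 3))(grid), ecdf(c(101, 102, 103))(grid))
  expect_equal(r, ref)
  expect_lt(r, 1)
})

test_that("cross-correlation screen drops later duplicated columns", {
  set.seed(31)
  X <- data.frame(a = rnorm(20))
  X$b <- 2 * X$a + 3        # |r| = 1 with a
  X$c <- rnorm(20)
  scr <- cross_correlation_screen(X)
  expect_equal(scr$dropped, "b")
  expect_equal(names(scr$X), c("a", "c"))
  expect_equal(abs(scr$correlation["a", "b"]), 1)
  none <- cross_correlation_screen(data.frame(a = c(1, 2, 3, 4),
                                              b = c(1, -1, 1, -1)))
  expect_length(none$dropped, 0)
  # strength duplicates degree under unit weights
  g <- build_rin(ca_structure(cbind(seq_len(10) * 3.8, 0, 0)))
  cent <- rin_centralities(g)
  scr2 <- cross_correlation_screen(cent[, c("degree", "strength",
                                            "closeness")])
  expect_equal(scr2$dropped, "strength")
  expect_equal(scr2$correlation["degree", "strength"], 1)
})

test_that("two-group Kruskal-Wallis agrees with Mann-Whitney significance", {
  set.seed(37)
  for (r in 1:10) {
    a <- rnorm(15); b <- rnorm(15) + r / 5
    kw <- kruskal_wallis(list(a, b))$p
    mw <- mann_whitney(a, b)
    expect_equal(kw < 0.05, mw < 0.05)
  }
})
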