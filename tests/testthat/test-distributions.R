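test_that("closed-form MLE for normal and lognormal uses population SD", {
  f <- fit_mle(c(1, 2, 3, 4, 5), "normal")
  expect_equal(unname(f$params), c(3, sqrt(2)), tolerance = 1e-12)
  expect_true(f$converged)

  x <- exp(c(-1, 0, 0.5, 1, 2))
  g <- fit_mle(x, "lognormal")
  lx <- log(x)
  expect_equal(unname(g$params),
               c(mean(lx), sqrt(mean((lx - mean(lx))^2))), tolerance = 1e-12)
})

test_that("degenerate and undersized samples are rejected", {
  expect_error(fit_mle(c(2, 2, 2), "normal"), "zero variance")
  expect_error(fit_mle(c(1, 2), "normal"), "at least 3")
  expect_error(fit_mle(c(-1, 1, 2), "weibull"), "non-negative")
  expect_warning(fit_mle(c(0, 0.5, 1, 1.5, 2), "weibull"), "dropped 1 zero")
})

test_that("MLE recovers generator parameters within 5% at n = 5000", {
  for (fam in names(recovery_truths)) {
    truth <- recovery_truths[[fam]]
    x <- sample_family(fitted_distribution(fam, truth), 5000,
                       seed = derive_seed(2024, fam))
    fit <- fit_mle(x, fam)
    expect_true(fit$converged, label = paste(fam, "converged"))
    rel <- abs(fit$params - truth) / abs(truth)
    expect_lt(max(rel), 0.05, label = paste(fam, "relative error"))
  }
})

test_that("iterative MLE agrees with fitdistrplus on the same data", {
  skip_if_not_installed("fitdistrplus")
  x <- sample_family(fitted_distribution("weibull", recovery_truths$weibull),
                     500, seed = 11)
  ours <- fit_mle(x, "weibull")
  ref <- fitdistrplus::fitdist(x, "weibull")
  expect_equal(unname(ours$params), unname(ref$estimate), tolerance = 1e-3)
  expect_equal(ours$loglik, ref$loglik, tolerance = 1e-6)

  y <- sample_family(fitted_distribution("logistic", recovery_truths$logistic),
                     500, seed = 12)
  ours2 <- fit_mle(y, "logistic")
  ref2 <- fitdistrplus::fitdist(y, "logis")
  expect_equal(unname(ours2$params), unname(ref2$estimate), tolerance = 1e-3)
  expect_equal(ours2$loglik, ref2$loglik, tolerance = 1e-6)
})

test_that("Anderson-Darling statistic matches the hand-evaluated sum", {
  expect_equal(anderson_darling_statistic(c(0.25, 0.5, 0.75), identity),
               0.26943, tolerance = 1e-5)
})

test_that("A-squared is a functional of the CDF values alone", {
  # samples placed at the exact (i - 0.5)/n quantiles of each family give
  # the same statistic for every family
  n <- 10
  u <- (seq_len(n) - 0.5) / n
  vals <- vapply(dist_families(), function(fam) {
    params <- recovery_truths[[fam]]
    anderson_darling_statistic(family_quantile(u, fam, params),
                               fitted_distribution(fam, params))
  }, numeric(1))
  expect_lt(diff(range(vals)), 1e-9)
})

test_that("pushing one tail observation outward strictly increases A-squared", {
  x <- c(0.05, 0.12, 0.23, 0.31, 0.42, 0.55, 0.61, 0.74, 0.86, 0.93)
  dist <- fitted_distribution("normal", c(location = 0.5, scale = 0.3))
  a <- vapply(c(1.2, 1.6, 2.0, 2.4), function(far) {
    anderson_darling_statistic(c(x[-10], far), dist)
  }, numeric(1))
  expect_true(all(diff(a) > 0))
})

test_that("A-squared is invariant under joint affine transforms", {
  x <- sample_family(fitted_distribution("gumbel_max", recovery_truths$gumbel_max),
                     200, seed = 5)
  base <- anderson_darling_statistic(x, fit_mle(x, "gumbel_max"))
  for (ab in list(c(2, 0), c(1, -7), c(0.03, 5))) {
    y <- ab[1] * x + ab[2]
    expect_equal(anderson_darling_statistic(y, fit_mle(y, "gumbel_max")),
                 base, tolerance = 1e-4)
  }
})

test_that("against the true CDF, A-squared is family-independent (PIT)", {
  # identical uniform streams produce bit-identical statistics across
  # families, and the case-0 mean is near its theoretical value of 1
  stats_by_family <- sapply(dist_families(), function(fam) {
    params <- recovery_truths[[fam]]
    dist <- fitted_distribution(fam, params)
    vapply(1:50, function(r) {
      x <- sample_family(dist, 100, seed = 1000 + r)
      anderson_darling_statistic(x, dist)
    }, numeric(1))
  })
  expect_lt(max(apply(stats_by_family, 1, function(v) diff(range(v)))), 1e-7)
  expect_lt(abs(mean(stats_by_family[, 1]) - 1), 0.3)
})

test_that("Shapiro-Wilk screen behaves at the null and under skew", {
  pvals_null <- vapply(1:60, function(r) {
    x <- sample_family(fitted_distribution("normal", c(location = 0, scale = 1)),
                       500, seed = 3000 + r)
    normality_test(x)$p_value
  }, numeric(1))
  expect_gte(mean(pvals_null > 0.05), 0.90)

  pvals_exp <- vapply(1:60, function(r) {
    u <- sample_family(fitted_distribution("normal", c(location = 0, scale = 1)),
                       500, seed = 4000 + r)
    normality_test(qexp(pnorm(u)))$p_value
  }, numeric(1))
  expect_gte(mean(pvals_exp < 0.05), 0.95)

  w3 <- normality_test(c(-1, 0, 1))
  expect_gt(w3$statistic, 0.9)
  expect_match(w3$method, "Shapiro-Wilk")
  expect_error(normality_test(c(1, 2)), "3 <= n")
})

test_that("selection ranks the generating family first on clear cases", {
  x <- sample_family(fitted_distribution("weibull", recovery_truths$weibull),
                     1000, seed = 99)
  rk <- select_distribution(x)
  expect_equal(rk[[1]]$family, "weibull")
  expect_equal(unname(vapply(rk, `[[`, integer(1), "rank")), seq_along(rk))
  expect_true(all(diff(vapply(rk, `[[`, numeric(1), "ad_stat")) >= -1e-9))

  g <- sample_family(fitted_distribution("gumbel_max", recovery_truths$gumbel_max),
                     1000, seed = 77)
  rg <- select_distribution(g, c("normal", "gumbel_max"))
  expect_equal(rg[[1]]$family, "gumbel_max")

  # single normal candidate on normal data is trivially first
  z <- sample_family(fitted_distribution("normal", recovery_truths$normal),
                     100, seed = 13)
  expect_equal(select_distribution(z, "normal")[[1]]$family, "normal")
})

test_that("selection fails informatively when no candidate fits", {
  expect_error(select_distribution(c(-3, -2, -1), c("weibull", "lognormal")),
               "no candidate")
  x <- c(-3, -2, -1, 0, 1, 2)
  rk <- select_distribution(x)
  expect_false("weibull" %in% vapply(rk, `[[`, character(1), "family"))
  expect_true("weibull" %in% names(attr(rk, "failures")))
  tab <- as.data.frame(rk)
  expect_s3_class(tab, "data.frame")
  expect_equal(tab$rank, seq_len(nrow(tab)))
})
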