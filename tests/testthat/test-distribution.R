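test_that("density has the right point mass, continuous part and support", {
  expect_equal(ddln(0, delta = 0.7), 0.3)
  # standard lognormal at its median
  expect_equal(ddln(1, delta = 1, mu = 0, sigma2 = 1), 1 / sqrt(2 * pi),
               tolerance = 1e-12)
  # continuous part integrates to delta; with the zero mass the law is proper
  for (p in list(c(0.3, 0, 1), c(0.9, 1.5, 2.5))) {
    mass <- stats::integrate(ddln, 1e-12, Inf, delta = p[1], mu = p[2],
                             sigma2 = p[3], rel.tol = 1e-9)$value
    expect_equal(mass + (1 - p[1]), 1, tolerance = 1e-6)
  }
  expect_error(ddln(-1, delta = 0.5), "non-negative")
  expect_error(ddln(1, delta = 0), "delta")
  expect_error(ddln(1, delta = 0.5, sigma2 = -1), "sigma2")
})

test_that("moments match closed forms and the lognormal reduction", {
  m <- dln_moments(delta = 0.5, mu = 0, sigma2 = 1)
  expect_equal(m$mean, 0.8243606354, tolerance = 1e-9)
  expect_equal(m$variance, 0.5 * exp(1) * (exp(1) - 0.5), tolerance = 1e-12)
  # delta = 1 reduces to the lognormal moments
  m1 <- dln_moments(delta = 1, mu = 0.3, sigma2 = 0.8)
  expect_equal(m1$mean, exp(0.3 + 0.4), tolerance = 1e-12)
  expect_equal(m1$variance, exp(0.6 + 0.8) * (exp(0.8) - 1), tolerance = 1e-12)
  # Monte Carlo check of the analytic mean
  set.seed(401)
  x <- rdln(2e5, 0.5, 0, 1)
  se <- sqrt(m$variance / 2e5)
  expect_lt(abs(mean(x) - m$mean), 4 * se)
})

test_that("CV agrees with its log form, the moments and lognormal closed forms", {
  expect_equal(dln_cv(delta = 1, sigma2 = 1), sqrt(exp(1) - 1),
               tolerance = 1e-12)
  expect_equal(dln_cv(delta = 0.5, sigma2 = 1), 2.1063151846,
               tolerance = 1e-9)
  grid <- expand.grid(delta = c(0.05, 0.2, 0.5, 0.8, 1),
                      sigma2 = c(0.01, 0.1, 1, 5, 20))
  for (i in seq_len(nrow(grid))) {
    d <- grid$delta[i]; s2 <- grid$sigma2[i]
    expect_equal(dln_cv(d, s2), sqrt((exp(s2) - d) / d),
                 tolerance = 1e-12)
    m <- dln_moments(d, 0.7, s2)
    expect_equal(dln_cv(d, s2), sqrt(m$variance) / m$mean, tolerance = 1e-12)
  }
})

test_that("log-CV transform is finite and exact for very large variances", {
  # naive form exp(800) overflows; the log-space form stays exact
  expect_equal(phi_log_cv(800, 0.5), 400.3465735903, tolerance = 1e-12)
  expect_true(is.finite(phi_log_cv(750, 1)))
  # matches the naive form where that one is representable
  expect_equal(phi_log_cv(3, 0.4), 0.5 * (log(exp(3) - 0.4) - log(0.4)),
               tolerance = 1e-12)
  expect_error(phi_log_cv(1, 0), "delta")
})

test_that("sampler hits the zero rate and recovers the log-scale parameters", {
  set.seed(402)
  x <- rdln(1e5, 0.5, 1.2, 0.8)
  expect_lt(abs(mean(x == 0) - 0.5), 4 * sqrt(0.25 / 1e5))
  expect_true(all(x >= 0))
  expect_identical(sum(rdln(2000, 1, 0, 1) == 0), 0L)
  # parameter recovery at n = 1e4 within 4 standard errors
  set.seed(403)
  y <- rdln(1e4, 0.7, -0.5, 1.5)
  s <- summarize_dln(y)
  expect_lt(abs(s$delta_hat - 0.7), 4 * sqrt(0.7 * 0.3 / 1e4))
  expect_lt(abs(s$mu_hat + 0.5), 4 * sqrt(1.5 / s$n1))
  expect_lt(abs(s$sigma2_hat - 1.5), 4 * sqrt(2 * 1.5^2 / (s$n1 - 1)))
})

test_that("summaries carry exact counts and hand-checked log statistics", {
  s <- summarize_dln(c(0, 0, 2, 4))
  expect_identical(s$n, 4L)
  expect_identical(s$n1, 2L)
  expect_equal(s$delta_hat, 0.5)
  expect_equal(s$mu_hat, 1.0397207708, tolerance = 1e-9)
  expect_equal(s$sigma2_hat, 0.2402265070, tolerance = 1e-9)
  expect_false(is_degenerate(s))

  allpos <- summarize_dln(c(1, 2, 3))
  expect_equal(allpos$delta_hat, 1)
  expect_identical(allpos$n0, 0L)

  deg <- summarize_dln(c(0, 0, 5))
  expect_true(is_degenerate(deg))
  expect_true(is.na(deg$sigma2_hat))
  expect_error(common_cv(list(deg)), "degenerate")
  expect_error(summarize_dln(c(-1, 2)), "negative")
})

test_that("summary constructor recovers counts from a rounded rate", {
  s <- dln_summary(62, delta_hat = 0.7258, sigma2_hat = 1.7857)
  expect_identical(s$n1, 45L)
  expect_equal(s$delta_hat, 45 / 62)
  expect_error(dln_summary(62, delta_hat = 0.5, n1 = 63), "0..n")
})
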