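test_that("posterior parameters match the conjugate closed forms", {
  ck <- dln_summary(62, n1 = 45, sigma2_hat = 1.7857)
  pj <- posterior_parameters(ck, "jeffreys")
  expect_equal(pj$beta_a, 17.5)
  expect_equal(pj$beta_b, 45.5)
  expect_equal(pj$ig_shape, 22)
  expect_equal(pj$ig_scale, 39.2854, tolerance = 1e-10)
  pu <- posterior_parameters(ck, "uniform")
  expect_equal(pu$beta_a, 18)
  expect_equal(pu$beta_b, 46)
  expect_equal(pu$ig_shape, 21.5)
  expect_equal(pu$ig_scale, 38.39255, tolerance = 1e-10)
  # the uniform prior needs three non-zero observations
  expect_error(posterior_parameters(dln_summary(10, n1 = 2, sigma2_hat = 1),
                                    "uniform"), "uniform")
})

test_that("posterior draws respect domains and the beta posterior mean", {
  s <- dln_summary(62, n1 = 45, sigma2_hat = 1.7857)
  set.seed(601)
  post <- posterior_common_cv(list(s), "jeffreys", 4e4)
  expect_true(all(post$delta > 0 & post$delta < 1))
  expect_true(all(post$sigma2 > 0))
  expect_true(all(post$eta > 0))
  # E[delta | x] = (n1 + 1/2) / (n + 1) under the Jeffreys prior
  expect_lt(abs(mean(post$delta) - 45.5 / 63), 4 * sqrt(0.25 / 4e4))
})

test_that("posterior of the non-zero rate concentrates at the truth", {
  set.seed(602)
  x <- rdln(1e4, 0.35, 0, 1)
  post <- posterior_common_cv(list(summarize_dln(x)), "jeffreys", 2000)
  expect_lt(abs(mean(post$delta) - 0.35), 0.01)
})

test_that("equal-tailed interval is equal-tailed and contains the median", {
  set.seed(603)
  x <- stats::rlnorm(5000, 1, 0.4)
  ci <- equal_tailed_interval(x, 0.9)
  expect_equal(ci$lower, quantile_oracle(x, 0.05), tolerance = 1e-12)
  expect_equal(ci$upper, quantile_oracle(x, 0.95), tolerance = 1e-12)
  med <- stats::median(x)
  expect_true(ci$lower < med && med < ci$upper)
  # symmetric draws give an interval symmetric about the median
  y <- 50 + c(-(2000:1), 2000:1) / 100
  cis <- equal_tailed_interval(y, 0.95)
  expect_equal(cis$lower + cis$upper, 2 * stats::median(y), tolerance = 1e-9)
})

test_that("HPD matches the exhaustive shortest-window oracle", {
  set.seed(604)
  for (i in 1:6) {
    x <- switch(1 + i %% 3,
                stats::rlnorm(100 + 67 * i, 0, 0.5 + i / 10),
                stats::rgamma(100 + 67 * i, shape = 1.5),
                stats::rbeta(100 + 67 * i, 2, 5))
    ci <- hpd_interval(x, 0.9)
    expect_equal(c(ci$lower, ci$upper), hpd_oracle(x, 0.9), tolerance = 1e-12)
  }
})

test_that("HPD picks the leftmost window on ties and is never longer than equal-tailed", {
  # equally spaced draws: every window of 96 points spans exactly 95 units,
  # so the leftmost tie must win
  ci <- hpd_interval(0:100, 0.95)
  expect_equal(ci$lower, 0)
  expect_equal(ci$upper, 95)
  set.seed(605)
  for (i in 1:8) {
    x <- stats::rlnorm(400, 0, 0.3 + i / 8)
    expect_lte(hpd_interval(x, 0.95)$length,
               equal_tailed_interval(x, 0.95)$length)
  }
})

test_that("Bayesian rainfall intervals bracket the point estimate", {
  rain <- rainfall_summaries()
  eta <- common_cv(rain)
  set.seed(606)
  for (prior in c("jeffreys", "uniform")) {
    for (type in c("equal-tailed", "hpd")) {
      ci <- bayes_common_cv(rain, prior, type, draws = 2000)
      expect_lt(ci$lower, eta)
      expect_gt(ci$upper, eta)
    }
  }
})

test_that("per-draw weights are positive and data weights remain as an option", {
  rain <- rainfall_summaries()
  set.seed(607)
  a <- posterior_common_cv(rain, "jeffreys", 500)
  set.seed(607)
  b <- posterior_common_cv(rain, "jeffreys", 500, weights = "data")
  expect_identical(a$delta, b$delta)      # same underlying parameter draws
  expect_false(isTRUE(all.equal(a$eta, b$eta)))
  # per-draw weights vary with the draws and stay strictly positive
  expect_gt(max(apply(a$weight, 2, stats::sd)), 0)
  expect_true(all(a$var > 0))
  expect_true(all(is.finite(a$eta)))
  # data weights are constant across draws
  expect_equal(max(apply(b$weight, 2, stats::sd)), 0)
})
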