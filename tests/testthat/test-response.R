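test_that("model means evaluate their closed forms", {
  expect_equal(model_mean("step_mean", list(a = 1, c = -2), t = 4:5,
                          tau = 5), c(1, -1))
  p <- list(a = 1, c = 4, t0 = 10, s = 2)
  expect_equal(model_mean("sigmoid", p, t = 10), 1 + 4 / 2) # midpoint
  expect_error(model_mean("sigmoid", list(a = 0, c = 1, t0 = 5, s = 0),
                          t = 1), "s must be non-zero")
  # equal-segment linear_linear collapses to linear
  t <- 1:12
  ll <- model_mean("linear_linear",
                   list(a = 2, b = 0.5, a2 = 2, b2 = 0.5), t, tau = 6)
  expect_equal(ll, model_mean("linear", list(a = 2, b = 0.5), t))
})

test_that("closed-form fits are exact on noise-free data", {
  # step: exact interpolation
  f <- fit_response(annual_series(1:16, c(rep(0, 8), rep(5, 8))),
                    "step_mean", tau = 9)
  expect_equal(f$params$a, 0, tolerance = 1e-10)
  expect_equal(f$params$c, 5, tolerance = 1e-10)
  expect_equal(sum(f$residuals^2), 0, tolerance = 1e-12)
  # linear regression closed form
  t <- 1:20
  g <- fit_response(annual_series(t, 2 + 0.5 * t), "linear")
  expect_equal(g$params$a, 2, tolerance = 1e-10)
  expect_equal(g$params$b, 0.5, tolerance = 1e-10)
})

test_that("aicc follows the finite-sample formula", {
  expect_equal(aicc(-10, 2, 14), 24 + 12 / 11)
  # converges to plain AIC
  expect_equal(aicc(-10, 2, 1e6), -2 * (-10) + 4, tolerance = 1e-4)
  # smaller k wins at equal likelihood
  expect_lt(aicc(-10, 2, 14), aicc(-10, 3, 14))
  expect_warning(bad <- aicc(-10, 13, 14), "undefined")
  expect_true(is.na(bad))
})

test_that("iid fit agrees with ar1 fit when noise is white", {
  set.seed(20)
  s <- gen_annual_series("linear", list(a = 1, b = 0.02), 200,
                         noise_sd = 1)
  f_iid <- fit_response(s, "linear", error = "iid")
  f_ar1 <- fit_response(s, "linear", error = "ar1")
  expect_lt(abs(f_ar1$phi), 0.15)
  expect_equal(unlist(f_iid$params), unlist(f_ar1$params),
               tolerance = 1e-2)
})

test_that("ar1 likelihood equals a dense multivariate-normal oracle", {
  set.seed(21)
  for (r in 1:10) {
    n <- sample(5:50, 1)
    e <- rnorm(n)
    phi <- runif(1, -0.9, 0.9)
    sigma2 <- runif(1, 0.5, 2)
    w <- exp(runif(n, -0.3, 0.3))
    expect_equal(ar1_loglik(e, phi, sigma2, w),
                 dense_ar1_loglik(e, phi, sigma2, w), tolerance = 1e-8)
  }
})

test_that("gls profile likelihood is consistent with ar1_loglik", {
  set.seed(22)
  s <- gen_annual_series("step_mean", list(a = 0, c = 3), 30, tau = 16,
                         noise_sd = 1, phi = 0.5)
  f <- fit_response(s, "step_mean", tau = 16, error = "ar1")
  direct <- ar1_loglik(f$residuals, f$phi, f$sigma2)
  expect_equal(f$logL, direct, tolerance = 1e-6)
})

test_that("nested least squares: RSS(linear) >= RSS(linear_linear)", {
  set.seed(23)
  for (r in 1:10) {
    s <- gen_annual_series("linear", list(a = 0, b = 0.1), 20,
                           noise_sd = 1)
    rss <- function(fam) sum(fit_response(s, fam, tau = 10)$residuals^2)
    expect_gte(rss("linear") + 1e-10, rss("linear_linear"))
    expect_gte(rss("null") + 1e-10, rss("linear"))
  }
})

test_that("constant shift moves intercepts but not the family ranking", {
  set.seed(24)
  s <- gen_annual_series("step_mean", list(a = 0, c = 4), 30, tau = 16,
                         noise_sd = 1)
  c1 <- select_best(s, tau = 16, error = "iid")
  s2 <- annual_series(s$label, s$value + 50)
  c2 <- select_best(s2, tau = 16, error = "iid")
  expect_equal(c1$table$family, c2$table$family)
  expect_equal(c2$fits$step_mean$params$a,
               c1$fits$step_mean$params$a + 50, tolerance = 1e-6)
  expect_equal(c2$fits$step_mean$params$c, c1$fits$step_mean$params$c,
               tolerance = 1e-6)
})

test_that("selection recovers strong noise-free and step signals", {
  cmp <- select_best(annual_series(1:16, c(rep(0, 8), rep(5, 8))),
                     tau = 9)
  expect_equal(cmp$best$family, "step_mean")
  # parameter recovery across replicates (step 3 sd, tau known)
  set.seed(25)
  err <- wins <- numeric(100)
  for (r in 1:100) {
    s <- gen_annual_series("step_mean", list(a = 0, c = 3), 30, tau = 16,
                           noise_sd = 1)
    f <- fit_response(s, "step_mean", tau = 16)
    err[r] <- abs(f$params$c - 3)
    wins[r] <- select_best(s, tau = 16)$best$family == "step_mean"
  }
  expect_lte(mean(err), 0.5)
  expect_gte(mean(wins), 0.80)
})

test_that("white noise selects the null model most of the time", {
  set.seed(26)
  wins <- 0
  for (r in 1:100) {
    cmp <- select_best(rnorm(30), tau = 16, error = "iid")
    if (cmp$best$family == "null") wins <- wins + 1
  }
  expect_gte(wins / 100, 0.60)
})

test_that("residual autocorrelation check has power and holds its size", {
  # exact fit leaves zero autocorrelation
  f <- fit_response(annual_series(1:16, c(rep(0, 8), rep(5, 8))),
                    "step_mean", tau = 9)
  expect_equal(residual_lag1(f$residuals)$r1, 0)
  expect_false(residual_lag1(f$residuals)$flag)
  set.seed(27)
  power <- size <- 0
  for (r in 1:200) {
    ar <- as.numeric(arima.sim(list(ar = 0.7), 100))
    if (residual_lag1(ar)$flag) power <- power + 1
    if (residual_lag1(rnorm(100))$flag) size <- size + 1
  }
  expect_gte(power / 200, 0.95)
  expect_lte(size / 200, 0.10)
})

test_that("autocorrelated residuals trigger the AR(1) refit pass", {
  set.seed(28)
  s <- gen_annual_series("step_mean", list(a = 0, c = 4), 40, tau = 20,
                         noise_sd = 1, phi = 0.8)
  cmp <- select_best(s, tau = 20)
  expect_true(cmp$error_used %in% c("iid", "ar1"))
  if (isTRUE(cmp$residual_check$refit)) {
    expect_equal(cmp$error_used, "ar1")
    expect_gt(cmp$best$phi, 0)
  }
})

test_that("per-regime variance structure estimates the variance ratio", {
  set.seed(29)
  t <- 1:60
  y <- c(rnorm(30, 0, 0.5), rnorm(30, 4, 2))
  f <- fit_response(annual_series(t, y), "step_mean", tau = 31,
                    error = "ar1_hetvar")
  expect_gt(f$var_ratio, 4)  # true ratio 16
  expect_equal(f$k, 2 + 3)
})
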