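#' The seven candidate response-function families
#'
#' Temporal shapes a state variable can follow through a regime change:
#' `null` (constant), `linear` (monotone trend), `step_mean` (abrupt level
#' change at the change point), `linear_linear` (two independent linear
#' segments), `linear_stable` (trend then constant), `stable_linear`
#' (constant then trend) and `sigmoid` (smooth logistic transition).
#'
#' @return Character vector of family names.
#' @export
model_families <- function() {
  c("null", "linear", "linear_linear", "step_mean",
    "linear_stable", "stable_linear", "sigmoid")
}

#' Mean function of a response-family model
#'
#' @param family One of [model_families()].
#' @param params Named list of parameters: `null`: `a`; `linear`: `a`, `b`;
#'   `step_mean`: `a`, `c` (level jumps from `a` to `a + c` at `tau`);
#'   `linear_linear`: `a`, `b`, `a2`, `b2`; `linear_stable`: `a`, `b`, `m`;
#'   `stable_linear`: `m`, `a`, `b`; `sigmoid`: `a`, `c`, `t0`, `s`
#'   (`a + c / (1 + exp(-(t - t0)/s))`).
#' @param t Numeric time(s) (year labels).
#' @param tau Change point (year label); the segmented families switch at
#'   `t >= tau`.
#' @return Predicted mean value(s) at `t`.
#' @examples
#' model_mean("step_mean", list(a = 1, c = -2), t = 4:5, tau = 5)
#' @export
model_mean <- function(family, params, t, tau = NULL) {
  after <- if (!is.null(tau)) t >= tau else rep(FALSE, length(t))
  switch(family,
    null = rep(params$a, length(t)),
    linear = params$a + params$b * t,
    step_mean = params$a + params$c * after,
    linear_linear = ifelse(after, params$a2 + params$b2 * t,
                           params$a + params$b * t),
    linear_stable = ifelse(after, params$m, params$a + params$b * t),
    stable_linear = ifelse(after, params$a + params$b * t, params$m),
    sigmoid = {
      if (params$s == 0) stop("sigmoid slope s must be non-zero",
                              call. = FALSE)
      params$a + params$c / (1 + exp(-(t - params$t0) / params$s))
    },
    stop("unknown family: ", family, call. = FALSE)
  )
}

# design matrix of the linear-in-parameter families; sigmoid needs (t0, s)
design_matrix <- function(family, t, tau, t0 = NULL, s = NULL) {
  after <- as.numeric(t >= tau)
  before <- 1 - after
  switch(family,
    null = cbind(a = rep(1, length(t))),
    linear = cbind(a = 1, b = t),
    step_mean = cbind(a = 1, c = after),
    linear_linear = cbind(a = before, b = before * t,
                          a2 = after, b2 = after * t),
    linear_stable = cbind(a = before, b = before * t, m = after),
    stable_linear = cbind(m = before, a = after, b = after * t),
    sigmoid = cbind(a = 1, c = 1 / (1 + exp(-(t - t0) / s))),
    stop("unknown family: ", family, call. = FALSE)
  )
}

n_mean_params <- function(family) {
  c(null = 1L, linear = 2L, step_mean = 2L, linear_linear = 4L,
    linear_stable = 3L, stable_linear = 3L, sigmoid = 4L)[[family]]
}

# Prais-Winsten style whitening: T y with (Ty)_1 = sqrt(1-phi^2) y_1,
# (Ty)_t = y_t - phi y_{t-1}; then e' R^{-1} e = ||T e||^2 / (1 - phi^2)
# for the AR(1) correlation matrix R (closed-form tridiagonal inverse).
ar1_whiten <- function(m, phi) {
  m <- as.matrix(m)
  n <- nrow(m)
  out <- m
  out[1L, ] <- sqrt(1 - phi^2) * m[1L, ]
  if (n > 1L) out[-1L, ] <- m[-1L, , drop = FALSE] -
      phi * m[-n, , drop = FALSE]
  out
}

# profile Gaussian log-likelihood for fixed (phi, weights): GLS for theta,
# MLE for the overall variance. weights w_i multiply the error sd.
gls_profile <- function(y, X, phi = 0, w = NULL) {
  n <- length(y)
  if (is.null(w)) w <- rep(1, n)
  ys <- y / w
  Xs <- X / w
  yt <- ar1_whiten(ys, phi)
  Xt <- ar1_whiten(Xs, phi)
  fit <- stats::lm.fit(Xt, yt)
  theta <- fit$coefficients
  theta[is.na(theta)] <- 0
  r <- yt - Xt %*% theta
  q <- sum(r^2) / (1 - phi^2)
  logdet <- (n - 1) * log(1 - phi^2) + 2 * sum(log(w))
  sigma2 <- q / n
  exact <- sigma2 <= 1e-20 * (mean(ys^2) + 1e-300)
  logL <- if (exact) Inf_loglik(n) else
    -n / 2 * log(2 * pi * sigma2) - logdet / 2 - n / 2
  list(theta = theta, sigma2 = if (exact) 0 else sigma2, logL = logL,
       fitted = as.numeric(X %*% theta), exact = exact)
}

# exact interpolation: residuals are numerically zero and the Gaussian
# profile likelihood is unbounded. All exact fits get the same capped
# log-likelihood (a variance floor), so competing exact fits are ranked by
# their parameter counts alone, and every exact fit dominates every
# inexact one.
Inf_loglik <- function(n) {
  -n / 2 * log(2 * pi * 1e-300) - n / 2
}

#' Exact AR(1) Gaussian log-likelihood
#'
#' Log-likelihood of residuals `e` under N(0, sigma1^2 D R D) with R the
#' AR(1) correlation matrix (phi^|i-j|) and D = diag(w). Evaluated in O(n)
#' through the closed-form tridiagonal inverse of R.
#'
#' @param e Residual vector.
#' @param phi AR(1) coefficient, |phi| < 1.
#' @param sigma2 Innovation-free marginal variance (scalar).
#' @param w Per-observation standard-deviation multipliers (default 1).
#' @return Scalar log-likelihood.
#' @export
ar1_loglik <- function(e, phi, sigma2, w = NULL) {
  n <- length(e)
  if (is.null(w)) w <- rep(1, n)
  z <- e / w
  q <- sum(ar1_whiten(z, phi)^2) / (1 - phi^2)
  logdet <- n * log(sigma2) + (n - 1) * log(1 - phi^2) + 2 * sum(log(w))
  -n / 2 * log(2 * pi) - logdet / 2 - q / (2 * sigma2)
}

# fit one family at fixed (t0, s) nuisance (sigmoid) / none (linear ones)
# returns the best profile over the requested error structure
fit_structure <- function(y, X, t, tau, error) {
  n <- length(y)
  weights_for <- function(r) if (is.null(tau)) rep(1, n)
                             else ifelse(t >= tau, exp(r), 1)
  # an exact interpolation leaves nothing for covariance parameters to fit
  res0 <- gls_profile(y, X, 0)
  if (isTRUE(res0$exact) || error == "iid") {
    n_cov <- switch(error, iid = 1L, ar1 = 2L, ar1_hetvar = 3L)
    return(c(res0, list(phi = 0, var_ratio = 1, n_cov = n_cov)))
  }
  if (error == "ar1") {
    obj <- function(phi) -gls_profile(y, X, phi)$logL
    grid <- seq(-0.9, 0.9, by = 0.15)
    vals <- vapply(grid, obj, numeric(1))
    i <- which.min(vals)
    lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
    opt <- stats::optimize(obj, c(lo, hi))
    phi <- opt$minimum
    res <- gls_profile(y, X, phi)
    return(c(res, list(phi = phi, var_ratio = 1, n_cov = 2L)))
  }
  if (error == "ar1_hetvar") {
    obj <- function(par) {
      phi <- max(min(par[1L], 0.95), -0.95)
      -gls_profile(y, X, phi, weights_for(par[2L]))$logL
    }
    start <- c(0, 0)
    opt <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(maxit = 300))
    phi <- max(min(opt$par[1L], 0.95), -0.95)
    r <- opt$par[2L]
    res <- gls_profile(y, X, phi, weights_for(r))
    return(c(res, list(phi = phi, var_ratio = exp(2 * r), n_cov = 3L)))
  }
  stop("unknown error structure: ", error, call. = FALSE)
}

#' Fit one response-family model to an annual series
#'
#' Linear-in-parameter families are solved by (generalised) least squares in
#' closed form; the sigmoid profiles its centre and slope by bounded
#' multi-start optimisation (five centres spread over the series) with the
#' linear level and span solved in closed form at each step. Error
#' structures: `"iid"` (independent Gaussian), `"ar1"` (AR(1) correlation
#' phi^|i-j|, phi profiled on a grid then polished) and `"ar1_hetvar"`
#' (AR(1) plus a separate error variance on each side of the change point).
#' `k` counts every estimated quantity — mean parameters, each variance and
#' phi — uniformly across families; the fixed change point is not counted.
#'
#' @param series An `"annual_series"` or numeric vector.
#' @param family One of [model_families()].
#' @param tau Change point (year label), fixed from STARS. Ignored by `null`
#'   and `linear`; the sigmoid uses it only as the starting centre.
#' @param error `"iid"`, `"ar1"` or `"ar1_hetvar"`.
#' @return A `"fit_result"` list: `family`, `params` (named), `phi`,
#'   `var_ratio`, `sigma2`, `logL`, `k`, `n`, `aicc`, `fitted`,
#'   `residuals`, `tau`.
#' @export
fit_response <- function(series, family, tau = NULL, error = "iid") {
  s <- as_annual_series(series)
  y <- s$value
  t <- s$label
  n <- length(y)
  segmented <- family %in% c("step_mean", "linear_linear",
                             "linear_stable", "stable_linear")
  if (segmented) {
    if (is.null(tau)) stop("segmented family needs a change point tau",
                           call. = FALSE)
    if (tau <= min(t) || tau > max(t))
      stop("tau must lie strictly inside the series", call. = FALSE)
  }

  if (family != "sigmoid") {
    X <- design_matrix(family, t, tau)
    res <- fit_structure(y, X, t, tau, error)
    params <- as.list(res$theta)
    names(params) <- colnames(X)
    extra <- list()
  } else {
    rng <- diff(range(t))
    centers <- unique(c(stats::quantile(t, c(0.2, 0.35, 0.5, 0.65, 0.8)),
                        if (!is.null(tau)) tau))
    s_min <- 0.1
    best <- NULL
    for (c0 in centers) {
      obj <- function(par) {
        X <- design_matrix("sigmoid", t, tau, t0 = par[1L],
                           s = max(par[2L], s_min))
        -fit_structure(y, X, t, tau, error)$logL
      }
      opt <- tryCatch(
        stats::optim(c(c0, rng / 8), obj, method = "L-BFGS-B",
                     lower = c(min(t), s_min), upper = c(max(t), rng),
                     control = list(maxit = 200)),
        error = function(e) NULL)
      if (!is.null(opt) && (is.null(best) || opt$value < best$value))
        best <- opt
    }
    if (is.null(best))
      return(structure(list(family = family, converged = FALSE),
                       class = "fit_result"))
    t0 <- best$par[1L]; sl <- max(best$par[2L], s_min)
    X <- design_matrix("sigmoid", t, tau, t0 = t0, s = sl)
    res <- fit_structure(y, X, t, tau, error)
    params <- list(a = res$theta[[1L]], c = res$theta[[2L]],
                   t0 = t0, s = sl)
    extra <- list()
  }

  k <- n_mean_params(family) + res$n_cov
  fit <- list(family = family,
              params = params,
              phi = res$phi,
              var_ratio = res$var_ratio,
              sigma2 = res$sigma2,
              logL = res$logL,
              k = k,
              n = n,
              aicc = aicc(res$logL, k, n),
              fitted = res$fitted,
              residuals = y - res$fitted,
              tau = if (segmented) tau else NULL,
              error = error,
              converged = TRUE)
  class(fit) <- "fit_result"
  fit
}

#' @export
print.fit_result <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat(sprintf("fit_result: %s (did not converge)\n", x$family))
    return(invisible(x))
  }
  cat(sprintf("fit_result: %s (%s errors), logL = %.3f, k = %d, AICc = %.3f\n",
              x$family, x$error, x$logL, x$k, x$aicc))
  cat("  params:", paste(sprintf("%s = %.4g", names(x$params),
                                 unlist(x$params)), collapse = ", "), "\n")
  invisible(x)
}

#' Small-sample corrected Akaike information criterion
#'
#' AICc = -2 logL + 2k + 2k(k + 1)/(n - k - 1).
#'
#' @param logL Maximised log-likelihood.
#' @param k Number of estimated parameters (mean, variance and correlation
#'   parameters alike).
#' @param n Number of observations.
#' @return The AICc, or `NA` (with a warning) when `n - k - 1 < 1`.
#' @export
aicc <- function(logL, k, n) {
  if (n - k - 1 < 1) {
    warning("AICc undefined for n - k - 1 < 1", call. = FALSE)
    return(NA_real_)
  }
  -2 * logL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Lag-1 autocorrelation of residuals
#'
#' Pearson lag-1 autocorrelation with the conventional +/- 1.96/sqrt(n)
#' white-noise band; the flag is raised when the band is exceeded.
#'
#' @param residuals Numeric residual vector (length >= 4).
#' @return List with `r1`, `bound` and `flag`.
#' @export
residual_lag1 <- function(residuals) {
  n <- length(residuals)
  if (n < 4L) stop("need at least 4 residuals", call. = FALSE)
  e <- residuals - mean(residuals)
  denom <- sum(e^2)
  # residuals from an exact interpolation are numerical noise, not signal
  tiny <- denom <= n * (1e-12 * max(1, max(abs(residuals))))^2
  r1 <- if (tiny) 0 else sum(e[-1L] * e[-n]) / denom
  bound <- 1.96 / sqrt(n)
  list(r1 = r1, bound = bound, flag = abs(r1) > bound)
}

#' Fit all families and select the best by AICc
#'
#' All requested families are fitted with independent errors and ranked by
#' AICc. If the best model's residuals show lag-1 autocorrelation beyond
#' +/- 1.96/sqrt(n), every family is refitted with AR(1) errors and the
#' ranking is redone — the conventional two-pass treatment of temporally
#' correlated residuals. Fits that fail to converge or whose AICc is
#' undefined are excluded with a warning.
#'
#' Because several families are nested (a segmented linear segment with
#' zero slope is a step; two matching segments are a line), the strict
#' AICc minimum routinely lands on a richer family whose extra parameter
#' only chases noise. The default selection therefore applies the standard
#' parsimony convention for effectively-equivalent models: among all fits
#' within `parsimony_delta` AICc units (default 2) of the minimum, the one
#' with the fewest parameters is selected. Set `rule = "min"` for the
#' strict minimum.
#'
#' @param series An `"annual_series"` or numeric vector.
#' @param tau Change point for the segmented families.
#' @param families Families to fit (default all seven).
#' @param error `"auto"` (two-pass, the default), or one of `"iid"`,
#'   `"ar1"`, `"ar1_hetvar"` to force a single structure.
#' @param rule `"parsimony"` (default) or `"min"`, see above.
#' @param parsimony_delta AICc band treated as model equivalence.
#' @param free_tau When `TRUE`, the change point of each segmented family is
#'   profiled over all interior year labels instead of being fixed.
#' @return A `"model_comparison"`: data frame `table` (family, k, logL,
#'   aicc, delta_aicc relative to the AICc minimum, selected) sorted by
#'   AICc, list `fits`, element `best` (the selected `"fit_result"`),
#'   `error_used`, `residual_check`.
#' @export
select_best <- function(series, tau = NULL, families = model_families(),
                        error = "auto", rule = c("parsimony", "min"),
                        parsimony_delta = 2, free_tau = FALSE) {
  rule <- match.arg(rule)
  s <- as_annual_series(series)
  run_pass <- function(struct) {
    fits <- lapply(families, function(fam) {
      fit1 <- function(tt) tryCatch(
        fit_response(s, fam, tau = tt, error = struct),
        error = function(e) structure(list(family = fam, converged = FALSE),
                                      class = "fit_result"))
      segmented <- fam %in% c("step_mean", "linear_linear",
                              "linear_stable", "stable_linear")
      if (free_tau && segmented) {
        cand <- s$label[-c(1L, nrow(s))]
        best <- NULL
        for (tt in cand) {
          f <- fit1(tt)
          if (isTRUE(f$converged) && !is.na(f$aicc) &&
              (is.null(best) || f$aicc < best$aicc)) best <- f
        }
        if (is.null(best)) fit1(NULL) else best
      } else fit1(tau)
    })
    names(fits) <- families
    fits
  }
  rank_pass <- function(fits, struct) {
    ok <- vapply(fits, function(f) isTRUE(f$converged) && !is.na(f$aicc),
                 logical(1))
    if (!any(ok)) stop("no admissible fits", call. = FALSE)
    if (any(!ok))
      warning("excluded from ranking: ",
              paste(families[!ok], collapse = ", "), call. = FALSE)
    tab <- data.frame(
      family = families[ok],
      k = vapply(fits[ok], `[[`, integer(1), "k"),
      logL = vapply(fits[ok], `[[`, numeric(1), "logL"),
      aicc = vapply(fits[ok], `[[`, numeric(1), "aicc"),
      phi = vapply(fits[ok], `[[`, numeric(1), "phi"))
    tab <- tab[order(tab$aicc, match(tab$family, model_families())), ]
    tab$delta_aicc <- tab$aicc - tab$aicc[1L]
    winner <- if (rule == "min") tab$family[1L] else {
      cand <- tab[tab$delta_aicc < parsimony_delta, ]
      cand$family[order(cand$k, match(cand$family, model_families()))][1L]
    }
    tab$selected <- tab$family == winner
    rownames(tab) <- NULL
    list(table = tab, fits = fits, best = fits[[winner]],
         error_used = struct)
  }

  first <- if (error == "auto") "iid" else error
  pass <- rank_pass(run_pass(first), first)
  res_check <- residual_lag1(pass$best$residuals)
  if (error == "auto" && res_check$flag) {
    pass <- rank_pass(run_pass("ar1"), "ar1")
    res_check <- c(res_check, list(refit = TRUE))
  }
  out <- c(pass, list(residual_check = res_check, tau = tau))
  class(out) <- "model_comparison"
  out
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Response-function comparison (%s errors%s)\n", x$error_used,
              if (!is.null(x$tau)) sprintf(", tau = %s", x$tau) else ""))
  print(x$table, row.names = FALSE)
  invisible(x)
}
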