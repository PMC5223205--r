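#' Annual series container
#'
#' A light container pairing ordered labels (years or cycle ids) with
#' values. Explicitly-missing cycles are simply absent; nothing is imputed.
#'
#' @param labels Strictly increasing numeric labels (e.g. starting year of
#'   each flood-pulse cycle) or cycle-id strings `"YYYY-YYYY"` (converted to
#'   their starting year).
#' @param values Finite numeric values, one per label.
#' @return An `"annual_series"`: a data frame with columns `label`, `value`.
#' @export
annual_series <- function(labels, values) {
  if (is.character(labels))
    labels <- as.numeric(sub("-.*$", "", labels))
  labels <- as.numeric(labels)
  values <- as.numeric(values)
  stopifnot(length(labels) == length(values))
  if (anyNA(labels) || is.unsorted(labels, strictly = TRUE))
    stop("labels must be strictly increasing", call. = FALSE)
  if (any(!is.finite(values)))
    stop("values must be finite", call. = FALSE)
  out <- data.frame(label = labels, value = values)
  class(out) <- c("annual_series", "data.frame")
  out
}

as_annual_series <- function(x) {
  if (inherits(x, "annual_series")) return(x)
  if (is.numeric(x) && is.null(dim(x))) {
    labs <- if (!is.null(names(x))) names(x) else seq_along(x)
    return(annual_series(labs, unname(x)))
  }
  stop("cannot coerce to annual_series", call. = FALSE)
}

#' Lag-1 autoregression coefficient by ordinary least squares
#'
#' The slope of the regression of the series on its own lag after centering:
#' alpha = sum (x_t - m)(x_{t-1} - m) / sum (x_{t-1} - m)^2. Estimates are
#' clamped to (-0.99, 0.99) so the white-noise filter stays invertible.
#'
#' @param series An `"annual_series"` or numeric vector.
#' @return The estimated coefficient (numeric scalar).
#' @export
estimate_ar1 <- function(series) {
  x <- as_annual_series(series)$value
  n <- length(x)
  if (n < 3L) stop("need at least 3 points", call. = FALSE)
  m <- mean(x)
  denom <- sum((x[-n] - m)^2)
  if (denom == 0) {
    warning("zero-variance series; alpha = 0", call. = FALSE)
    return(0)
  }
  a <- sum((x[-1L] - m) * (x[-n] - m)) / denom
  max(min(a, 0.99), -0.99)
}

#' White-noise (prewhitening) filter
#'
#' Removes lag-1 autocorrelation before the sequential t-test:
#' x'_t = x_t - alpha x_{t-1} for t >= 2, with the first value scaled by
#' (1 - alpha) so a constant series stays constant (at c(1 - alpha)).
#' Labels are preserved.
#'
#' @param series An `"annual_series"` or numeric vector.
#' @param alpha AR(1) coefficient, |alpha| < 1; defaults to
#'   [estimate_ar1()] of the series.
#' @return A filtered `"annual_series"`.
#' @export
prewhiten <- function(series, alpha = NULL) {
  s <- as_annual_series(series)
  if (is.null(alpha)) alpha <- estimate_ar1(s)
  if (abs(alpha) >= 1) stop("|alpha| must be < 1", call. = FALSE)
  x <- s$value
  n <- length(x)
  out <- c(x[1L] * (1 - alpha), x[-1L] - alpha * x[-n])
  annual_series(s$label, out)
}

#' Sequential t-test analysis of regime shifts (STARS)
#'
#' A one-pass online change-point detector for mean shifts. The scale of a
#' detectable shift is set from the whole series: sigma_l^2 is the average
#' sample variance over all consecutive windows of length `l`, and
#' `diff = t_crit * sqrt(2 sigma_l^2 / l)` with `t_crit` the two-sided
#' Student critical value at significance `p` on `2l - 2` degrees of
#' freedom. The first `l` points seed the current regime. Each later point
#' deviating from the current regime mean (mean of the most recent
#' `min(l, regime length)` points) by more than `diff` becomes a candidate
#' shift; the Regime Shift Index (RSI) then accumulates the normalised
#' exceedances `(x_j - (mean +/- diff)) / (l sigma_l)` over the following up
#' to `l` points. If the cumulative sum ever turns negative the candidate is
#' rejected and absorbed; if it stays positive through the window the shift
#' is confirmed at the candidate point and a new regime starts there. A
#' window truncated by the series end can still confirm, provided it covers
#' at least `min_support` points (default half the cut-off length, rounded
#' up) — without this guard the last couple of points, whose confirmation
#' window is a handful of values, produce abundant spurious shifts in pure
#' noise. No retroactive adjustment is made after confirmation.
#'
#' Missing cycles are absent points: windows count available points only,
#' and `gap_spanned` flags confirmations whose test window spanned a label
#' gap.
#'
#' @param series An `"annual_series"` or numeric vector.
#' @param params A list with `significance` (default 0.05), `window`
#'   (cut-off length `l`, default 10), `prewhiten` (default `FALSE`;
#'   when `TRUE` the series is prewhitened with its OLS AR(1) estimate
#'   first) and `min_support` (smallest truncated confirmation window that
#'   can still confirm a shift; default `ceiling(l / 2)`). A [run_config()]
#'   may be given instead.
#' @return A `"stars_result"` list: `shifts` (labels of the first point of
#'   each new regime), `rsi` (RSI of each confirmed shift), `regimes`
#'   (data frame label-range/mean per regime), `sigma_l`, `diff`,
#'   `t_crit`, `alpha` (AR(1) estimate used, or `NA`), `gap_spanned`.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(10, 0, 0.1), rnorm(10, 5, 0.1))
#' stars(x, list(significance = 0.05, window = 10))$shifts  # 11
#' @export
stars <- function(series, params = list()) {
  s <- as_annual_series(series)
  if (inherits(params, "run_config"))
    params <- list(significance = params$stars_significance,
                   window = params$stars_window,
                   prewhiten = params$prewhiten)
  p <- params$significance %||% 0.05
  l <- as.integer(params$window %||% 10L)
  do_pw <- isTRUE(params$prewhiten)
  min_support <- as.integer(params$min_support %||% ceiling(l / 2))
  n <- nrow(s)
  if (l > n) stop("window length exceeds series length", call. = FALSE)
  if (l < 3L) stop("window must be at least 3", call. = FALSE)

  alpha <- NA_real_
  if (do_pw) {
    alpha <- estimate_ar1(s)
    s <- prewhiten(s, alpha)
  }
  x <- s$value
  labs <- s$label

  # scale of detectable change from the whole series
  nw <- n - l + 1L
  sigma2_l <- mean(vapply(seq_len(nw),
                          function(i) stats::var(x[i:(i + l - 1L)]),
                          numeric(1)))
  sigma_l <- sqrt(sigma2_l)
  t_crit <- stats::qt(1 - p / 2, df = 2L * l - 2L)
  diff_thr <- t_crit * sqrt(2 * sigma2_l / l)

  regime_start <- 1L
  shifts <- integer(0)
  rsis <- numeric(0)
  gap_flags <- logical(0)

  regime_mean <- function(upto) {
    len <- upto - regime_start + 1L
    use <- max(regime_start, upto - min(l, len) + 1L):upto
    mean(x[use])
  }

  i <- l + 1L
  while (i <= n) {
    mu <- regime_mean(i - 1L)
    dev <- x[i] - mu
    if (abs(dev) > diff_thr && sigma_l > 0) {
      sgn <- sign(dev)
      target <- mu + sgn * diff_thr
      csum <- 0
      jmax <- min(i + l - 1L, n)
      ok <- (jmax - i + 1L) >= min_support
      if (ok) for (j in i:jmax) {
        csum <- csum + sgn * (x[j] - target) / (l * sigma_l)
        if (csum < 0) { ok <- FALSE; break }
      }
      if (ok) {
        shifts <- c(shifts, i)
        rsis <- c(rsis, csum)
        gap_flags <- c(gap_flags,
                       (labs[jmax] - labs[i]) > (jmax - i))
        regime_start <- i
      }
    }
    i <- i + 1L
  }

  bounds <- c(1L, shifts, n + 1L)
  regimes <- data.frame(
    start_label = labs[bounds[-length(bounds)]],
    end_label = labs[bounds[-1L] - 1L],
    mean = vapply(seq_len(length(bounds) - 1L), function(k) {
      idx <- bounds[k]:(bounds[k + 1L] - 1L)
      len <- length(idx)
      mean(x[idx[max(1L, len - min(l, len) + 1L):len]])
    }, numeric(1))
  )

  out <- list(shifts = labs[shifts],
              rsi = rsis,
              regimes = regimes,
              sigma_l = sigma_l,
              diff = diff_thr,
              t_crit = t_crit,
              alpha = alpha,
              gap_spanned = gap_flags,
              params = list(significance = p, window = l,
                            prewhiten = do_pw, min_support = min_support))
  class(out) <- "stars_result"
  out
}

#' @export
print.stars_result <- function(x, ...) {
  cat(sprintf("STARS (p = %g, l = %d%s): %d shift(s)\n",
              x$params$significance, x$params$window,
              if (x$params$prewhiten)
                sprintf(", prewhitened alpha = %.3f", x$alpha) else "",
              length(x$shifts)))
  if (length(x$shifts))
    for (k in seq_along(x$shifts))
      cat(sprintf("  shift at %s (RSI = %.3f)%s\n", x$shifts[k], x$rsi[k],
                  if (x$gap_spanned[k]) " [window spans gap]" else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
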