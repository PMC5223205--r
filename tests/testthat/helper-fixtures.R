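# shared fixture builders; everything is generated in code at test time

write_csv_fixture <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

# a stage series from raw levels on consecutive days
stage_from_levels <- function(levels, start = as.Date("2000-01-01")) {
  out <- data.frame(date = start + seq_along(levels) - 1L, level_m = levels)
  attr(out, "n_gap_days") <- 0L
  class(out) <- c("stage_series", "data.frame")
  out
}

# symmetric triangular pulse 18 -> 28 -> 18 m at 0.5 m/day, with dry tails,
# repeated twice so one complete cycle exists
two_pulse_triangle <- function() {
  pulse <- c(seq(18, 28, by = 0.5), seq(27.5, 18, by = -0.5))
  stage_from_levels(c(pulse, pulse + c(rep(0, 0), rep(0, length(pulse)))))
}

# default response-family parameter sets at a given signal size
family_params <- function(n, tau, sig = 4, sigmoid_s = 1) {
  list(
    null = list(a = 0),
    linear = list(a = 0, b = sig / (n - 1)),
    linear_linear = list(a = 0, b = sig / (tau - 1),
                         a2 = sig + sig / (n - tau), b2 = -sig / (n - tau)),
    step_mean = list(a = 0, c = sig),
    linear_stable = list(a = sig + sig / (tau - 1), b = -sig / (tau - 1),
                         m = 0),
    stable_linear = list(m = 0, a = 0, b = sig / (n - tau)),
    sigmoid = list(a = 0, c = sig, t0 = tau, s = sigmoid_s))
}

# dense multivariate-normal AR(1) log-likelihood oracle (independent of the
# package's O(n) tridiagonal route)
dense_ar1_loglik <- function(e, phi, sigma2, w = NULL) {
  n <- length(e)
  if (is.null(w)) w <- rep(1, n)
  R <- phi^abs(outer(seq_len(n), seq_len(n), "-"))
  S <- sigma2 * outer(w, w) * R
  ch <- chol(S)
  z <- backsolve(ch, e, transpose = TRUE)
  -n / 2 * log(2 * pi) - sum(log(diag(ch))) - sum(z^2) / 2
}
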