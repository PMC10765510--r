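# Stationarity (ADF + KPSS) and FFT periodicity analysis of dynamic
# indicator traces. Both tests are the constant-only ("level") variants:
# dynamic graph indicators have a nonzero mean but no modelled trend.
# P-values come from interpolation in the classical lookup tables and are
# clamped to the tables' ranges, as the standard R implementations do.

# Dickey-Fuller tau_mu critical values (constant, no trend) by sample size.
ADF_TAU_MU <- list(
  n = c(25, 50, 100, 250, 500, 1e6),
  p = c(0.01, 0.025, 0.05, 0.10, 0.90, 0.95, 0.975, 0.99),
  cv = rbind(
    c(-3.75, -3.33, -3.00, -2.63, -0.37, 0.00, 0.34, 0.72),
    c(-3.58, -3.22, -2.93, -2.60, -0.40, -0.03, 0.29, 0.66),
    c(-3.51, -3.17, -2.89, -2.58, -0.42, -0.05, 0.26, 0.63),
    c(-3.46, -3.14, -2.88, -2.57, -0.42, -0.06, 0.24, 0.62),
    c(-3.44, -3.13, -2.87, -2.57, -0.43, -0.07, 0.24, 0.61),
    c(-3.43, -3.12, -2.86, -2.57, -0.44, -0.07, 0.23, 0.60)))

# KPSS level-stationarity critical values.
KPSS_LEVEL <- list(p = c(0.10, 0.05, 0.025, 0.01),
                   cv = c(0.347, 0.463, 0.574, 0.739))

#' Augmented Dickey-Fuller unit-root test (constant, automatic lag)
#'
#' Regression of the differenced series on a constant, the lagged level and
#' lagged differences; the lag order is chosen by AIC over 0..maxLag on a
#' common estimation sample. The p-value interpolates the Dickey-Fuller
#' tau distribution (constant case) and is clamped to [0.01, 0.99].
#'
#' @param x numeric series (length >= 10 after differencing).
#' @param maxLag maximum augmentation lag; default
#'   \code{trunc(12 * (n/100)^0.25)} capped so enough observations remain.
#' @return list: \code{statistic} (tau), \code{p_value}, \code{lag},
#'   \code{clamped} (TRUE when the p-value hit a table bound).
#' @export
adfTest <- function(x, maxLag = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  stopifnot(n >= 12L)
  if (stats::sd(x) == 0) stop("constant series: ADF regression is degenerate")
  dx <- diff(x)
  if (is.null(maxLag)) maxLag <- trunc(12 * (n / 100)^0.25)
  maxLag <- max(0L, min(as.integer(maxLag), n - 10L))
  # common estimation sample across candidate lags for AIC comparability
  start <- maxLag + 2L
  idx <- start:n
  nEff <- length(idx)
  yl <- x[idx - 1L]
  dy <- x[idx] - x[idx - 1L]
  fitFor <- function(p) {
    X <- cbind(1, yl)
    if (p > 0L)
      for (l in seq_len(p)) X <- cbind(X, x[idx - l] - x[idx - l - 1L])
    fit <- stats::lm.fit(X, dy)
    rss <- sum(fit$residuals^2)
    aic <- nEff * log(rss / nEff) + 2 * ncol(X)
    list(fit = fit, X = X, rss = rss, aic = aic, p = p)
  }
  cands <- lapply(0:maxLag, fitFor)
  best <- cands[[which.min(vapply(cands, `[[`, numeric(1), "aic"))]]
  dof <- nEff - ncol(best$X)
  s2 <- best$rss / dof
  xtxInv <- chol2inv(chol(crossprod(best$X)))
  se <- sqrt(s2 * xtxInv[2, 2])
  tau <- best$fit$coefficients[2] / se
  # interpolate critical values over sample size, then p over the statistic
  cvAtN <- vapply(seq_along(ADF_TAU_MU$p), function(j)
    stats::approx(ADF_TAU_MU$n, ADF_TAU_MU$cv[, j], xout = nEff,
                  rule = 2)$y, numeric(1))
  pv <- stats::approx(cvAtN, ADF_TAU_MU$p, xout = tau, rule = 2)$y
  clamped <- tau < cvAtN[1] || tau > cvAtN[length(cvAtN)]
  list(statistic = unname(tau), p_value = pv, lag = best$p,
       clamped = clamped)
}

#' KPSS level-stationarity test
#'
#' Null hypothesis: the series is level-stationary. Statistic
#' \code{sum(S_t^2) / (n^2 s^2(l))} with partial sums of the demeaned
#' series and a Bartlett-window long-run variance at truncation lag
#' \code{trunc(4 * (n/100)^0.25)} (the standard data-length heuristic).
#' The p-value interpolates the level-case table, clamped to [0.01, 0.10].
#'
#' @param x numeric series (length >= 10).
#' @param lag truncation lag; default the heuristic above.
#' @return list: \code{statistic}, \code{p_value}, \code{lag},
#'   \code{clamped}.
#' @export
kpssTest <- function(x, lag = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  stopifnot(n >= 10L)
  if (stats::sd(x) == 0) stop("constant series: KPSS statistic is degenerate")
  if (is.null(lag)) lag <- trunc(4 * (n / 100)^0.25)
  lag <- max(0L, min(as.integer(lag), n - 1L))
  e <- x - mean(x)
  s2 <- sum(e^2) / n
  if (lag > 0L)
    for (l in seq_len(lag))
      s2 <- s2 + 2 * (1 - l / (lag + 1)) * sum(e[(l + 1):n] * e[1:(n - l)]) / n
  stat <- sum(cumsum(e)^2) / (n^2 * s2)
  pv <- stats::approx(KPSS_LEVEL$cv, KPSS_LEVEL$p, xout = stat, rule = 2)$y
  clamped <- stat < KPSS_LEVEL$cv[1] || stat > KPSS_LEVEL$cv[length(KPSS_LEVEL$cv)]
  list(statistic = stat, p_value = pv, lag = lag, clamped = clamped)
}

#' Combined stationarity verdict for a dynamic indicator trace
#'
#' Runs ADF (null: unit root) and KPSS (null: level-stationary) and
#' combines them: \code{"stationary"} when ADF rejects and KPSS does not,
#' \code{"nonstationary"} when KPSS rejects and ADF does not, otherwise
#' \code{"conflicting"}. A constant series is reported stationary with a
#' degenerate-series flag.
#'
#' @param x numeric series of one metric over windows (length >= 20).
#' @param alpha significance level (default 0.05).
#' @return one-row data.frame: \code{adf_statistic}, \code{adf_p},
#'   \code{kpss_statistic}, \code{kpss_p}, \code{verdict},
#'   \code{degenerate}.
#' @export
stationarityTest <- function(x, alpha = 0.05) {
  x <- as.numeric(x)
  stopifnot(length(x) >= 20L)
  if (stats::sd(x) == 0) {
    return(data.frame(adf_statistic = NA_real_, adf_p = NA_real_,
                      kpss_statistic = NA_real_, kpss_p = NA_real_,
                      verdict = "stationary", degenerate = TRUE,
                      stringsAsFactors = FALSE))
  }
  adf <- adfTest(x)
  kpss <- kpssTest(x)
  verdict <- if (adf$p_value < alpha && kpss$p_value >= alpha) "stationary"
    else if (adf$p_value >= alpha && kpss$p_value < alpha) "nonstationary"
    else "conflicting"
  data.frame(adf_statistic = adf$statistic, adf_p = adf$p_value,
             kpss_statistic = kpss$statistic, kpss_p = kpss$p_value,
             verdict = verdict, degenerate = FALSE, stringsAsFactors = FALSE)
}

#' FFT periodicity analysis of a dynamic indicator trace
#'
#' Linearly detrends the series, takes the discrete Fourier transform and
#' reports the dominant nonzero frequency (in cycles per window), the
#' corresponding period in seconds (via the window stride), and the peak
#' power to median power ratio. "No significant periodicity" can be read as
#' a ratio below the cutoff (default 10). A constant series has no dominant
#' frequency.
#'
#' @param x numeric series over windows (length >= 8).
#' @param trSeconds repetition time of the source run (seconds).
#' @param stepTr window step in TR.
#' @param cutoff ratio above which the peak is flagged periodic.
#' @return one-row data.frame: \code{dominant_frequency} (cycles/window in
#'   (0, 0.5]), \code{dominant_period_seconds}, \code{peak_power_ratio},
#'   \code{periodic} (logical).
#' @export
periodicityTest <- function(x, trSeconds, stepTr = 1L, cutoff = 10) {
  x <- as.numeric(x)
  n <- length(x)
  stopifnot(n >= 8L)
  if (stats::sd(x) == 0) {
    return(data.frame(dominant_frequency = NA_real_,
                      dominant_period_seconds = NA_real_,
                      peak_power_ratio = NA_real_, periodic = FALSE))
  }
  t0 <- seq_len(n)
  res <- stats::lm.fit(cbind(1, t0), x)$residuals
  pow <- Mod(stats::fft(res))^2
  # positive frequencies below Nyquist; for even n the Nyquist bin is
  # excluded (no phase information, chi-squared(1) null) as periodogram
  # practice recommends
  hi <- if (n %% 2 == 0) n %/% 2 else n %/% 2 + 1
  half <- pow[2:hi]
  kk <- which.max(half)
  freq <- kk / n  # cycles per window
  ratio <- max(half) / stats::median(half)
  data.frame(dominant_frequency = freq,
             dominant_period_seconds = (1 / freq) * stepTr * trSeconds,
             peak_power_ratio = ratio, periodic = ratio >= cutoff)
}
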