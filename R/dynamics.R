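# The eight dynamics metrics computed on breath-indexed series: mean, SD,
# CV (variability), ACW-50 and PSD slope (timescales), LZ76 complexity,
# sample entropy, multiscale entropy (complexity/entropy).

#' @rdname series_cv
#' @export
series_mean <- function(x) {
  if (length(x) < 2L) stop("series too short")
  mean(x)
}

#' @rdname series_cv
#' @export
series_sd <- function(x) {
  if (length(x) < 2L) stop("series too short")
  sd(x)  # n-1 denominator
}

#' Central tendency and variability of a series
#'
#' `series_cv` is the coefficient of variation sd/mean, a scale-free
#' variability measure; it is invariant under positive rescaling.
#'
#' @param x numeric series.
#' @return A scalar.
#' @export
series_cv <- function(x) {
  m <- series_mean(x)
  if (m == 0) stop("cv undefined for zero-mean series")
  series_sd(x) / m
}

#' Autocorrelation window (ACW-50)
#'
#' Computes the biased (n-denominator) normalized autocorrelation function
#' and returns the first integer lag at which it drops below 0.5 — the
#' signal's intrinsic timescale in breath units. If the ACF never drops
#' below 0.5 within n/2 lags, acw50 is set to that maximum lag and
#' `censored` is flagged.
#'
#' @param x numeric series, length >= 10, nonzero variance.
#' @return list with `lags`, `acf`, `acw50`, `censored`.
#' @export
autocorr_window <- function(x) {
  n <- length(x)
  if (n < 10L) stop("series too short for ACW")
  if (sd(x) == 0) stop("zero-variance series")
  L <- floor(n / 2)
  a <- as.numeric(acf(x, lag.max = L, plot = FALSE,
                      demean = TRUE, type = "correlation")$acf)
  below <- which(a[-1L] < 0.5)
  censored <- length(below) == 0L
  list(lags = 0:L, acf = a,
       acw50 = if (censored) L else below[1L],
       censored = censored)
}

#' Power spectral density slope
#'
#' Raw periodogram of the mean-removed series over breath-index frequencies
#' 0 < f <= 0.5, then ordinary least squares of log10(power) on
#' log10(frequency). The reported exponent `beta` is minus the regression
#' slope, so beta > 0 means low-frequency dominance (P ~ 1/f^beta) and a
#' decrease in beta is a shift towards faster frequencies.
#'
#' @param x numeric series, length >= 32, nonzero variance.
#' @return list with `freqs`, `power`, `beta`, `slope` (the raw regression
#'   slope = -beta) and `fit_range`.
#' @export
psd_slope <- function(x) {
  n <- length(x)
  if (n < 32L) stop("series too short for PSD slope")
  if (sd(x) == 0) stop("zero-variance series")
  z <- x - mean(x)
  k <- seq_len(floor(n / 2))
  f <- k / n
  P <- Mod(fft(z)[k + 1L])^2 / n
  keep <- P > 0
  fit <- lm(log10(P[keep]) ~ log10(f[keep]))
  slope <- unname(coef(fit)[2L])
  list(freqs = f, power = P, beta = -slope, slope = slope,
       fit_range = range(f))
}

#' Lempel-Ziv complexity (LZ76)
#'
#' Binarizes the series at its mean (values >= mean map to 1), parses the
#' binary string with the exhaustive LZ76 production scheme, and returns
#' the phrase count c and the normalized complexity c log2(n) / n, which
#' approaches 1 for an incompressible (fair-coin) sequence. Invariant under
#' positive affine rescaling of the input because the threshold moves with
#' the data.
#'
#' @param x numeric series, length >= 16.
#' @return list with `pattern_count`, `n`, `normalized`.
#' @export
lempel_ziv_complexity <- function(x) {
  n <- length(x)
  if (n < 16L) stop("series too short for LZC")
  b <- as.integer(x >= mean(x))
  c <- .lz76_count(b)
  list(pattern_count = c, n = n, normalized = c * log2(n) / n)
}

#' Sample entropy parameters
#'
#' @param m embedding dimension.
#' @param r_factor tolerance as a fraction of the series SD.
#' @param delay samples between embedded elements.
#' @return A `sampen_params` list.
#' @export
sampen_params <- function(m = 2L, r_factor = 0.2, delay = 1L) {
  stopifnot(m >= 1, r_factor > 0, r_factor < 1, delay >= 1)
  structure(list(m = as.integer(m), r_factor = r_factor,
                 delay = as.integer(delay)), class = "sampen_params")
}

#' Sample entropy
#'
#' SampEn(m, r, N) = -ln(A/B) where B counts pairs of m-length templates
#' within Chebyshev distance r (self-matches excluded) and A the same for
#' (m+1)-length templates; the tolerance is r = r_factor x SD(x) unless an
#' absolute `r` is supplied (used by the multiscale wrapper to hold r fixed
#' across scales). Higher values mean a less predictable series.
#'
#' @param x numeric series, length >= 4(m+1), positive SD.
#' @param params a [sampen_params()].
#' @param r optional absolute tolerance overriding `r_factor x SD(x)`.
#' @return SampEn as a scalar; `NaN` (with a warning) when no template
#'   pairs match at length m.
#' @export
sample_entropy <- function(x, params = sampen_params(), r = NULL) {
  m <- params$m; delay <- params$delay
  n <- length(x)
  if (n < 4L * (m + 1L)) stop("series too short for sample entropy")
  s <- sd(x)
  if (is.null(r)) {
    if (s == 0) stop("zero-SD series: sample entropy undefined")
    r <- params$r_factor * s
  }
  cnt <- .sampen_counts(as.numeric(x), m, r, delay)
  if (cnt[1L] == 0) {
    warning("no m-template matches; sample entropy undefined")
    return(NaN)
  }
  if (cnt[2L] == 0) {
    warning("no (m+1)-template matches; sample entropy undefined")
    return(NaN)
  }
  -log(cnt[2L] / cnt[1L])
}

#' Multiscale entropy parameters
#'
#' @param base a [sampen_params()].
#' @param scales coarse-graining factors; `NULL` means 1..min(10,
#'   floor(N/10)), resolved against the series length at call time.
#' @param summary `"mean"` (default) or `"auc"` aggregation over scales.
#' @return An `mse_params` list.
#' @export
mse_params <- function(base = sampen_params(), scales = NULL,
                       summary = c("mean", "auc")) {
  summary <- match.arg(summary)
  if (!is.null(scales)) stopifnot(all(scales >= 1))
  structure(list(base = base, scales = scales, summary = summary),
            class = "mse_params")
}

coarse_grain <- function(x, tau) {
  n <- floor(length(x) / tau)
  if (tau == 1L) return(x[seq_len(n)])
  colMeans(matrix(x[seq_len(n * tau)], nrow = tau))
}

#' Multiscale entropy
#'
#' Coarse-grains the series by averaging non-overlapping windows of size
#' tau for each scale, then computes sample entropy at every scale with
#' the tolerance held fixed at r_factor x SD of the ORIGINAL series
#' (Costa convention), so the per-scale profile reflects structure rather
#' than the variance lost to averaging. The summary value is the mean of
#' the finite per-scale entropies.
#'
#' @param x numeric series, length >= 10 x max scale.
#' @param params an [mse_params()].
#' @param rescale_r recompute the tolerance from each coarse-grained
#'   series' own SD instead of holding it fixed.
#' @return list with `value` (summary), `scales`, `profile` (per-scale
#'   SampEn).
#' @export
multiscale_entropy <- function(x, params = mse_params(), rescale_r = FALSE) {
  n <- length(x)
  scales <- params$scales
  if (is.null(scales)) scales <- seq_len(max(1L, min(10L, floor(n / 10))))
  if (n < 10L * max(scales)) stop("series too short for requested scales")
  m <- params$base$m
  if (floor(n / max(scales)) < m + 2L) stop("coarse-grained series too short")
  s0 <- sd(x)
  if (s0 == 0) stop("zero-SD series: multiscale entropy undefined")
  r_abs <- params$base$r_factor * s0
  prof <- vapply(scales, function(tau) {
    cg <- coarse_grain(x, tau)
    # scales whose coarse series is too short for SampEn contribute NaN
    tryCatch(
      suppressWarnings(sample_entropy(cg, params$base,
                                      r = if (rescale_r) NULL else r_abs)),
      error = function(e) NaN)
  }, numeric(1))
  fin <- is.finite(prof)
  if (!any(fin)) stop("multiscale entropy undefined at every scale")
  value <- if (params$summary == "mean") {
    mean(prof[fin])
  } else {  # trapezoidal area under the scale profile
    sc <- scales[fin]; pr <- prof[fin]
    if (length(sc) < 2L) pr[1L]
    else sum(diff(sc) * (pr[-1L] + pr[-length(pr)]) / 2)
  }
  list(value = value, scales = scales, profile = prof)
}
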