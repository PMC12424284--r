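# Assemble the 16-feature dynamics vector per recording and the table-level
# transforms applied before inference: natural-log and site harmonization.

#' Compute the 16-feature dynamics vector for one breath series
#'
#' Applies the eight metrics (mean, SD, CV, ACW-50, PSD slope, LZC,
#' SampEn, MSE) to both the rate and the amplitude series. Censored
#' ACW-50 values (ACF never below 0.5) are kept at the maximum lag and
#' recorded in the `flags` attribute; metric errors are re-thrown with the
#' feature name attached.
#'
#' @param series a `breath_series` from [extract_breath_series()].
#' @param sampen a [sampen_params()].
#' @param mse an [mse_params()].
#' @param min_breaths minimum series length accepted.
#' @return Named numeric vector of length 16 in canonical order, with a
#'   `flags` attribute.
#' @export
compute_dynamics <- function(series, sampen = sampen_params(),
                             mse = mse_params(base = sampen),
                             min_breaths = 20) {
  qs <- quality_summary(series, min_breaths)
  if (qs$n_breaths < min_breaths)
    stop("series too short: ", qs$n_breaths, " breaths (need ", min_breaths, ")")
  flags <- character(0)
  one <- function(x, tag) {
    wrap <- function(metric, expr) {
      tryCatch(expr, error = function(e)
        stop(metric, "_", tag, ": ", conditionMessage(e), call. = FALSE))
    }
    aw <- wrap("acw50", autocorr_window(x))
    if (aw$censored) flags <<- c(flags, paste0("acw50_", tag, " censored"))
    c(mean = wrap("mean", series_mean(x)),
      sd = wrap("sd", series_sd(x)),
      cv = wrap("cv", series_cv(x)),
      acw50 = aw$acw50,
      psd_slope = wrap("psd_slope", psd_slope(x)$beta),
      lzc = wrap("lzc", lempel_ziv_complexity(x)$normalized),
      sampen = wrap("sampen", sample_entropy(x, sampen)),
      mse = wrap("mse", multiscale_entropy(x, mse)$value))
  }
  vr <- one(series$rate, "rate")
  va <- one(series$amplitude, "amp")
  out <- as.vector(rbind(vr, va))
  names(out) <- feature_names()
  attr(out, "flags") <- flags
  out
}

#' Full extraction pipeline: recording -> feature-table row
#'
#' Band-pass filter, extrema detection, series extraction and
#' [compute_dynamics()] in one call.
#'
#' @param rec a [breath_recording()].
#' @param low,high filter band in Hz.
#' @param amp_min_frac excursion-pruning threshold.
#' @param ... passed to [compute_dynamics()].
#' @return One-row data.frame with metadata plus the 16 features.
#' @export
extract_features <- function(rec, low = 0.05, high = 3.0,
                             amp_min_frac = 0.3, ...) {
  filt <- bandpass_filter(rec, low, high)
  ev <- detect_breath_extrema(filt, rec$fs, amp_min_frac)
  ser <- extract_breath_series(filt, ev, rec$fs)
  dv <- compute_dynamics(ser, ...)
  cbind(data.frame(subject = rec$subject_id, condition = rec$condition,
                   site = rec$site_id, stringsAsFactors = FALSE),
        as.data.frame(as.list(dv)))
}

#' Natural-log transform of a feature table
#'
#' Applies log() to every strictly positive feature column; columns
#' containing any non-positive value (possible for the PSD slope, whose
#' exponent can be negative) are passed through unchanged with a warning.
#'
#' @param t a raw [feature_table()].
#' @return The logged table; untransformed columns are listed in the
#'   `untransformed` attribute.
#' @export
log_transform_features <- function(t) {
  stopifnot(inherits(t, "feature_table"))
  if (attr(t, "transform_state") != "raw")
    stop("log transform expects a raw table")
  skipped <- character(0)
  for (fn in feature_names()) {
    v <- t[[fn]]
    # undefined entries (e.g. SampEn with no template match) stay NaN
    if (all(v[is.finite(v)] > 0)) t[[fn]] <- log(v)
    else skipped <- c(skipped, fn)
  }
  if (length(skipped))
    warning("non-positive values, passed through untransformed: ",
            paste(skipped, collapse = ", "))
  attr(t, "transform_state") <- "logged"
  attr(t, "untransformed") <- skipped
  t
}

#' Location/scale site harmonization
#'
#' Removes site differences per feature by standardizing each site's
#' values with the site mean/SD and rescaling to the pooled mean/SD
#' (location/scale adjustment in the spirit of ComBat, without empirical
#' Bayes shrinkage). After harmonization every site's feature mean equals
#' the grand mean.
#'
#' @param t a logged [feature_table()].
#' @return The harmonized table.
#' @export
harmonize_sites <- function(t) {
  stopifnot(inherits(t, "feature_table"))
  if (attr(t, "transform_state") != "logged")
    stop("harmonization expects a logged table")
  sites <- unique(t$site)
  if (length(sites) > 1L) {
    counts <- table(t$site)
    if (any(counts < 3L))
      stop("every site needs >= 3 rows for harmonization")
    for (fn in feature_names()) {
      v <- t[[fn]]
      gm <- mean(v, na.rm = TRUE); gs <- sd(v, na.rm = TRUE)
      for (s in sites) {
        i <- t$site == s
        ms <- mean(v[i], na.rm = TRUE); ss <- sd(v[i], na.rm = TRUE)
        v[i] <- if (is.finite(ss) && ss > 0) (v[i] - ms) / ss * gs + gm else gm
      }
      t[[fn]] <- v
    }
  }
  attr(t, "transform_state") <- "harmonized"
  t
}
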