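# Raw belt recording -> breath-by-breath rate and amplitude series:
# zero-phase band-pass, zero-crossing extrema detection with small-excursion
# pruning, then peak-to-peak rates and peak-minus-trough amplitudes.

#' Zero-phase band-pass filter for a belt recording
#'
#' Second-order Butterworth band-pass applied forward-backward
#' (zero phase, so extrema timing is preserved). The pass band default
#' (0.05-3 Hz) brackets human breathing and removes drift and
#' high-frequency noise; the DC component is removed.
#'
#' @param rec a [breath_recording()].
#' @param low,high band edges in Hz.
#' @return Numeric vector, same length as the input samples.
#' @export
bandpass_filter <- function(rec, low = 0.05, high = 3.0) {
  stopifnot(inherits(rec, "breath_recording"))
  fs <- rec$fs
  if (!(low > 0 && low < high)) stop("need 0 < low < high")
  if (high >= fs / 2) stop("high cut-off at or above Nyquist (fs/2)")
  n <- length(rec$samples)
  if (n / fs <= 3 / low)
    stop("recording too short for stable filtering at low = ", low, " Hz")
  bf <- signal::butter(2, c(low, high) / (fs / 2), type = "pass")
  x <- rec$samples - mean(rec$samples)
  y <- as.numeric(signal::filtfilt(bf, x))
  y - mean(y)   # edge transients leave a residual mean; remove it exactly
}

#' Detect breath peaks and troughs by zero crossings
#'
#' On the zero-mean filtered signal, the maximum between each upward and
#' the next downward zero crossing is an inhalation peak, and the minimum
#' between a downward and the next upward crossing an exhalation trough.
#' Peak-trough pairs whose vertical distance falls below
#' `amp_min_frac` x the median pair distance are pruned as sub-breath
#' ripples and alternation is re-enforced (adjacent same-kind extrema
#' collapse to the more extreme one).
#'
#' @param filtered zero-mean filtered sample vector.
#' @param fs sampling rate in Hz.
#' @param amp_min_frac pruning threshold as a fraction of the median
#'   peak-trough distance.
#' @return A `breath_events` list with `peak_indices`, `trough_indices`
#'   (1-based sample indices) and `n_pruned`.
#' @export
detect_breath_extrema <- function(filtered, fs, amp_min_frac = 0.3) {
  x <- as.numeric(filtered)
  if (sd(x) == 0) stop("no zero crossings: signal has zero variance")
  s <- sign(x)
  s[s == 0] <- 1
  flip <- which(diff(s) != 0)            # crossing between flip and flip+1
  up <- flip[s[flip] < 0]
  down <- flip[s[flip] > 0]
  if (length(up) < 2L || length(down) < 2L)
    stop("fewer than 2 detected breaths")

  # walk crossings in order, recording one extremum per half-cycle; the
  # partial segments before the first and after the last crossing also
  # contribute an extremum so edge breaths keep their trough/peak pair
  cr <- sort(c(up, down))
  kind <- ifelse(cr %in% up, "up", "down")
  idx <- integer(0); typ <- character(0)
  if (cr[1L] > 1L) {
    seg <- x[1:cr[1L]]
    if (kind[1L] == "up") { idx <- which.min(seg); typ <- "trough" }
    else { idx <- which.max(seg); typ <- "peak" }
  }
  for (i in seq_len(length(cr) - 1L)) {
    a <- cr[i] + 1L; b <- cr[i + 1L]
    seg <- x[a:b]
    if (kind[i] == "up") {               # rising segment holds a peak
      idx <- c(idx, a - 1L + which.max(seg)); typ <- c(typ, "peak")
    } else {
      idx <- c(idx, a - 1L + which.min(seg)); typ <- c(typ, "trough")
    }
  }
  last <- cr[length(cr)]
  if (last < length(x)) {
    seg <- x[(last + 1L):length(x)]
    if (kind[length(cr)] == "up") {
      idx <- c(idx, last + which.max(seg)); typ <- c(typ, "peak")
    } else {
      idx <- c(idx, last + which.min(seg)); typ <- c(typ, "trough")
    }
  }

  ev <- prune_small_excursions(idx, typ, x, amp_min_frac)
  idx <- ev$idx; typ <- ev$typ

  # start with a trough, end cleanly; counts differ by at most 1
  if (length(typ) && typ[1L] == "peak") { idx <- idx[-1L]; typ <- typ[-1L] }
  if (sum(typ == "peak") < 2L) stop("fewer than 2 detected breaths")

  # sub-sample refinement: quadratic vertex fit around each extremum
  # suppresses sample noise on the flat breath tops
  h <- max(2L, round(0.4 * median(diff(cr))))
  ref <- refine_extrema(x, idx, typ, h)
  is_pk <- typ == "peak"
  structure(list(peak_indices = idx[is_pk],
                 trough_indices = idx[!is_pk],
                 peak_pos = ref$pos[is_pk], trough_pos = ref$pos[!is_pk],
                 peak_val = ref$val[is_pk], trough_val = ref$val[!is_pk],
                 n_pruned = ev$n_pruned, fs = fs),
            class = "breath_events")
}

# sub-sample extremum refinement: tricube-weighted parabola vertex over
# idx +/- h, which suppresses sample noise on the flat breath tops; the
# height comes from an unweighted quadratic fit (harder noise averaging).
# The window is kept narrow (h ~ 0.4 half-cycles) so unequal inhale and
# exhale durations do not bias the vertex. Falls back to the raw sample
# extremum when the fit curves the wrong way or the vertex escapes the
# window. Projection matrices for the full window are precomputed.
refine_extrema <- function(x, idx, typ, h) {
  n <- length(x)
  pos <- as.numeric(idx); val <- x[idx]
  proj <- function(tt, weighted) {
    X <- cbind(1, tt, tt^2)
    w <- if (weighted) (1 - pmin(abs(tt) / (h + 1), 1)^3)^3
         else rep(1, length(tt))
    solve(crossprod(X, w * X), t(w * X))
  }
  tt_full <- (-h):h
  P2w <- proj(tt_full, TRUE)
  P2 <- proj(tt_full, FALSE)
  for (i in seq_along(idx)) {
    a <- max(1L, idx[i] - h); b <- min(n, idx[i] + h)
    if (b - a < 4L) next
    full <- b - a == 2L * h
    tt <- (a:b) - idx[i]
    cf <- if (full) drop(P2w %*% x[a:b]) else drop(proj(tt, TRUE) %*% x[a:b])
    curv_ok <- if (typ[i] == "peak") cf[3L] < 0 else cf[3L] > 0
    if (!is.na(curv_ok) && curv_ok) {
      v <- -cf[2L] / (2 * cf[3L])
      if (abs(v) <= h) {
        pos[i] <- idx[i] + v
        cu <- if (full) drop(P2 %*% x[a:b])
              else drop(proj(tt, FALSE) %*% x[a:b])
        val[i] <- cu[1L] + cu[2L] * v + cu[3L] * v^2
      }
    }
  }
  list(pos = pos, val = val)
}

# Remove peak-trough pairs with sub-threshold vertical excursion, then
# collapse adjacent same-kind extrema (keep the more extreme).
prune_small_excursions <- function(idx, typ, x, amp_min_frac) {
  n_pruned <- 0L
  repeat {
    # collapse duplicates first so distances are between true neighbours
    repeat {
      same <- which(typ[-1L] == typ[-length(typ)])
      if (!length(same)) break
      i <- same[1L]
      drop <- if (typ[i] == "peak") {
        if (x[idx[i]] >= x[idx[i + 1L]]) i + 1L else i
      } else {
        if (x[idx[i]] <= x[idx[i + 1L]]) i + 1L else i
      }
      idx <- idx[-drop]; typ <- typ[-drop]
    }
    if (length(idx) < 4L) break
    d <- abs(diff(x[idx]))               # vertical distance between neighbours
    med <- median(d)
    bad <- which(d < amp_min_frac * med)
    if (!length(bad)) break
    i <- bad[which.min(d[bad])]          # prune the smallest excursion pair
    idx <- idx[-c(i, i + 1L)]; typ <- typ[-c(i, i + 1L)]
    n_pruned <- n_pruned + 1L
  }
  list(idx = idx, typ = typ, n_pruned = n_pruned)
}

#' Per-breath rate and amplitude series
#'
#' For consecutive peaks at times t_i, t_{i+1} the instantaneous rate is
#' 60/(t_{i+1} - t_i) breaths/min, assigned to the later peak; the
#' amplitude of a peak is its value minus the immediately preceding trough
#' value. Both series are aligned on peaks 2..n.
#'
#' @param filtered filtered sample vector.
#' @param events a `breath_events` from [detect_breath_extrema()].
#' @param fs sampling rate in Hz.
#' @return A `breath_series` list with `rate` (breaths/min), `amplitude`
#'   (a.u.) and `breath_times` (seconds, peaks 2..n).
#' @export
extract_breath_series <- function(filtered, events, fs) {
  pk <- events$peak_indices
  tr <- events$trough_indices
  if (length(pk) < 3L) stop("need at least 3 peaks")
  # use sub-sample positions/values when the detector provides them
  pk_pos <- if (!is.null(events$peak_pos)) events$peak_pos else as.numeric(pk)
  pk_val <- if (!is.null(events$peak_val)) events$peak_val else filtered[pk]
  tr_val <- if (!is.null(events$trough_val)) events$trough_val
            else filtered[tr]
  pt <- (pk_pos - 1) / fs
  iv <- diff(pt)
  if (any(iv <= 0)) stop("non-positive breath interval")
  rate <- 60 / iv
  amp <- vapply(seq_along(pk)[-1L], function(i) {
    prev <- which(tr < pk[i])
    if (!length(prev)) return(NA_real_)
    pk_val[i] - tr_val[max(prev)]
  }, numeric(1))
  if (anyNA(amp) || any(amp <= 0))
    stop("non-positive breath amplitude after filtering")
  structure(list(rate = rate, amplitude = amp, breath_times = pt[-1L]),
            class = "breath_series")
}

#' @export
print.breath_series <- function(x, ...) {
  cat(sprintf("<breath_series> %d breaths, rate %.1f-%.1f bpm\n",
              length(x$rate), min(x$rate), max(x$rate)))
  invisible(x)
}

#' Recording-quality summary for a breath series
#'
#' @param series a `breath_series`.
#' @param min_breaths flag threshold (recordings shorter than this are
#'   unreliable for entropy estimation).
#' @return list with `n_breaths`, `rate_range`, and `flags`.
#' @export
quality_summary <- function(series, min_breaths = 20) {
  n <- length(series$rate)
  flags <- character(0)
  if (n < min_breaths) flags <- c(flags, "short recording")
  list(n_breaths = n,
       rate_range = if (n) range(series$rate) else c(NA_real_, NA_real_),
       flags = flags)
}

#' Export detected events as a long data.frame
#'
#' @param events a `breath_events`.
#' @param filtered the filtered signal the events index into.
#' @param subject,condition metadata columns.
#' @return data.frame `subject, condition, kind, index, time_s, value`.
#' @export
events_table <- function(events, filtered, subject = "s1", condition = "rest") {
  idx <- c(events$peak_indices, events$trough_indices)
  kind <- rep(c("peak", "trough"),
              c(length(events$peak_indices), length(events$trough_indices)))
  o <- order(idx)
  data.frame(subject = subject, condition = condition, kind = kind[o],
             index = idx[o], time_s = (idx[o] - 1) / events$fs,
             value = filtered[idx[o]])
}
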