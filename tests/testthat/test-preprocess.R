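# Band-pass filtering, zero-crossing extrema detection, breath series.

make_rec <- function(x, fs = 10) breath_recording(x, fs = fs)

test_that("in-band sinusoids pass with little attenuation", {
  tt <- (0:2999) / 10
  rec <- make_rec(sin(2 * pi * 0.25 * tt))
  y <- bandpass_filter(rec)
  mid <- 500:2500   # away from edge transients
  expect_gt(max(y[mid]), 0.95)
  expect_lt(abs(mean(y)), 1e-6 * sd(rec$samples))
})

test_that("a constant offset is removed entirely", {
  rec <- make_rec(rep(3.7, 1000))
  y <- bandpass_filter(rec)
  expect_lt(max(abs(y)), 1e-8)
})

test_that("filter preconditions are enforced", {
  rec <- make_rec(rnorm(1000))
  expect_error(bandpass_filter(rec, high = 5), "Nyquist")
  expect_error(bandpass_filter(rec, low = 0.3, high = 0.1), "low < high")
  expect_error(bandpass_filter(make_rec(rnorm(100))), "too short")
})

test_that("a 60 s breathing-band sinusoid yields 15 alternating breaths", {
  tt <- seq(0, 60 - 0.1, by = 0.1)
  x <- -cos(2 * pi * 0.25 * tt)   # starts at a trough
  ev <- detect_breath_extrema(x, 10)
  expect_length(ev$peak_indices, 15)
  # boundary troughs at both edges may both be kept
  expect_true(length(ev$trough_indices) %in% 15:16)
  # strict alternation starting with a trough
  idx <- sort(c(ev$peak_indices, ev$trough_indices))
  kinds <- ifelse(idx %in% ev$peak_indices, "p", "t")
  expect_equal(kinds[1], "t")
  expect_true(all(kinds[-1] != kinds[-length(kinds)]))
  # every peak sits above its neighbouring troughs
  expect_true(all(x[ev$peak_indices] > 0.9))
  expect_true(all(x[ev$trough_indices] < -0.9))
})

test_that("constant signals have no zero crossings", {
  expect_error(detect_breath_extrema(rep(0, 100), 10), "zero variance")
})

test_that("sub-threshold ripples are pruned without losing breaths", {
  tt <- seq(0, 60 - 0.1, by = 0.1)
  x <- -cos(2 * pi * 0.25 * tt)
  # a brief dip across the zero line creates a spurious extremum pair
  ripple <- -0.6 * exp(-((tt - 21.4) / 0.2)^2)
  ev0 <- detect_breath_extrema(x, 10)
  ev <- detect_breath_extrema(x + ripple, 10, amp_min_frac = 0.3)
  expect_gte(ev$n_pruned, 1)
  expect_length(ev$peak_indices, length(ev0$peak_indices))
  expect_length(ev$trough_indices, length(ev0$trough_indices))
})

test_that("rates and amplitudes follow the peak/trough geometry", {
  # peaks at t = 0, 5, 10 s with unit peaks and -1 troughs
  filtered <- rep(0, 120)
  pk <- c(1L, 51L, 101L); tr <- c(26L, 76L)
  filtered[pk] <- 1; filtered[tr] <- -1
  ev <- structure(list(peak_indices = pk, trough_indices = tr, fs = 10),
                  class = "breath_events")
  ser <- extract_breath_series(filtered, ev, 10)
  expect_equal(ser$rate, c(12, 12))
  expect_equal(ser$amplitude, c(2, 2))
  expect_equal(ser$breath_times, c(5, 10))
})

test_that("planted per-breath rates are recovered within 0.5 bpm", {
  w <- waveform_from_rates(c(10, 10, 12, 15, 12), fs = 10)
  ev <- detect_breath_extrema(w$wave, 10)
  ser <- extract_breath_series(w$wave, ev, 10)
  expect_equal(length(ser$rate), 4)
  expect_true(all(abs(ser$rate - c(10, 12, 15, 12)) < 0.5))
})

test_that("noise-free planted waveforms round-trip peak times exactly", {
  p <- breathdyn:::condition_params("rest")
  p$noise_sd <- 0
  g <- gen_breathing_signal(p, seed = 5)
  filt <- bandpass_filter(g$recording)
  ev <- detect_breath_extrema(filt, 10)
  expect_equal(length(ev$peak_indices), g$truth$n_breaths)
  det_t <- (ev$peak_indices - 1) / 10
  expect_lt(max(abs(det_t - g$truth$peak_times)), 0.1 + 1e-9)  # 1 sample
})

test_that("alternation invariant holds on noisy recordings", {
  p <- breathdyn:::condition_params("rest")
  for (s in 1:3) {
    g <- gen_breathing_signal(p, seed = s)
    filt <- bandpass_filter(g$recording)
    ev <- detect_breath_extrema(filt, 10)
    idx <- sort(c(ev$peak_indices, ev$trough_indices))
    kinds <- ifelse(idx %in% ev$peak_indices, "p", "t")
    expect_true(all(kinds[seq_along(kinds) %% 2 == 1] == "t"))
    expect_true(all(kinds[seq_along(kinds) %% 2 == 0] == "p"))
    expect_lte(abs(length(ev$peak_indices) - length(ev$trough_indices)), 1)
    # every peak strictly above the next trough
    for (i in seq_along(ev$peak_indices)) {
      nxt <- ev$trough_indices[ev$trough_indices > ev$peak_indices[i]]
      if (length(nxt))
        expect_gt(filt[ev$peak_indices[i]], filt[nxt[1]])
    }
  }
})

test_that("rate and amplitude recovery meets tolerance on noisy cohorts", {
  errs <- c(); cors <- c()
  for (cond in c("rest", "task")) {
    p <- breathdyn:::condition_params(cond)
    for (s in 1:3) {
      g <- gen_breathing_signal(p, seed = s)
      filt <- bandpass_filter(g$recording)
      ev <- detect_breath_extrema(filt, 10)
      ser <- extract_breath_series(filt, ev, 10)
      pk_t <- ser$breath_times
      j <- vapply(pk_t, function(t) which.min(abs(g$truth$peak_times - t)),
                  integer(1))
      errs <- c(errs, mean(abs(ser$rate - g$truth$rate[j - 1])))
      cors <- c(cors, cor(ser$amplitude, g$truth$amplitude[j - 1]))
    }
  }
  expect_lt(mean(errs), 0.5)
  expect_gt(mean(cors), 0.95)
})

test_that("quality summaries flag short recordings", {
  p <- breathdyn:::condition_params("rest")
  p$base_rate <- 15; p$phi <- 0; p$rate_innov_sd <- 0; p$rate_jitter_sd <- 0
  g <- gen_breathing_signal(p, seed = 1)
  filt <- bandpass_filter(g$recording)
  ser <- extract_breath_series(filt, detect_breath_extrema(filt, 10), 10)
  qs <- quality_summary(ser)
  expect_equal(qs$n_breaths, 74, tolerance = 0.03)  # ~75 breaths in 5 min
  expect_length(qs$flags, 0)

  short <- list(rate = rep(15, 14), amplitude = rep(1, 14),
                breath_times = seq_len(14) * 4)
  expect_match(quality_summary(short)$flags, "short")
  empty <- list(rate = numeric(0), amplitude = numeric(0),
                breath_times = numeric(0))
  expect_equal(quality_summary(empty)$n_breaths, 0)
  expect_match(quality_summary(empty)$flags, "short")
})

test_that("events export carries both kinds in time order", {
  tt <- seq(0, 60 - 0.1, by = 0.1)
  x <- -cos(2 * pi * 0.25 * tt)
  ev <- detect_breath_extrema(x, 10)
  tab <- events_table(ev, x, subject = "a", condition = "rest")
  expect_true(!is.unsorted(tab$index))
  expect_setequal(unique(tab$kind), c("peak", "trough"))
  expect_equal(tab$value, x[tab$index])
})
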