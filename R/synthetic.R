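# Ground-truthed generators: AR(1) and power-law noise oracles, belt-like
# breathing waveforms with planted per-breath rates/amplitudes, latent-
# coupled blocks, and a full synthetic cohort emulating the study design
# (5-min rest, ~30-min task, rest->task shifts, BAI and N-back outcomes
# coupled to planted breathing traits).

#' Stationary AR(1) series
#'
#' x_t = phi x_\{t-1\} + e_t with unit-variance Gaussian innovations and a
#' stationary initial draw, so acf(k) = phi^k from the first sample.
#'
#' @param phi autoregressive coefficient, |phi| < 1.
#' @param n length.
#' @param seed RNG seed.
#' @param innov_sd innovation SD.
#' @return Numeric vector of length n.
#' @export
gen_ar1_series <- function(phi, n, seed = 1, innov_sd = 1) {
  if (abs(phi) >= 1) stop("|phi| must be < 1")
  set.seed(seed)
  x <- numeric(n)
  x[1L] <- rnorm(1, sd = innov_sd / sqrt(1 - phi^2))
  e <- rnorm(n - 1L, sd = innov_sd)
  for (t in 2:n) x[t] <- phi * x[t - 1L] + e[t - 1L]
  x
}

#' Power-law (1/f^beta) noise by spectral synthesis
#'
#' Fourier amplitudes proportional to f^(-beta/2) with uniform random
#' phases, inverse-transformed and standardized to zero mean and unit
#' variance, so the planted log-log PSD slope is exactly -beta.
#'
#' @param beta power-law exponent, 0 <= beta <= 3.
#' @param n length, >= 64.
#' @param seed RNG seed.
#' @return Numeric vector of length n.
#' @export
gen_powerlaw_series <- function(beta, n, seed = 1) {
  stopifnot(beta >= 0, beta <= 3, n >= 64)
  set.seed(seed)
  half <- floor(n / 2)
  f <- (1:half) / n
  amp <- f^(-beta / 2)
  ph <- runif(half, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = ph)
  full <- complex(real = numeric(n))
  full[2:(half + 1L)] <- spec
  # conjugate symmetry for a real signal; Nyquist bin kept real when n even
  if (n %% 2 == 0) {
    full[half + 1L] <- complex(real = amp[half] * cos(ph[half]))
    if (half > 1L) full[n:(half + 2L)] <- Conj(spec[1:(half - 1L)])
  } else {
    full[n:(half + 2L)] <- Conj(spec[seq_len(half)])
  }
  x <- Re(fft(full, inverse = TRUE)) / n
  as.numeric(scale(x))
}

# default per-condition generative parameters: the study conditions the
# generator emulates (5-min rest, ~30-min task at 10 Hz; task breathing is
# faster, shallower, more variable and more irregular than rest)
condition_params <- function(condition = c("rest", "task")) {
  condition <- match.arg(condition)
  if (condition == "rest")
    list(duration = 300, fs = 10, base_rate = 14, phi = 0.93,
         rate_innov_sd = 0.40, rate_jitter_sd = 0.08, rate_pink_sd = 0,
         amp_mean = 1.0, amp_phi = 0.9, amp_innov_rel = 0.05,
         amp_jitter_rel = 0.015, amp_pink_rel = 0, noise_sd = 0.05)
  else
    list(duration = 1800, fs = 10, base_rate = 17, phi = 0.35,
         rate_innov_sd = 0.60, rate_jitter_sd = 0.85, rate_pink_sd = 0.90,
         amp_mean = 0.75, amp_phi = 0.5, amp_innov_rel = 0.09,
         amp_jitter_rel = 0.06, amp_pink_rel = 0.10, noise_sd = 0.05)
}

#' Synthetic cohort specification
#'
#' Bundles the generator parameters for a study-like cohort: paired
#' rest/task recordings per subject, site location offsets, between-
#' subject trait latents (a variability scale coupled to working-memory
#' efficiency, an irregularity scale coupled to anxiety), and the
#' coupling strengths.
#'
#' @param n_subjects number of subjects.
#' @param sites data.frame with `site`, `rate_offset` (bpm added to the
#'   base rate) and `amp_scale` (multiplier on amplitude); subjects are
#'   assigned round-robin.
#' @param rest,task per-condition generative parameter lists
#'   (see `condition_params`).
#' @param sigma_variability log-SD of the between-subject variability
#'   scale (multiplies the rate innovation and jitter SDs).
#' @param sigma_irregularity log-SD of the between-subject irregularity
#'   scale (multiplies the rest white-jitter SD).
#' @param anxiety_coupling correlation between the irregularity latent
#'   and the BAI latent.
#' @param efficiency_coupling standardized drop in log-efficiency per SD
#'   of the variability latent (negative latent effect).
#' @param trials_per_load N-back trials generated per subject x load.
#' @param seed master RNG seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 51,
                        sites = data.frame(site = "site1", rate_offset = 0,
                                           amp_scale = 1),
                        rest = condition_params("rest"),
                        task = condition_params("task"),
                        sigma_variability = 0.35,
                        sigma_irregularity = 0.45,
                        anxiety_coupling = 0.65,
                        efficiency_coupling = 0.55,
                        trials_per_load = 80,
                        seed = 1) {
  stopifnot(n_subjects >= 1, rest$duration >= 120, task$duration >= 120,
            abs(rest$phi) < 1, abs(task$phi) < 1)
  structure(list(n_subjects = n_subjects, sites = sites, rest = rest,
                 task = task, sigma_variability = sigma_variability,
                 sigma_irregularity = sigma_irregularity,
                 anxiety_coupling = anxiety_coupling,
                 efficiency_coupling = efficiency_coupling,
                 trials_per_load = trials_per_load, seed = seed),
            class = "cohort_spec")
}

#' Generate one belt-like breathing recording with planted ground truth
#'
#' Per-breath rates follow base_rate + AR(1) + white jitter (clipped to
#' 4-60 bpm); peak times are planted so the interval ending at peak i is
#' exactly 60/rate_i seconds. The waveform interpolates alternating
#' trough/peak extrema with half-cosine segments (troughs at minus half
#' the breath amplitude, peaks at plus half), then adds white Gaussian
#' noise — so planted peak times and peak-minus-trough amplitudes are
#' exact by construction.
#'
#' @param params per-condition parameter list (see `condition_params`).
#' @param seed RNG seed.
#' @param subject_id,condition,site_id metadata for the recording.
#' @return list with `recording` (a [breath_recording()]) and `truth`
#'   (planted `peak_times`, `rate`, `amplitude` aligned on peaks 2..n,
#'   `n_breaths`, `n_clipped`).
#' @export
gen_breathing_signal <- function(params, seed = 1, subject_id = "s1",
                                 condition = "rest", site_id = "site1") {
  set.seed(seed)
  fs <- params$fs; dur <- params$duration
  n_max <- ceiling(dur / 60 * (params$base_rate + 15)) + 5L
  ar <- numeric(n_max)
  ar[1L] <- rnorm(1, sd = params$rate_innov_sd / sqrt(1 - params$phi^2))
  e <- rnorm(n_max - 1L, sd = params$rate_innov_sd)
  for (t in 2:n_max) ar[t] <- params$phi * ar[t - 1L] + e[t - 1L]
  pink_sd <- if (is.null(params$rate_pink_sd)) 0 else params$rate_pink_sd
  pink <- if (pink_sd > 0)
    pink_sd * gen_powerlaw_series(1, max(64L, n_max),
                                  seed = sample.int(2^30, 1))[seq_len(n_max)]
  else 0
  rate <- params$base_rate + ar + pink +
    rnorm(n_max, sd = params$rate_jitter_sd)
  n_clipped <- sum(rate <= 4 | rate >= 60)
  rate <- pmin(pmax(rate, 4), 60)

  am <- numeric(n_max)
  am[1L] <- rnorm(1, sd = params$amp_innov_rel / sqrt(1 - params$amp_phi^2))
  ea <- rnorm(n_max - 1L, sd = params$amp_innov_rel)
  for (t in 2:n_max) am[t] <- params$amp_phi * am[t - 1L] + ea[t - 1L]
  apink_rel <- if (is.null(params$amp_pink_rel)) 0 else params$amp_pink_rel
  apink <- if (apink_rel > 0)
    apink_rel * gen_powerlaw_series(1, max(64L, n_max),
                                    seed = sample.int(2^30, 1))[seq_len(n_max)]
  else 0
  amp <- params$amp_mean *
    pmax(1 + am + apink + rnorm(n_max, sd = params$amp_jitter_rel), 0.2)

  # plant peak times: interval ending at peak i is 60/rate_i
  pk <- cumsum(c(30 / rate[1L], 60 / rate[-1L]))
  keep <- pk <= dur - 1 / fs
  if (sum(keep) < 4L) stop("duration too short for the planted rates")
  pk <- pk[keep]; rate <- rate[keep]; amp <- amp[keep]
  nb <- length(pk)

  # alternating extrema: leading trough, peak_i, inter-peak troughs, tail
  tr_t <- c(max(0, pk[1L] - 30 / rate[1L]),
            (pk[-nb] + pk[-1L]) / 2,
            min(dur, pk[nb] + 30 / rate[nb]))
  ex_t <- c(rbind(tr_t[seq_len(nb)], pk), tr_t[nb + 1L])
  ex_v <- c(rbind(-amp / 2, amp / 2), -amp[nb] / 2)

  tt <- (seq_len(round(dur * fs)) - 1L) / fs
  j <- findInterval(tt, ex_t, all.inside = TRUE)
  frac <- (tt - ex_t[j]) / (ex_t[j + 1L] - ex_t[j])
  frac <- pmin(pmax(frac, 0), 1)
  wave <- ex_v[j] + (ex_v[j + 1L] - ex_v[j]) * (1 - cos(pi * frac)) / 2
  wave <- wave + rnorm(length(wave), sd = params$noise_sd)

  rec <- breath_recording(wave, fs = fs, subject_id = subject_id,
                          condition = condition, site_id = site_id)
  list(recording = rec,
       truth = list(peak_times = pk, rate = rate[-1L], amplitude = amp[-1L],
                    n_breaths = nb, n_clipped = n_clipped))
}

#' Latent-coupled data blocks for PLSC validation
#'
#' X = sum_k sqrt(strength_k) z_k a_k' + noise and likewise for Y, with
#' shared standard-normal latent scores z_k and unit-norm, mutually
#' orthogonal salience vectors, so the cross-block covariance of latent k
#' is proportional to strength_k and the squared-singular-value
#' proportions recover strengths^2 up to z-scoring attenuation.
#'
#' @param n rows; `p`, `q` block widths.
#' @param x_saliences,y_saliences p x k and q x k matrices of planted
#'   saliences (columns unit-norm, orthogonal).
#' @param strengths length-k latent strengths.
#' @param noise_sd SD of the additive Gaussian noise.
#' @param seed RNG seed.
#' @return list with `X`, `Y`, and `truth` (latent scores, saliences,
#'   strengths).
#' @export
gen_coupled_blocks <- function(n, p, q, x_saliences, y_saliences,
                               strengths, noise_sd = 1, seed = 1) {
  A <- as.matrix(x_saliences); B <- as.matrix(y_saliences)
  k <- length(strengths)
  stopifnot(nrow(A) == p, nrow(B) == q, ncol(A) == k, ncol(B) == k)
  gram <- function(M) max(abs(crossprod(M) - diag(k)))
  if (gram(A) > 1e-8 || gram(B) > 1e-8)
    stop("salience columns must be unit-norm and mutually orthogonal")
  if (any(strengths < 0)) stop("strengths must be non-negative")
  set.seed(seed)
  Z <- matrix(rnorm(n * k), n, k)
  X <- Z %*% (sqrt(strengths) * t(A)) +
    matrix(rnorm(n * p, sd = noise_sd), n, p)
  Y <- Z %*% (sqrt(strengths) * t(B)) +
    matrix(rnorm(n * q, sd = noise_sd), n, q)
  colnames(X) <- paste0("x", seq_len(p)); colnames(Y) <- paste0("y", seq_len(q))
  list(X = X, Y = Y,
       truth = list(scores = Z, x_saliences = A, y_saliences = B,
                    strengths = strengths))
}

# BAI items: discretized monotone transform of a Gaussian latent, thresholds
# chosen so a subclinical sample mostly scores 0-1 per item
bai_items_from_latent <- function(latent, n_items = 21) {
  n <- length(latent)
  z <- matrix(0.8 * rep(latent, n_items) + 0.6 * rnorm(n * n_items),
              n, n_items)
  items <- matrix(cut(z, c(-Inf, 0.4, 1.3, 2.2, Inf), labels = FALSE) - 1L,
                  n, n_items)
  colnames(items) <- paste0("item_", seq_len(n_items))
  items
}

#' Generate a full synthetic study bundle
#'
#' Rest and task recordings per subject with planted rest->task shifts
#' (task: faster, shallower, more variable, whiter/more irregular
#' breathing), BAI item scores coupled to a between-subject breathing-
#' irregularity latent, and N-back trials whose efficiency is negatively
#' coupled to a between-subject breathing-variability latent. Sites add
#' planted rate/amplitude offsets. Deterministic given the spec seed.
#'
#' @param spec a [cohort_spec()].
#' @return list with `recordings` (list of [breath_recording()]),
#'   `anxiety` (data.frame), `behavior` (trial data.frame), and `truth`
#'   (per-recording planted series, subject latents, planted paired-shift
#'   signs in the rest-minus-task convention, coupling targets).
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  subjects <- sprintf("sub%03d", seq_len(n))
  site_idx <- rep(seq_len(nrow(spec$sites)), length.out = n)

  z_var <- rnorm(n)     # variability latent -> sd/cv and low efficiency
  z_irr <- rnorm(n)     # irregularity latent -> entropy/complexity and BAI
  var_scale <- exp(spec$sigma_variability * z_var)
  irr_scale <- exp(spec$sigma_irregularity * z_irr)
  # per-subject smoothness heterogeneity so timescale features vary; the
  # irregularity latent makes resting breathing less smooth (whiter)
  phi_rest <- pmin(0.965, pmax(0.80, 0.93 - 0.035 * z_irr + runif(n, -0.015, 0.015)))
  phi_task <- runif(n, 0.38, 0.62)
  aphi_rest <- pmin(0.95, pmax(0.75, 0.90 - 0.035 * z_irr + runif(n, -0.02, 0.02)))
  aphi_task <- runif(n, 0.38, 0.68)
  rec_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n)

  recordings <- vector("list", 2L * n)
  truth_rec <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    st <- spec$sites[site_idx[i], ]
    for (ci in 1:2) {
      cond <- c("rest", "task")[ci]
      par <- if (cond == "rest") spec$rest else spec$task
      par$phi <- if (cond == "rest") phi_rest[i] else phi_task[i]
      par$amp_phi <- if (cond == "rest") aphi_rest[i] else aphi_task[i]
      par$base_rate <- par$base_rate + st$rate_offset
      par$amp_mean <- par$amp_mean * st$amp_scale
      par$rate_innov_sd <- par$rate_innov_sd * var_scale[i]
      par$rate_jitter_sd <- par$rate_jitter_sd * var_scale[i]
      par$rate_pink_sd <- par$rate_pink_sd * var_scale[i]
      if (cond == "rest")
        par$rate_jitter_sd <- par$rate_jitter_sd * irr_scale[i]
      g <- gen_breathing_signal(par, seed = rec_seeds[2L * (i - 1L) + ci],
                                subject_id = subjects[i], condition = cond,
                                site_id = as.character(st$site))
      recordings[[2L * (i - 1L) + ci]] <- g$recording
      truth_rec[[2L * (i - 1L) + ci]] <- g$truth
    }
  }

  # anxiety block: BAI latent correlated with the irregularity latent
  bai_latent <- spec$anxiety_coupling * z_irr +
    sqrt(1 - spec$anxiety_coupling^2) * rnorm(n)
  items <- bai_items_from_latent(bai_latent)
  anxiety <- data.frame(subject = subjects, bai_total = rowSums(items))
  anxiety <- cbind(anxiety, as.data.frame(items))

  # behavior: planted efficiency drops with load and with the variability
  # latent; trials realized around the planted accuracy and mean RT
  base_acc <- c(0.95, 0.86, 0.76)
  base_rt <- c(0.55, 0.70, 0.85)
  behavior <- vector("list", 3L * n)
  planted_eff <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    for (l in 1:3) {
      eff <- base_acc[l] / base_rt[l] *
        exp(-spec$efficiency_coupling * z_var[i] + 0.12 * rnorm(1))
      planted_eff[i, l] <- eff
      acc <- min(0.98, max(0.4, base_acc[l] + 0.03 * rnorm(1)))
      mrt <- acc / eff
      nt <- spec$trials_per_load
      correct <- rbinom(nt, 1, acc)
      rt <- mrt * exp(rnorm(nt, -0.03, 0.25))  # ~lognormal, mean ~ mrt
      behavior[[3L * (i - 1L) + l]] <- data.frame(
        subject = subjects[i], load = l,
        speed = rep(c("slow", "fast"), length.out = nt),
        correct = correct, rt = rt)
    }
  }
  behavior <- do.call(rbind, behavior)

  # planted rest-minus-task direction per feature (sign of the expected t)
  planted_signs <- c(mean_rate = -1, mean_amp = 1, sd_rate = -1,
                     acw50_rate = 1, psd_slope_rate = 1, lzc_rate = -1,
                     sampen_rate = -1, mse_rate = -1)

  list(recordings = recordings, anxiety = anxiety, behavior = behavior,
       truth = list(subjects = subjects, site = spec$sites$site[site_idx],
                    z_variability = z_var, z_irregularity = z_irr,
                    recordings = truth_rec, planted_eff = planted_eff,
                    planted_signs = planted_signs,
                    efficiency_target_features = c("sd_rate", "cv_rate")))
}

#' Feature table for a list of recordings
#'
#' Runs [extract_features()] over every recording and stacks the rows
#' into a raw [feature_table()]. Recordings that fail extraction are
#' dropped with a warning (listwise exclusion).
#'
#' @param recordings list of [breath_recording()].
#' @param ... passed to [extract_features()].
#' @return A raw [feature_table()].
#' @export
cohort_features <- function(recordings, ...) {
  rows <- lapply(recordings, function(r) {
    tryCatch(extract_features(r, ...), error = function(e) {
      warning("dropped ", r$subject_id, "/", r$condition, ": ",
              conditionMessage(e))
      NULL
    })
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no recording could be processed")
  feature_table(do.call(rbind, rows))
}
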