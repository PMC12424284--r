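# Independent brute-force oracles and small fixture builders used across
# the suite. All oracles are written from the definitions, not from the
# package implementation.

# literal LZ76 exhaustive parsing via substring search: a phrase grows
# until it is no longer reproducible from the prior history; the trailing
# reproducible phrase is not counted
lz76_oracle <- function(bits) {
  s <- paste(bits, collapse = "")
  n <- nchar(s)
  c <- 0L; l <- 1L
  while (l <= n) {
    k <- 1L
    repeat {
      pe <- l + k - 1L
      if (pe > n) return(c)
      hist <- substr(s, 1, pe - 1L)
      phrase <- substr(s, l, pe)
      if (!grepl(phrase, hist, fixed = TRUE)) {
        c <- c + 1L; l <- pe + 1L; break
      }
      k <- k + 1L
    }
  }
  c
}

# O(n^2) double-loop template counter from the SampEn definition
sampen_oracle <- function(x, m = 2, r = 0.2 * sd(x), delay = 1) {
  n <- length(x); nt <- n - m * delay
  B <- 0; A <- 0
  for (i in 1:(nt - 1)) for (j in (i + 1):nt) {
    dm <- max(abs(x[i + (0:(m - 1)) * delay] - x[j + (0:(m - 1)) * delay]))
    if (dm <= r) {
      B <- B + 1
      if (max(dm, abs(x[i + m * delay] - x[j + m * delay])) <= r) A <- A + 1
    }
  }
  -log(A / B)
}

# literal BH step-up: p_(i) * m / i, cumulative minimum from the top rank
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# half-cosine waveform through alternating trough/peak extrema with given
# per-breath rates (bpm) and amplitudes; mirrors the planted-signal idea
# but built independently for round-trip tests
waveform_from_rates <- function(rates, amps = rep(1, length(rates)),
                                fs = 10) {
  pk <- cumsum(c(30 / rates[1], 60 / rates[-1]))
  nb <- length(pk)
  tr_t <- c(0, (pk[-nb] + pk[-1]) / 2, pk[nb] + 30 / rates[nb])
  ex_t <- c(rbind(tr_t[seq_len(nb)], pk), tr_t[nb + 1])
  ex_v <- c(rbind(-amps / 2, amps / 2), -amps[nb] / 2)
  tt <- seq(0, max(ex_t), by = 1 / fs)
  j <- findInterval(tt, ex_t, all.inside = TRUE)
  frac <- pmin(pmax((tt - ex_t[j]) / (ex_t[j + 1] - ex_t[j]), 0), 1)
  wave <- ex_v[j] + (ex_v[j + 1] - ex_v[j]) * (1 - cos(pi * frac)) / 2
  list(wave = wave, peak_times = pk, fs = fs)
}

# small feature table with controlled content
make_feature_table <- function(n = 8, seed = 1, site = "site1",
                               condition = "rest") {
  set.seed(seed)
  df <- data.frame(subject = sprintf("s%02d", 1:n), condition = condition,
                   site = site, stringsAsFactors = FALSE)
  for (fn in feature_names())
    df[[fn]] <- exp(rnorm(n, 0.5, 0.3))
  feature_table(df)
}
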