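# Shared fixtures, built in code.

# Triangular envelope: linear rise 0 -> 1 over 100 ms, fall 1 -> 0 over
# 150 ms, sampled at `rate`. Closed-form markers: sharpness 4 /s, MA 1 at
# 100 ms, 80% latency 80 ms, plateau 50 ms, MD 10 /s at 0 ms.
tri_envelope <- function(rate = 1000) {
  t_ms <- seq(0, 250, by = 1000 / rate)
  v <- ifelse(t_ms <= 100, t_ms / 100, 1 - (t_ms - 100) / 150)
  envelope(v, rate, stage = "summed")
}

# O(n^2) double-loop oracle for the Gini index (chunked rows to bound
# memory); operates on the shifted non-negative values like the
# implementation.
gini_bruteforce <- function(x) {
  x <- x - min(x)
  n <- length(x)
  s <- sum(x)
  if (s == 0) return(0)
  tot <- 0
  step <- max(1L, min(n, floor(2e7 / n)))
  i <- 1L
  while (i <= n) {
    j <- min(n, i + step - 1L)
    tot <- tot + sum(abs(outer(x[i:j], x, "-")))
    i <- j + 1L
  }
  tot / (2 * n * s)
}

# Events for a toy experiment: `n_pres` presentations of one stream of 20
# isochronous syllables with a common edge-time jitter sd.
toy_events <- function(n_pres = 10, jitter_sd_ms = 0,
                       stream = "c.1", condition = "c") {
  onsets <- (seq_len(n_pres) - 1) * 7
  syl <- do.call(rbind, lapply(onsets, function(o)
    data.frame(time_s = o + (0:19) * 0.25 + 0.03,
               jitter_sd_ms = jitter_sd_ms)))
  list(presentations = data.frame(onset_s = onsets, stream = stream,
                                  condition = condition,
                                  is_filler = FALSE),
       syllables = syl)
}

# Epoched EEG holding a deterministic signal per trial; labels one stream.
toy_epochs <- function(signals, rate = 1000, n_channels = 1) {
  n_tr <- length(signals)
  n <- length(signals[[1]])
  dat <- array(0, dim = c(n_tr, n_channels, n))
  for (i in seq_len(n_tr)) for (ch in seq_len(n_channels))
    dat[i, ch, ] <- signals[[i]]
  structure(list(data = dat, rate = rate,
                 channel_names = paste0("C", seq_len(n_channels)),
                 labels = data.frame(condition = "c", stream = 1L,
                                     trial = seq_len(n_tr),
                                     participant = 1L)),
            class = "epoched_eeg")
}

# von Mises sampler (Best & Fisher rejection algorithm); mu = 0.
rvonmises <- function(n, kappa) {
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(pmin(1, pmax(-1, f)))
      i <- i + 1L
    }
  }
  out
}
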