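#' Configuration of the EEG simulator
#'
#' The simulator instantiates an edge-triggered evoked model: every
#' acoustic edge (one per syllable, at its maximum-derivative latency)
#' triggers a damped-oscillation evoked response, jittered in time with a
#' per-condition standard deviation, superimposed on 1/f background noise.
#' Phase locking at the syllable rate is then controlled by the jitter.
#'
#' @param n_channels Number of EEG channels (default 32).
#' @param rate Sampling rate in Hz (default 1000).
#' @param kernel_freq Evoked-response oscillation frequency in Hz.
#' @param kernel_tau Evoked-response decay time constant in seconds.
#' @param kernel_gain Evoked-response peak amplitude in microvolts.
#' @param kernel_dur_s Kernel support in seconds.
#' @param noise_alpha Spectral exponent of the background noise (power
#'   ~ 1/f^alpha).
#' @param noise_amp Background-noise RMS amplitude in microvolts.
#' @param channel_names Channel labels; defaults to a standard 32-channel
#'   montage (truncated or extended as needed).
#' @return A list of class `eeg_sim_config`.
#' @export
eeg_sim_config <- function(n_channels = 32L, rate = 1000, kernel_freq = 5,
                           kernel_tau = 0.06, kernel_gain = 6,
                           kernel_dur_s = 0.25, noise_alpha = 1,
                           noise_amp = 8, channel_names = NULL) {
  std <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "FC5", "FC1",
           "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8", "TP9", "CP5",
           "CP1", "CP2", "CP6", "TP10", "P7", "P3", "Pz", "P4", "P8",
           "PO9", "O1", "Oz", "O2", "PO10")
  if (is.null(channel_names)) {
    channel_names <- if (n_channels <= 32L) std[seq_len(n_channels)] else
      c(std, paste0("EX", seq_len(n_channels - 32L)))
  }
  if (length(channel_names) != n_channels)
    stop("channel_names length must equal n_channels")
  if (noise_amp < 0 || kernel_gain < 0) stop("amplitudes must be >= 0")
  structure(list(n_channels = n_channels, rate = rate,
                 kernel_freq = kernel_freq, kernel_tau = kernel_tau,
                 kernel_gain = kernel_gain, kernel_dur_s = kernel_dur_s,
                 noise_alpha = noise_alpha, noise_amp = noise_amp,
                 channel_names = channel_names),
            class = "eeg_sim_config")
}

#' Evoked-response kernel
#'
#' Damped oscillation `sin(2 pi f t) exp(-t / tau)`, peak-normalised and
#' scaled to the configured gain.
#'
#' @param cfg An [eeg_sim_config()].
#' @return Numeric vector of kernel samples at `cfg$rate`.
#' @export
evoked_kernel <- function(cfg) {
  t <- seq(0, cfg$kernel_dur_s, by = 1 / cfg$rate)
  k <- sin(2 * pi * cfg$kernel_freq * t) * exp(-t / cfg$kernel_tau)
  k / max(abs(k)) * cfg$kernel_gain
}

#' 1/f ("pink") noise
#'
#' Frequency-domain synthesis: spectral amplitudes proportional to
#' `f^(-alpha/2)` with random phases, normalised to unit RMS.
#'
#' @param n Number of samples.
#' @param alpha Spectral exponent (power ~ 1/f^alpha); 0 gives white noise.
#' @return Numeric vector of length `n`, RMS 1.
#' @export
pink_noise <- function(n, alpha = 1) {
  nf <- n %/% 2L
  amp <- (seq_len(nf))^(-alpha / 2)
  ph <- stats::runif(nf, 0, 2 * pi)
  spec <- numeric(n) + 0i
  spec[2L:(nf + 1L)] <- amp * exp(1i * ph)
  if (n %% 2L == 0L) spec[nf + 1L] <- Re(spec[nf + 1L])
  mirror <- 2L:(n - nf)
  spec[n + 2L - mirror] <- Conj(spec[mirror])
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Simulate a multichannel EEG recording from edge times
#'
#' Each channel is the convolution of an impulse train at the jittered
#' acoustic-edge times with the evoked kernel, scaled by a per-channel
#' gain, plus independent 1/f noise. Jitter is drawn per syllable per
#' presentation from a zero-mean normal with the syllable's configured
#' standard deviation. Stream-onset events are recorded for epoching.
#'
#' @param presentations Data frame with one row per stream presentation:
#'   `onset_s`, `stream`, `condition`, `is_filler`.
#' @param syllable_events Data frame with one row per syllable instance:
#'   `time_s` (absolute, jitter-free edge time) and `jitter_sd_ms`.
#' @param cfg An [eeg_sim_config()].
#' @param seed Integer seed; runs are bit-reproducible under it.
#' @return An [eeg_recording] with per-channel gains attached as attribute
#'   `"gains"`.
#' @export
simulate_eeg <- function(presentations, syllable_events, cfg, seed = 1L) {
  stopifnot(inherits(cfg, "eeg_sim_config"))
  if (any(syllable_events$jitter_sd_ms < 0))
    stop("jitter sd must be >= 0")
  with_seed(seed, {
    total_s <- max(presentations$onset_s) + 6
    n <- ceiling(total_s * cfg$rate)
    jit <- stats::rnorm(nrow(syllable_events), 0,
                        syllable_events$jitter_sd_ms / 1000)
    samp <- round((syllable_events$time_s + jit) * cfg$rate) + 1L
    samp <- samp[samp >= 1L & samp <= n]
    imp <- tabulate(samp, nbins = n)
    ev <- fft_conv(as.numeric(imp), evoked_kernel(cfg))[seq_len(n)]
    # dipolar scalp topography: the evoked field inverts sign across the
    # montage, so it survives average referencing
    gains <- stats::runif(cfg$n_channels, 0.7, 1.3) *
      rep_len(c(1, -1), cfg$n_channels)
    dat <- matrix(0, nrow = cfg$n_channels, ncol = n)
    for (ch in seq_len(cfg$n_channels)) {
      noise <- if (cfg$noise_amp > 0)
        cfg$noise_amp * pink_noise(n, cfg$noise_alpha) else 0
      dat[ch, ] <- gains[ch] * ev + noise
    }
    events <- data.frame(
      sample = round(presentations$onset_s * cfg$rate) + 1L,
      stream = presentations$stream,
      condition = presentations$condition,
      is_filler = presentations$is_filler
    )
    rec <- eeg_recording(dat, cfg$rate, cfg$channel_names, events)
    attr(rec, "gains") <- gains
    rec
  })
}
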