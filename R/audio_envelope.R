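#' Equivalent rectangular bandwidth of the human auditory filter
#'
#' Glasberg-Moore approximation, used to set gammatone filter bandwidths.
#'
#' @param f Center frequency in Hz.
#' @return Bandwidth in Hz.
#' @export
erb_bandwidth <- function(f) 24.7 * (4.37 * f / 1000 + 1)

#' Cochlear-style gammatone filterbank
#'
#' Filters a waveform through `n_bands` fourth-order gammatone bandpass
#' filters with center frequencies log-spaced from `f_lo` to `f_hi`
#' inclusive. Each filter is realised as an FIR kernel
#' `t^3 exp(-2 pi b t) cos(2 pi fc t)` (b = 1.019 ERB(fc)), normalised to
#' unit gain at its center frequency.
#'
#' @param w A [waveform].
#' @param n_bands Number of bands (default 32).
#' @param f_lo,f_hi Lowest / highest center frequency in Hz (defaults 80 and
#'   8000). `f_hi` must lie below the Nyquist frequency.
#' @param kernel_s Gammatone kernel duration in seconds. 0.1 s is ample for
#'   the decay of the lowest (80 Hz) band.
#' @return A list of `n_bands` band-limited [waveform]s, with the center
#'   frequencies attached as attribute `"centers"`.
#' @export
gammatone_filterbank <- function(w, n_bands = 32L, f_lo = 80, f_hi = 8000,
                                 kernel_s = 0.1) {
  stopifnot(inherits(w, "waveform"))
  if (n_bands < 1L) stop("n_bands must be >= 1")
  if (!(0 < f_lo && f_lo < f_hi)) stop("need 0 < f_lo < f_hi")
  if (f_hi >= w$rate / 2)
    stop("invalid filterbank spec: f_hi (", f_hi,
         " Hz) must be below the Nyquist frequency ", w$rate / 2, " Hz")
  centers <- if (n_bands == 1L) f_lo else
    exp(seq(log(f_lo), log(f_hi), length.out = n_bands))
  t <- seq(0, kernel_s, by = 1 / w$rate)
  bands <- lapply(centers, function(fc) {
    b <- 1.019 * erb_bandwidth(fc)
    g <- t^3 * exp(-2 * pi * b * t) * cos(2 * pi * fc * t)
    # unit gain at the center frequency
    g <- g / Mod(sum(g * exp(-2i * pi * fc * t)))
    y <- fft_conv(w$samples, g)[seq_along(w$samples)]
    waveform(y, w$rate, label = w$label)
  })
  attr(bands, "centers") <- centers
  bands
}

#' Narrowband envelope via the analytic signal
#'
#' The magnitude of the Hilbert-transform analytic signal of a band-limited
#' waveform; non-negative, same length as the input.
#'
#' @param band A band-limited [waveform].
#' @return An [envelope] with `stage = "narrowband"`.
#' @export
narrowband_envelope <- function(band) {
  stopifnot(inherits(band, "waveform"))
  envelope(Mod(analytic_signal(band$samples)), band$rate,
           stage = "narrowband")
}

#' Sum of narrowband envelopes
#'
#' @param envs A list of narrowband [envelope]s with equal lengths and rates.
#' @return An [envelope] with `stage = "summed"`.
#' @export
summed_envelope <- function(envs) {
  if (!length(envs)) stop("empty envelope list")
  stopifnot(all(vapply(envs, inherits, logical(1), "envelope")))
  lens <- vapply(envs, function(e) length(e$values), integer(1))
  rates <- vapply(envs, function(e) e$rate, numeric(1))
  if (length(unique(lens)) != 1L)
    stop("narrowband envelopes have mismatched lengths")
  if (length(unique(rates)) != 1L)
    stop("narrowband envelopes have mismatched rates")
  envelope(Reduce(`+`, lapply(envs, `[[`, "values")), rates[1L],
           stage = "summed")
}

#' Resample an envelope
#'
#' Decimation onto a coarser grid for modulation-rate processing. When
#' down-sampling, a zero-phase FIR anti-aliasing low-pass (cutoff at 40%
#' of the target rate) removes pitch-rate ripple from the summed envelope
#' first; the values are then read off the new grid by linear
#' interpolation. Narrowband/summed outputs are clipped at zero so the
#' non-negativity invariant survives the filtering.
#'
#' @param e An [envelope].
#' @param rate_out Target rate in Hz.
#' @return An [envelope] at `rate_out`, same stage.
#' @export
resample_envelope <- function(e, rate_out) {
  stopifnot(inherits(e, "envelope"))
  if (rate_out == e$rate) return(e)
  n <- length(e$values)
  v_in <- e$values
  if (rate_out < e$rate) {
    cutoff <- 0.4 * rate_out
    taps <- min(2L * floor(n / 2L), 2L * round(2 * e$rate / cutoff))
    if (taps >= 8L) {
      h <- signal::fir1(taps, cutoff / (e$rate / 2), type = "low")
      x <- reflect_pad(v_in, taps)
      y <- fft_conv(x, as.numeric(h))[seq_along(x) + taps / 2L]
      v_in <- y[(taps + 1L):(taps + n)]
    }
  }
  t_in <- (seq_len(n) - 1L) / e$rate
  t_out <- seq(0, t_in[n], by = 1 / rate_out)
  v <- stats::approx(t_in, v_in, xout = t_out)$y
  if (e$stage %in% c("narrowband", "summed")) v <- pmax(v, 0)
  envelope(v, rate_out, stage = e$stage)
}

#' Zero-phase FIR bandpass of a summed envelope
#'
#' Applies a linear-phase Kaiser-window FIR bandpass (defaults: 2-10 Hz,
#' order 350, beta = 5) with group-delay compensation, so the output has no
#' net phase shift. The envelope is reflection-padded by `pad_s` seconds on
#' each side before filtering and cropped afterwards, keeping the output
#' length equal to the input length and avoiding spurious onset edges on
#' short syllables.
#'
#' @param e A summed [envelope]. Its rate must exceed `2 * hi`.
#' @param lo,hi Band edges in Hz.
#' @param order FIR filter order (number of taps minus one; must be even).
#' @param beta Kaiser window shape parameter.
#' @param pad_s Reflection padding per side, in seconds.
#' @return An [envelope] with `stage = "bandpassed"` (signed values).
#' @export
bandpass_smooth <- function(e, lo = 2, hi = 10, order = 350L, beta = 5,
                            pad_s = 0.8) {
  stopifnot(inherits(e, "envelope"))
  if (e$stage != "summed")
    stop("bandpass_smooth expects a summed envelope, got stage '",
         e$stage, "'")
  if (e$rate <= 2 * hi)
    stop("envelope rate must exceed 2 * hi = ", 2 * hi, " Hz")
  if (order %% 2L != 0L) stop("order must be even for delay compensation")
  n <- length(e$values)
  n_pad <- round(pad_s * e$rate)
  if (n + 2L * n_pad < order + 1L)
    stop("envelope too short for the order-", order, " filter even after ",
         "padding; increase pad_s or decimate to a lower envelope rate")
  h <- signal::fir1(order, c(lo, hi) / (e$rate / 2), type = "pass",
                    window = signal::kaiser(order + 1L, beta))
  x <- reflect_pad(e$values, n_pad)
  y_full <- fft_conv(x, as.numeric(h))
  # compensate the (order/2)-sample group delay of the symmetric FIR
  y <- y_full[seq_len(length(x)) + order / 2L]
  envelope(y[(n_pad + 1L):(n_pad + n)], e$rate, stage = "bandpassed")
}

#' Full audio-to-envelope chain
#'
#' Runs a syllable waveform through the cochlear filterbank, extracts and
#' sums the narrowband Hilbert envelopes, decimates the sum to `env_rate`,
#' and (optionally) applies the zero-phase 2-10 Hz smoothing bandpass. The
#' default envelope rate of 250 Hz makes the 351-tap kernel 1.4 s long,
#' which is what the 2 Hz lower band edge requires for meaningful stopband
#' attenuation.
#'
#' @param w A [waveform].
#' @param n_bands,f_lo,f_hi Filterbank layout; see [gammatone_filterbank()].
#' @param env_rate Envelope processing rate in Hz.
#' @param lo,hi,order,beta,pad_s Bandpass settings; see [bandpass_smooth()].
#' @param bandpass If `FALSE`, stop after decimating the summed envelope.
#' @return A list with elements `summed` (decimated summed envelope) and,
#'   when `bandpass = TRUE`, `bandpassed`.
#' @export
cochlear_envelope <- function(w, n_bands = 32L, f_lo = 80, f_hi = 8000,
                              env_rate = 250, lo = 2, hi = 10,
                              order = 350L, beta = 5, pad_s = 0.8,
                              bandpass = TRUE) {
  bands <- gammatone_filterbank(w, n_bands = n_bands, f_lo = f_lo,
                                f_hi = f_hi)
  summed <- summed_envelope(lapply(bands, narrowband_envelope))
  summed <- resample_envelope(summed, env_rate)
  out <- list(summed = summed)
  if (bandpass)
    out$bandpassed <- bandpass_smooth(summed, lo = lo, hi = hi,
                                      order = order, beta = beta,
                                      pad_s = pad_s)
  out
}
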