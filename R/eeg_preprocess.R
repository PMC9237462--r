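#' Construct a multichannel EEG recording
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param rate Sampling rate in Hz (nominal 1000).
#' @param channel_names Character vector, one name per row of `data`.
#' @param events Data frame of stimulus events with at least columns
#'   `sample` (1-based sample index of stream onset) and `stream`
#'   (stream id); typically also `condition` and `is_filler`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, rate, channel_names,
                          events = data.frame(sample = integer(),
                                              stream = integer())) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("data must be a numeric channels x samples matrix")
  if (length(channel_names) != nrow(data))
    stop("channel_names length (", length(channel_names),
         ") does not match channel count (", nrow(data), ")")
  if (rate <= 0) stop("rate must be positive")
  if (nrow(events) && (any(events$sample < 1L) ||
                       any(events$sample > ncol(data))))
    stop("events fall outside the recording")
  structure(list(data = data, rate = rate,
                 channel_names = as.character(channel_names),
                 events = events),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording: %d channels x %d samples @ %g Hz, %d events>\n",
              nrow(x$data), ncol(x$data), x$rate, nrow(x$events)))
  invisible(x)
}

#' Zero-phase bandpass filter of an EEG recording
#'
#' Applies the squared-magnitude response of cascaded Butterworth designs
#' (order-8 low-pass at `hi`, order-2 high-pass at `lo`) in the frequency
#' domain with zero phase — the forward-backward (filtfilt) response
#' without its edge transients, and fast for long recordings. Channel
#' means are subtracted afterwards so any residual DC is removed exactly.
#'
#' @param rec An [eeg_recording]. Its rate must exceed `2 * hi`.
#' @param lo High-pass edge in Hz (default 1).
#' @param hi Low-pass edge in Hz (default 50).
#' @return A filtered [eeg_recording].
#' @export
bandpass_eeg <- function(rec, lo = 1, hi = 50) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$rate <= 2 * hi)
    stop("sampling rate ", rec$rate, " Hz too low for a ", hi,
         " Hz low-pass")
  n <- ncol(rec$data)
  f <- (seq_len(n) - 1L) / n * rec$rate
  f <- pmin(f, rec$rate - f)  # two-sided frequency axis
  # |H|^2 of the causal designs = the net filtfilt magnitude, zero phase
  g_lp <- 1 / (1 + (f / hi)^16)
  g_hp <- (f / lo)^4 / (1 + (f / lo)^4)
  g <- g_lp * g_hp
  out <- rec$data
  for (ch in seq_len(nrow(out))) {
    y <- Re(stats::fft(stats::fft(out[ch, ]) * g, inverse = TRUE)) / n
    out[ch, ] <- y - mean(y)
  }
  rec$data <- out
  rec
}

#' Re-reference to the channel average
#'
#' Subtracts the instantaneous mean over channels from every channel, so
#' the channel mean is exactly zero at every sample. Idempotent.
#'
#' @param rec An [eeg_recording] with at least 2 channels.
#' @return A re-referenced [eeg_recording].
#' @export
average_reference <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$data) < 2L) stop("average reference needs >= 2 channels")
  rec$data <- sweep(rec$data, 2L, colMeans(rec$data), "-")
  rec
}

#' Remove ocular components by frontal-power share
#'
#' Given a blind-source-separation decomposition of the recording
#' (`data = t(mixing) %*% sources`), zeroes every component whose
#' back-projected power in the designated frontal channels exceeds
#' `threshold` times that component's total back-projected power, and
#' reconstructs the signal from the remaining components. The decomposition
#' backend (ICA or otherwise) is deliberately pluggable; only the rejection
#' rule lives here.
#'
#' @param rec An [eeg_recording].
#' @param mixing Components x channels mixing matrix.
#' @param sources Components x samples source time courses.
#' @param frontal_channels Channel names counted as frontal (default
#'   Fp1, Fp2, F7, F8).
#' @param threshold Maximum tolerated frontal power share (default 0.12).
#' @return The reconstructed [eeg_recording]; indices of removed components
#'   are attached as attribute `"removed"`.
#' @export
reject_eye_components <- function(rec, mixing, sources,
                                  frontal_channels = c("Fp1", "Fp2",
                                                       "F7", "F8"),
                                  threshold = 0.12) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (ncol(mixing) != nrow(rec$data))
    stop("mixing has ", ncol(mixing), " channels but the recording has ",
         nrow(rec$data))
  if (nrow(mixing) != nrow(sources))
    stop("mixing and sources disagree on the number of components")
  if (ncol(sources) != ncol(rec$data))
    stop("sources have ", ncol(sources), " samples but the recording has ",
         ncol(rec$data))
  fr <- which(rec$channel_names %in% frontal_channels)
  if (!length(fr)) stop("none of the frontal channels are present")
  tot <- rowSums(mixing^2)
  share <- rowSums(mixing[, fr, drop = FALSE]^2) / tot
  share[tot == 0] <- 0
  removed <- which(share > threshold)
  keep <- setdiff(seq_len(nrow(mixing)), removed)
  rec$data <- t(mixing[keep, , drop = FALSE]) %*%
    sources[keep, , drop = FALSE]
  attr(rec, "removed") <- removed
  rec
}

#' Split a recording into fixed-length stream epochs
#'
#' One epoch per stream-onset event; events too close to the end of the
#' recording for a full epoch are skipped with a warning. Filler streams
#' are excluded by default (they only serve the attention task).
#'
#' @param rec An [eeg_recording] whose `events` mark stream onsets.
#' @param duration_s Epoch length in seconds (default 5).
#' @param include_fillers Keep filler presentations? Default `FALSE`.
#' @return An object of class `epoched_eeg`: list with `data` (trials x
#'   channels x samples array), `rate`, `channel_names`, and `labels` (one
#'   row per trial: `condition`, `stream`, `trial`, `participant`).
#' @export
epoch_eeg <- function(rec, duration_s = 5, include_fillers = FALSE) {
  stopifnot(inherits(rec, "eeg_recording"))
  ev <- rec$events
  if (!include_fillers && "is_filler" %in% names(ev))
    ev <- ev[!ev$is_filler, , drop = FALSE]
  n_samp <- round(duration_s * rec$rate)
  ok <- ev$sample + n_samp - 1L <= ncol(rec$data)
  if (any(!ok))
    warning(sum(!ok), " event(s) skipped: less than ", duration_s,
            " s of data after stream onset")
  ev <- ev[ok, , drop = FALSE]
  n_tr <- nrow(ev)
  dat <- array(NA_real_, dim = c(n_tr, nrow(rec$data), n_samp))
  for (i in seq_len(n_tr))
    dat[i, , ] <- rec$data[, ev$sample[i] + seq_len(n_samp) - 1L]
  labels <- data.frame(
    condition = if ("condition" %in% names(ev)) ev$condition else
      rep(NA_character_, n_tr),
    stream = if (n_tr) ev$stream else integer(),
    trial = stats::ave(seq_len(n_tr), ev$stream, FUN = seq_along),
    participant = if ("participant" %in% names(ev)) ev$participant else
      rep(NA_integer_, n_tr),
    stringsAsFactors = FALSE
  )
  structure(list(data = dat, rate = rec$rate,
                 channel_names = rec$channel_names, labels = labels),
            class = "epoched_eeg")
}

#' @export
print.epoched_eeg <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoched_eeg: %d trials x %d channels x %d samples @ %g Hz>\n",
              d[1L], d[2L], d[3L], x$rate))
  invisible(x)
}

#' Trim the onset of every epoch
#'
#' Removes the first `trim_ms` of each epoch (default 500 ms) so transient
#' auditory onset responses do not contaminate the steady-state phase
#' spectra; 5 s epochs become 4.5 s.
#'
#' @param ep An `epoched_eeg`.
#' @param trim_ms Onset interval to discard, in ms.
#' @return The trimmed `epoched_eeg`.
#' @export
trim_onset <- function(ep, trim_ms = 500) {
  stopifnot(inherits(ep, "epoched_eeg"))
  n_trim <- round(trim_ms / 1000 * ep$rate)
  if (n_trim >= dim(ep$data)[3L])
    stop("trim (", trim_ms, " ms) is not shorter than the epoch")
  if (n_trim > 0L)
    ep$data <- ep$data[, , (n_trim + 1L):dim(ep$data)[3L], drop = FALSE]
  ep
}

#' Standard preprocessing chain
#'
#' filter -> average reference -> (optional ocular-component rejection) ->
#' epoch -> trim. The component rejection is a linear, time-invariant
#' channel mixing, so applying it on the continuous recording is equivalent
#' to applying it per epoch.
#'
#' @param rec An [eeg_recording].
#' @param lo,hi Bandpass edges in Hz.
#' @param duration_s Epoch length in seconds.
#' @param trim_ms Onset trim in ms.
#' @param mixing,sources Optional decomposition for
#'   [reject_eye_components()]; both or neither.
#' @param ... Further arguments to [reject_eye_components()].
#' @return An `epoched_eeg`.
#' @export
preprocess_eeg <- function(rec, lo = 1, hi = 50, duration_s = 5,
                           trim_ms = 500, mixing = NULL, sources = NULL,
                           ...) {
  rec <- bandpass_eeg(rec, lo = lo, hi = hi)
  rec <- average_reference(rec)
  if (!is.null(mixing) && !is.null(sources))
    rec <- reject_eye_components(rec, mixing, sources, ...)
  trim_onset(epoch_eeg(rec, duration_s = duration_s), trim_ms = trim_ms)
}
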