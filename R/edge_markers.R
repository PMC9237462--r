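#' Envelope sharpness
#'
#' Mean of the total positive derivative of the envelope: discrete forward
#' differences scaled by the sampling rate, negative values clipped to zero,
#' averaged over all difference samples. Units: amplitude per second.
#'
#' @param e An [envelope] (length >= 2).
#' @return Sharpness in amplitude/s.
#' @export
sharpness <- function(e) {
  stopifnot(inherits(e, "envelope"), length(e$values) >= 2L)
  mean(pmax(diff(e$values), 0)) * e$rate
}

#' Maximum amplitude and its latency
#'
#' Ties are broken by first occurrence; latency is measured from the start
#' of the envelope (syllable audio onset), in milliseconds.
#'
#' @param e An [envelope].
#' @return Named numeric vector `c(ma = , ma_latency = )` (amplitude, ms).
#' @export
max_amplitude <- function(e) {
  stopifnot(inherits(e, "envelope"), length(e$values) >= 1L)
  i <- which.max(e$values)
  c(ma = e$values[i], ma_latency = (i - 1L) / e$rate * 1000)
}

#' Latency to 80% of the maximum amplitude
#'
#' Time of the first sample whose value reaches 0.8 times the maximum; a
#' more noise-robust onset latency than the maximum itself when the
#' envelope has a plateau.
#'
#' @param e An [envelope].
#' @return Latency in ms.
#' @export
latency_80 <- function(e) {
  stopifnot(inherits(e, "envelope"), length(e$values) >= 1L)
  thr <- 0.8 * max(e$values)
  i <- which(e$values >= thr)[1L]
  (i - 1L) / e$rate * 1000
}

#' Plateau width of the envelope peak
#'
#' Interval from the first ascending attainment of 80% of the maximum
#' amplitude to the first sample after the maximum's latency at which the
#' envelope has fallen back to (or below) that level; if it never falls
#' back, the plateau extends to the end of the envelope.
#'
#' @param e An [envelope].
#' @return Plateau width in ms.
#' @export
plateau <- function(e) {
  stopifnot(inherits(e, "envelope"), length(e$values) >= 1L)
  v <- e$values
  n <- length(v)
  i_max <- which.max(v)
  thr <- 0.8 * v[i_max]
  rise <- which(v >= thr)[1L]
  after <- which(v <= thr & seq_len(n) > i_max)
  fall_t <- if (length(after)) (after[1L] - 1L) / e$rate else n / e$rate
  (fall_t - (rise - 1L) / e$rate) * 1000
}

#' Maximum derivative and its latency
#'
#' Maximum of the discrete forward-difference derivative (scaled by the
#' sampling rate) and the time of its first occurrence; the latency is
#' assigned to the left sample of the difference.
#'
#' @param e An [envelope] (length >= 2).
#' @return Named numeric vector `c(md = , md_latency = )` (amplitude/s, ms).
#' @export
max_derivative <- function(e) {
  stopifnot(inherits(e, "envelope"), length(e$values) >= 2L)
  d <- diff(e$values) * e$rate
  # first occurrence among numerically tied maxima
  i <- which(d >= max(d) - 1e-9 * max(abs(d), 1))[1L]
  c(md = d[i], md_latency = (i - 1L) / e$rate * 1000)
}

#' Gini index of an envelope
#'
#' Inequality of the envelope values,
#' `G = sum_i sum_j |x_i - x_j| / (2 n sum_i x_i)`,
#' computed via the O(n log n) sorted form. Zero for a constant envelope,
#' approaching one when all mass sits in a single sample; quantifies how
#' prominent the syllable's peak is. Because the 2-10 Hz bandpass makes
#' envelope values signed, the minimum is subtracted first to restore the
#' non-negativity the definition requires.
#'
#' @param e An [envelope].
#' @return Gini index in `[0, (n-1)/n]`. A constant input returns 0 with
#'   attribute `degenerate = TRUE`.
#' @export
gini_index <- function(e) {
  stopifnot(inherits(e, "envelope"))
  x <- e$values - min(e$values)
  n <- length(x)
  s <- sum(x)
  if (s == 0)
    return(structure(0, degenerate = TRUE))
  xs <- sort(x)
  (2 * sum(seq_len(n) * xs) - (n + 1) * s) / (n * s)
}

#' All edge markers of an envelope
#'
#' Computes the full marker set: sharpness, maximum amplitude (MA) and its
#' latency, latency to 80% of MA, plateau width, maximum derivative (MD)
#' and its latency, and the Gini index.
#'
#' @param e An [envelope]; by convention the 2-10 Hz bandpassed envelope.
#' @return A named numeric vector of class `edge_marker_set` with elements
#'   `sharpness` (amp/s), `ma` (amp), `ma_latency` (ms), `ma80_latency`
#'   (ms), `plateau` (ms), `md` (amp/s), `md_latency` (ms), `gini`.
#' @export
edge_markers <- function(e) {
  ma <- max_amplitude(e)
  md <- max_derivative(e)
  out <- c(sharpness = sharpness(e),
           ma, ma80_latency = latency_80(e), plateau = plateau(e),
           md, gini = as.numeric(gini_index(e)))
  class(out) <- c("edge_marker_set", "numeric")
  out
}

#' Fieldwise average of edge-marker sets
#'
#' Per-condition marker values are the arithmetic means of the per-syllable
#' sets (one per vowel).
#'
#' @param sets A non-empty list of `edge_marker_set` vectors (or a
#'   data.frame with one row per syllable).
#' @return An `edge_marker_set` of fieldwise means.
#' @export
condition_average <- function(sets) {
  if (is.data.frame(sets)) sets <- lapply(seq_len(nrow(sets)),
                                          function(i) unlist(sets[i, ]))
  if (!length(sets)) stop("cannot average an empty list of marker sets")
  nm <- names(sets[[1L]])
  m <- do.call(rbind, lapply(sets, function(s) as.numeric(s[nm])))
  out <- colMeans(m)
  names(out) <- nm
  class(out) <- c("edge_marker_set", "numeric")
  out
}

#' Edge markers straight from audio
#'
#' Convenience wrapper: waveform in, marker set of the cochlear envelope
#' out. By default markers are measured on the summed envelope (decimated
#' with anti-aliasing), whose derivative retains the fast attack content
#' that distinguishes sharp from slow onsets; the 2-10 Hz bandpassed
#' envelope is available via `stage = "bandpassed"`.
#'
#' @param w A [waveform].
#' @param stage `"summed"` (default) or `"bandpassed"`.
#' @param ... Passed to [cochlear_envelope()].
#' @return An `edge_marker_set`.
#' @export
waveform_markers <- function(w, stage = c("summed", "bandpassed"), ...) {
  stage <- match.arg(stage)
  edge_markers(cochlear_envelope(w, bandpass = (stage == "bandpassed"),
                                 ...)[[stage]])
}
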