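#' Construct a waveform object
#'
#' A `waveform` is a uniformly sampled, finite, real-valued audio signal.
#' It is the input type for the cochlear-filterbank envelope chain.
#'
#' @param samples Numeric vector of amplitudes (arbitrary units).
#' @param rate Sampling rate in samples/second.
#' @param label Optional character tag (condition or syllable name).
#' @return An object of class `waveform` with fields `samples`, `rate`,
#'   `label`.
#' @examples
#' w <- waveform(sin(2 * pi * 440 * seq(0, 0.25, by = 1 / 44100)), 44100, "a")
#' @export
waveform <- function(samples, rate, label = NULL) {
  if (!is.numeric(samples) || length(samples) < 2L)
    stop("waveform needs at least 2 numeric samples")
  if (!all(is.finite(samples)))
    stop("waveform samples must be finite")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("waveform rate must be a positive scalar")
  structure(list(samples = as.numeric(samples), rate = as.numeric(rate),
                 label = label),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform%s: %d samples @ %g Hz (%.1f ms)>\n",
              if (is.null(x$label)) "" else paste0(" ", x$label),
              length(x$samples), x$rate,
              1000 * length(x$samples) / x$rate))
  invisible(x)
}

#' Construct an envelope object
#'
#' An `envelope` is a uniformly sampled amplitude contour, tagged with the
#' processing stage it came from. Narrowband and summed envelopes must be
#' non-negative; bandpassed envelopes are signed (the 2-10 Hz filter removes
#' the DC offset).
#'
#' @param values Numeric vector of envelope amplitudes.
#' @param rate Sampling rate in samples/second.
#' @param stage One of `"narrowband"`, `"summed"`, `"bandpassed"`.
#' @return An object of class `envelope`.
#' @export
envelope <- function(values, rate,
                     stage = c("narrowband", "summed", "bandpassed")) {
  stage <- match.arg(stage)
  if (!is.numeric(values) || length(values) < 1L)
    stop("envelope needs numeric values")
  if (!all(is.finite(values)))
    stop("envelope values must be finite")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("envelope rate must be a positive scalar")
  if (stage %in% c("narrowband", "summed") && any(values < -1e-9))
    stop(sprintf("%s envelopes must be non-negative", stage))
  structure(list(values = as.numeric(values), rate = as.numeric(rate),
                 stage = stage),
            class = "envelope")
}

#' @export
print.envelope <- function(x, ...) {
  cat(sprintf("<envelope (%s): %d samples @ %g Hz>\n",
              x$stage, length(x$values), x$rate))
  invisible(x)
}

## FFT-based linear convolution; returns the first `length(x)` samples of
## the full (causal) convolution of x with kernel h.
fft_conv <- function(x, h) {
  n <- length(x)
  m <- length(h)
  nfft <- stats::nextn(n + m - 1L, 2L)
  X <- stats::fft(c(x, numeric(nfft - n)))
  H <- stats::fft(c(h, numeric(nfft - m)))
  y <- Re(stats::fft(X * H, inverse = TRUE)) / nfft
  y[seq_len(n + m - 1L)]
}

## Analytic signal via the frequency-domain Hilbert transform.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

## Reflection padding that tolerates pad lengths longer than the signal by
## tiling alternating mirror images.
reflect_pad <- function(x, n_pad) {
  n <- length(x)
  if (n_pad == 0L) return(x)
  block <- c(rev(x[-1L]), x[-n])  # one full mirror period, length 2(n-1)
  idx_pre <- ((seq_len(n_pad) - 1L) %% length(block)) + 1L
  pre <- rev(block[idx_pre])
  post <- block[idx_pre]
  c(pre, x, post)
}

## Evaluate and restore the RNG state around a seeded computation so that
## generators do not perturb the caller's random stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Read a mono WAV file
#'
#' Supports uncompressed PCM (16- or 24-bit) and IEEE float32 data. Multi-
#' channel files are averaged to mono.
#'
#' @param path Path to a `.wav` file.
#' @return A [waveform] with amplitudes scaled to `[-1, 1]` for PCM data.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path)
  invisible(readBin(con, "integer", 1L, 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt_code <- NA_integer_; n_chan <- NA_integer_; rate <- NA_integer_
  bits <- NA_integer_; data <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (id == "fmt ") {
      fmt_code <- readBin(con, "integer", 1L, 2L, endian = "little",
                          signed = FALSE)
      n_chan <- readBin(con, "integer", 1L, 2L, endian = "little")
      rate <- readBin(con, "integer", 1L, 4L, endian = "little")
      invisible(readBin(con, "integer", 1L, 4L, endian = "little"))
      invisible(readBin(con, "integer", 1L, 2L, endian = "little"))
      bits <- readBin(con, "integer", 1L, 2L, endian = "little")
      if (size > 16L) invisible(readBin(con, "raw", size - 16L))
    } else if (id == "data") {
      if (fmt_code == 3L) {
        data <- readBin(con, "double", size / 4L, 4L, endian = "little")
      } else if (fmt_code == 1L && bits == 16L) {
        data <- readBin(con, "integer", size / 2L, 2L, endian = "little",
                        signed = TRUE) / 32768
      } else if (fmt_code == 1L && bits == 24L) {
        raw3 <- readBin(con, "raw", size)
        m <- matrix(as.integer(raw3), nrow = 3L)
        v <- m[1L, ] + 256L * m[2L, ] + 65536L * m[3L, ]
        v <- ifelse(v >= 8388608, v - 16777216, v)
        data <- v / 8388608
      } else {
        stop("unsupported WAV encoding (format ", fmt_code, ", ",
             bits, " bit)")
      }
      break
    } else {
      invisible(readBin(con, "raw", size + size %% 2L))
    }
  }
  if (is.null(data)) stop("no data chunk found in ", path)
  if (n_chan > 1L) {
    data <- colMeans(matrix(data, nrow = n_chan))
  }
  waveform(data, rate, label = sub("\\.wav$", "", basename(path),
                                   ignore.case = TRUE))
}

#' Write a mono WAV file
#'
#' @param w A [waveform].
#' @param path Output path.
#' @param format `"pcm16"` (values clipped to `[-1, 1]`) or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path, format = c("pcm16", "float32")) {
  format <- match.arg(format)
  stopifnot(inherits(w, "waveform"))
  n <- length(w$samples)
  bytes_per <- if (format == "pcm16") 2L else 4L
  data_size <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  fmt_code <- if (format == "pcm16") 1L else 3L
  writeBin(fmt_code, con, 2L, endian = "little")
  writeBin(1L, con, 2L, endian = "little")
  writeBin(as.integer(w$rate), con, 4L, endian = "little")
  writeBin(as.integer(w$rate * bytes_per), con, 4L, endian = "little")
  writeBin(bytes_per, con, 2L, endian = "little")
  writeBin(8L * bytes_per, con, 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4L, endian = "little")
  if (format == "pcm16") {
    v <- pmax(-1, pmin(1, w$samples))
    writeBin(as.integer(round(v * 32767)), con, 2L, endian = "little")
  } else {
    writeBin(w$samples, con, 4L, endian = "little")
  }
  invisible(path)
}
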