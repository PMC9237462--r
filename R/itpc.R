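#' Hann-tapered phase spectra of epoched EEG
#'
#' Per epoch and channel, applies a Hann taper and a discrete Fourier
#' transform and extracts the complex phase at every frequency bin up to
#' `fmax`. With 4.5 s epochs the bin spacing is 2/9 Hz, so the 4 Hz syllable
#' rate and its harmonics land exactly on bins.
#'
#' @param ep An `epoched_eeg` with equal-length, trimmed epochs.
#' @param fmax Analysis ceiling in Hz (default 26).
#' @return An object of class `phase_spectrum`: list with `phases`
#'   (bins x channels x trials array, radians in `(-pi, pi]`), `freqs`
#'   (bin frequencies, Hz), `labels` (trial labels), `rate`.
#' @export
phase_spectrum <- function(ep, fmax = 26) {
  stopifnot(inherits(ep, "epoched_eeg"))
  d <- dim(ep$data)
  n_tr <- d[1L]; n_ch <- d[2L]; n <- d[3L]
  T_s <- n / ep$rate
  kmax <- floor(fmax * T_s)
  if (kmax < 1L) stop("fmax below the first frequency bin")
  freqs <- seq_len(kmax) / T_s
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))  # Hann taper
  phases <- array(NA_real_, dim = c(kmax, n_ch, n_tr))
  for (tr in seq_len(n_tr)) {
    x <- t(ep$data[tr, , , drop = TRUE])
    if (n_ch == 1L) x <- matrix(ep$data[tr, 1L, ], ncol = 1L)
    X <- stats::mvfft(x * w)
    phases[, , tr] <- Arg(X[2L:(kmax + 1L), , drop = FALSE])
  }
  structure(list(phases = phases, freqs = freqs, labels = ep$labels,
                 rate = ep$rate, channel_names = ep$channel_names),
            class = "phase_spectrum")
}

#' Inter-trial phase coherence of one cell
#'
#' The squared mean resultant of K unit phasors,
#' `R = (mean cos theta)^2 + (mean sin theta)^2`, ranging from 0 (no
#' coherence; expectation 1/K for uniform random phases) to 1 (perfect
#' coherence). `squared = FALSE` gives the conventional unsquared resultant
#' length for comparison.
#'
#' @param phases Numeric vector of K >= 2 phases in radians.
#' @param squared Use the squared resultant (default `TRUE`).
#' @return ITPC value in `[0, 1]`.
#' @export
itpc_cell <- function(phases, squared = TRUE) {
  if (length(phases) < 2L) stop("itpc_cell needs at least K = 2 phases")
  r2 <- mean(cos(phases))^2 + mean(sin(phases))^2
  if (squared) r2 else sqrt(r2)
}

#' ITPC table of one participant
#'
#' Computes `R(f, e, s)` for every frequency bin, electrode and stream by
#' pooling the K repetitions of each stream.
#'
#' @param ps A `phase_spectrum`.
#' @param squared Squared-resultant convention (default `TRUE`).
#' @param participant Optional participant id stored with the table.
#' @return An object of class `itpc_table`: list with `R` (bins x
#'   electrodes x streams array), `freqs`, `K` (trials per stream),
#'   `stream_info` (stream id and condition), `participant`.
#' @export
itpc_table <- function(ps, squared = TRUE, participant = NA_integer_) {
  stopifnot(inherits(ps, "phase_spectrum"))
  streams <- unique(ps$labels$stream)
  d <- dim(ps$phases)
  R <- array(NA_real_, dim = c(d[1L], d[2L], length(streams)))
  K <- integer(length(streams))
  cond <- character(length(streams))
  for (si in seq_along(streams)) {
    idx <- which(ps$labels$stream == streams[si])
    if (length(idx) < 2L)
      stop("stream ", streams[si], " has fewer than 2 trials")
    K[si] <- length(idx)
    ph <- ps$phases[, , idx, drop = FALSE]
    C <- rowMeans(cos(ph), dims = 2L)
    S <- rowMeans(sin(ph), dims = 2L)
    r2 <- C^2 + S^2
    R[, , si] <- if (squared) r2 else sqrt(r2)
    cond[si] <- as.character(ps$labels$condition[idx[1L]])
  }
  if (length(unique(K)) != 1L)
    warning("unequal trial counts across streams: ",
            paste(unique(K), collapse = ", "))
  structure(list(R = R, freqs = ps$freqs, K = K[1L],
                 stream_info = data.frame(stream = streams,
                                          condition = cond,
                                          stringsAsFactors = FALSE),
                 participant = participant),
            class = "itpc_table")
}

#' Combine per-participant ITPC tables into a study array
#'
#' @param tables List of `itpc_table`s with identical frequency bins and
#'   stream sets.
#' @return An object of class `itpc_study`: list with `R` (bins x
#'   electrodes x streams x participants), `freqs`, `K`, `stream_info`,
#'   `participants`.
#' @export
combine_itpc <- function(tables) {
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, inherits, logical(1), "itpc_table")))
  f0 <- tables[[1L]]$freqs
  s0 <- tables[[1L]]$stream_info$stream
  for (tb in tables) {
    if (!isTRUE(all.equal(tb$freqs, f0)))
      stop("tables have different frequency bins")
    if (!identical(tb$stream_info$stream, s0))
      stop("tables have different stream sets")
  }
  d <- dim(tables[[1L]]$R)
  R <- array(NA_real_, dim = c(d, length(tables)))
  for (i in seq_along(tables)) R[, , , i] <- tables[[i]]$R
  structure(list(R = R, freqs = f0, K = tables[[1L]]$K,
                 stream_info = tables[[1L]]$stream_info,
                 participants = vapply(tables, `[[`, numeric(1),
                                       "participant")),
            class = "itpc_study")
}

#' The ITPC averaging hierarchy
#'
#' From the full table `R(f, e, s, a)` computes the participant-level
#' average `R(f, a)` (mean over streams and electrodes), the grand average
#' `R(f)` (further mean over participants), and the condition-level
#' averages in which the stream mean is restricted to each condition's
#' streams.
#'
#' @param study An `itpc_study` (or a single `itpc_table`, treated as a
#'   one-participant study).
#' @return List with `R_fa` (bins x participants matrix), `R_f` (numeric
#'   vector), `R_fca` (bins x conditions x participants array),
#'   `conditions`, `freqs`.
#' @export
average_hierarchy <- function(study) {
  if (inherits(study, "itpc_table"))
    study <- combine_itpc(list(study))
  stopifnot(inherits(study, "itpc_study"))
  if (anyNA(study$R)) {
    miss <- which(is.na(study$R), arr.ind = TRUE)
    stop("missing ITPC cells (first shown as bin/electrode/stream/",
         "participant): ",
         paste(apply(utils::head(miss, 5L), 1L, paste, collapse = "/"),
               collapse = ", "))
  }
  R_fa <- apply(study$R, c(1L, 4L), mean)
  R_f <- rowMeans(R_fa)
  conds <- unique(study$stream_info$condition)
  d <- dim(study$R)
  R_fca <- array(NA_real_, dim = c(d[1L], length(conds), d[4L]),
                 dimnames = list(NULL, conds, NULL))
  for (ci in seq_along(conds)) {
    si <- which(study$stream_info$condition == conds[ci])
    R_fca[, ci, ] <- apply(study$R[, , si, , drop = FALSE], c(1L, 4L),
                           mean)
  }
  list(R_fa = R_fa, R_f = R_f, R_fca = R_fca, conditions = conds,
       freqs = study$freqs)
}

#' Surrogate-phase null distribution of participant-level ITPC
#'
#' Builds fictive participants by replacing every cell's K trial phases
#' with independent draws uniform on `(-pi, pi]` and averaging the
#' resulting ITPC values over the same streams x electrodes structure as
#' the real analysis.
#'
#' @param n_streams,n_electrodes Averaging structure (defaults 45 and 32).
#' @param K Trials per cell (default 10).
#' @param n_fictive Number of fictive participants (default 5000).
#' @param seed Integer seed; the null is reproducible under it.
#' @param squared Squared-resultant convention (default `TRUE`).
#' @return An object of class `surrogate_null`: list with `values`
#'   (n_fictive participant-level means), `params`, `seed`.
#' @export
surrogate_null <- function(n_streams = 45L, n_electrodes = 32L, K = 10L,
                           n_fictive = 5000L, seed = 1L, squared = TRUE) {
  stopifnot(K >= 2L, n_fictive >= 1L)
  cells <- n_streams * n_electrodes
  vals <- numeric(n_fictive)
  with_seed(seed, {
    chunk <- max(1L, min(n_fictive, floor(4e6 / (cells * K))))
    done <- 0L
    while (done < n_fictive) {
      m <- min(chunk, n_fictive - done)
      th <- matrix(stats::runif(K * cells * m, -pi, pi), nrow = K)
      r2 <- colMeans(cos(th))^2 + colMeans(sin(th))^2
      if (!squared) r2 <- sqrt(r2)
      vals[done + seq_len(m)] <- colMeans(matrix(r2, nrow = cells))
      done <- done + m
    }
  })
  structure(list(values = vals,
                 params = list(n_streams = n_streams,
                               n_electrodes = n_electrodes, K = K,
                               n_fictive = n_fictive, squared = squared),
                 seed = seed),
            class = "surrogate_null")
}

#' Mann-Whitney significance of an ITPC peak
#'
#' One-sided rank-based two-sample test of real participant-level ITPC
#' values against the surrogate-null fictive participants (real > null).
#' Uses the exact distribution for tiny samples and the tie-corrected
#' normal approximation otherwise (the defaults of [stats::wilcox.test()]).
#'
#' @param real Numeric vector of at least 2 participant-level ITPC values
#'   at the tested bin.
#' @param null A `surrogate_null` (or numeric vector of null values).
#' @return List with `statistic` (U), `p.value`, `n_real`, `n_null`.
#' @export
peak_significance <- function(real, null) {
  if (length(real) < 2L)
    stop("peak_significance needs at least 2 real participant values")
  nv <- if (inherits(null, "surrogate_null")) null$values else
    as.numeric(null)
  if (length(unique(c(real, nv))) == 1L)
    return(list(statistic = length(real) * length(nv) / 2, p.value = 1,
                n_real = length(real), n_null = length(nv)))
  wt <- suppressWarnings(stats::wilcox.test(real, nv,
                                            alternative = "greater"))
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       n_real = length(real), n_null = length(nv))
}

#' Extract ITPC at the stimulus rate and harmonics
#'
#' Values are read at the bin nearest each requested frequency; with 4.5 s
#' epochs the 4/8/12/16 Hz targets are exact bins. A warning is raised when
#' a requested frequency misses its nearest bin by more than half the bin
#' spacing, and an error when it exceeds the analysis ceiling.
#'
#' @param x Numeric vector `R(f)` or matrix with bins in rows (e.g.
#'   `R(f, a)`).
#' @param freqs Bin frequencies in Hz, matching the rows of `x`.
#' @param harmonics Frequencies to extract (default `c(4, 8, 12, 16)`).
#' @return For vector input a named numeric vector; for matrix input a
#'   harmonics x columns matrix.
#' @export
harmonic_extract <- function(x, freqs, harmonics = c(4, 8, 12, 16)) {
  spacing <- freqs[2L] - freqs[1L]
  if (any(harmonics > max(freqs) + spacing / 2))
    stop("requested frequency above the analysis ceiling of ",
         max(freqs), " Hz")
  bins <- vapply(harmonics, function(h) which.min(abs(freqs - h)),
                 integer(1))
  miss <- abs(freqs[bins] - harmonics)
  off <- miss >= spacing / 2 - 1e-9
  if (any(off))
    warning("frequency/bin mismatch of half a bin or more at ",
            paste(harmonics[off], collapse = ", "), " Hz")
  if (is.matrix(x)) {
    out <- x[bins, , drop = FALSE]
    rownames(out) <- paste0("f", harmonics)
    out
  } else {
    stats::setNames(x[bins], paste0("f", harmonics))
  }
}

#' Plot an ITPC spectrum
#'
#' Grand-average ITPC against frequency with the participant traces behind
#' it, in the style usual for frequency-tagging reports.
#'
#' @param avg Output of [average_hierarchy()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot_itpc_spectrum <- function(avg, ...) {
  graphics::plot(avg$freqs, avg$R_f, type = "n", xlab = "frequency (Hz)",
                 ylab = "ITPC", ylim = c(0, max(avg$R_fa)), ...)
  for (a in seq_len(ncol(avg$R_fa)))
    graphics::lines(avg$freqs, avg$R_fa[, a], col = "#9ecae1")
  graphics::lines(avg$freqs, avg$R_f, lwd = 2)
  invisible(avg)
}
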