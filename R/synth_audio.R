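## Per-class onset acoustics. Attack times are ordered so that
## stops < nasals/liquids < vowel-only aside, fricatives/sibilants slowest,
## mirroring how abruptly each manner of articulation releases energy.
.class_params <- data.frame(
  class = c("stop_voiced", "stop_unvoiced", "nasal", "liquid",
            "fricative", "sibilant", "none"),
  onset_ms = c(15, 30, 40, 45, 70, 80, 0),
  attack_ms = c(20, 25, 55, 65, 120, 130, 35),
  onset_type = c("burst", "burst", "murmur", "murmur", "noise", "noise",
                 "none"),
  stringsAsFactors = FALSE
)

## Rough first/second formant targets (Hz) for the five vowels.
.vowel_formants <- list(a = c(710, 1100), e = c(550, 1750),
                        i = c(280, 2250), o = c(450, 800),
                        u = c(310, 870))

#' Phoneme class of a consonant label
#'
#' @param consonant A consonant label (`"b"`, ..., `"r"`) or `"vowel"` /
#'   `NA` for vowel-only syllables.
#' @return One of `"stop_voiced"`, `"stop_unvoiced"`, `"fricative"`,
#'   `"sibilant"`, `"nasal"`, `"liquid"`, `"none"`.
#' @export
consonant_class <- function(consonant) {
  map <- c(b = "stop_voiced", d = "stop_voiced", g = "stop_voiced",
           k = "stop_unvoiced", p = "stop_unvoiced", t = "stop_unvoiced",
           f = "fricative", v = "fricative",
           s = "sibilant", z = "sibilant",
           m = "nasal", n = "nasal", l = "liquid", r = "liquid",
           vowel = "none")
  if (is.na(consonant)) return("none")
  if (!consonant %in% names(map)) stop("unknown consonant: ", consonant)
  unname(map[consonant])
}

#' Recipe for one synthetic syllable
#'
#' Collects every parameter the syllable synthesiser needs; class defaults
#' are filled in for whatever is not given.
#'
#' @param consonant Consonant label or `"vowel"`.
#' @param vowel One of `"a"`, `"e"`, `"i"`, `"o"`, `"u"`.
#' @param duration_ms Syllable duration (default 250 ms; the schedule-level
#'   generator draws near-isochronous durations instead).
#' @param attack_ms Rise time of the vowel amplitude envelope; class
#'   default if `NULL`.
#' @param onset_ms Duration of the class-dependent onset segment preceding
#'   the vowel; class default if `NULL`.
#' @param f0 Fundamental frequency of the vowel carrier in Hz.
#' @return A list of class `syllable_recipe`.
#' @export
syllable_recipe <- function(consonant, vowel, duration_ms = 250,
                            attack_ms = NULL, onset_ms = NULL, f0 = 220) {
  if (!vowel %in% .vowels) stop("unknown vowel: ", vowel)
  cls <- consonant_class(consonant)
  par <- .class_params[.class_params$class == cls, ]
  if (is.null(attack_ms)) attack_ms <- par$attack_ms
  if (is.null(onset_ms)) onset_ms <- par$onset_ms
  if (attack_ms >= duration_ms)
    stop("attack time (", attack_ms, " ms) must be shorter than the ",
         "syllable (", duration_ms, " ms)")
  structure(list(consonant = consonant, vowel = vowel, class = cls,
                 duration_ms = duration_ms, attack_ms = attack_ms,
                 onset_ms = onset_ms, onset_type = par$onset_type,
                 f0 = f0),
            class = "syllable_recipe")
}

#' Synthesise one consonant-vowel syllable
#'
#' A class-dependent onset segment (silence plus a brief noise burst for
#' stops, a rising noise ramp for fricatives and sibilants, a low-amplitude
#' harmonic murmur for nasals and liquids) followed by a vowel-like
#' harmonic complex whose amplitude rises with a raised-cosine attack of
#' the recipe's attack time and decays to the syllable end. The token is
#' RMS-normalised to a common reference, emulating equal-loudness
#' normalisation of recorded stimuli.
#'
#' @param recipe A [syllable_recipe].
#' @param rate Audio sampling rate (default 44100 Hz, keeping the 8 kHz top
#'   filterbank band well below Nyquist).
#' @param seed Integer seed; the same seed gives a bit-identical waveform.
#' @param rms Target root-mean-square amplitude.
#' @return A [waveform] labelled `"<consonant><vowel>"`.
#' @export
synth_syllable <- function(recipe, rate = 44100, seed = NULL, rms = 0.1) {
  stopifnot(inherits(recipe, "syllable_recipe"))
  with_seed(seed, {
    n <- round(recipe$duration_ms / 1000 * rate)
    t <- (seq_len(n) - 1L) / rate
    fm <- .vowel_formants[[recipe$vowel]]
    h_max <- floor(4000 / recipe$f0)
    vowel_sig <- numeric(n)
    for (h in seq_len(h_max)) {
      fh <- h * recipe$f0
      amp <- h^-0.6 * (1 + 2 * exp(-((fh - fm[1L]) / 150)^2) +
                         1.5 * exp(-((fh - fm[2L]) / 200)^2))
      vowel_sig <- vowel_sig + amp * sin(2 * pi * fh * t)
    }
    on_n <- round(recipe$onset_ms / 1000 * rate)
    att_n <- max(1L, round(recipe$attack_ms / 1000 * rate))
    env <- numeric(n)
    i_rise <- seq(on_n + 1L, min(n, on_n + att_n))
    env[i_rise] <- 0.5 - 0.5 * cos(pi * seq_along(i_rise) / att_n)
    if (on_n + att_n < n) env[(on_n + att_n + 1L):n] <- 1
    rel_n <- min(round(0.04 * rate), n %/% 4L)     # 40 ms release
    i_rel <- (n - rel_n + 1L):n
    env[i_rel] <- env[i_rel] * (0.5 + 0.5 * cos(pi * seq_len(rel_n) /
                                                  rel_n))
    x <- vowel_sig * env
    if (on_n > 0L) {
      on_t <- (seq_len(on_n) - 1L) / rate
      onset_seg <- switch(
        recipe$onset_type,
        burst = {
          sil <- round(0.4 * on_n)
          burst <- numeric(on_n)
          idx <- (sil + 1L):on_n
          noise <- stats::rnorm(length(idx))
          burst[idx] <- noise * exp(-seq_along(idx) / (0.2 * on_n)) * 0.8
          burst
        },
        noise = {
          hf <- stats::rnorm(on_n)
          hf <- hf - stats::filter(hf, rep(1 / 9, 9), sides = 2L,
                                   circular = TRUE)  # crude high-pass
          as.numeric(hf) * (seq_len(on_n) / on_n)^0.9 * 0.8
        },
        murmur = 0.25 * sin(2 * pi * recipe$f0 * on_t) *
          (seq_len(on_n) / on_n),
        none = numeric(on_n)
      )
      x[seq_len(on_n)] <- x[seq_len(on_n)] + onset_seg
    }
    x <- x / sqrt(mean(x^2)) * rms
    waveform(x, rate,
             label = if (recipe$class == "none") recipe$vowel else
               paste0(recipe$consonant, recipe$vowel))
  })
}

#' Draw near-isochronous syllable durations
#'
#' Durations in ms from a normal distribution (mean 249.05, sd 2.42)
#' truncated to the observed stimulus range (241.63, 255.28), emulating
#' the slight duration scatter of pitch-preserving duration modification.
#'
#' @param n Number of draws.
#' @param mean_ms,sd_ms,min_ms,max_ms Distribution parameters.
#' @return Numeric vector of durations in ms.
#' @export
draw_durations <- function(n, mean_ms = 249.05, sd_ms = 2.42,
                           min_ms = 241.63, max_ms = 255.28) {
  out <- numeric(0)
  while (length(out) < n) {
    d <- stats::rnorm(2L * (n - length(out)) + 8L, mean_ms, sd_ms)
    out <- c(out, d[d >= min_ms & d <= max_ms])
  }
  out[seq_len(n)]
}

#' Build the bank of syllable tokens for a schedule
#'
#' Synthesises one audio token for every distinct syllable the schedule
#' uses (the 5 vowels of every condition plus all filler deviants), with
#' near-isochronous durations drawn per token.
#'
#' @param sch A `stimulus_schedule`.
#' @param rate Audio sampling rate.
#' @param seed Integer seed.
#' @param isochronous If `TRUE`, fix every duration at exactly 250 ms
#'   instead of drawing.
#' @return An object of class `syllable_bank`: list with `tokens` (named
#'   list of [waveform]s) and `info` (data frame: syllable, consonant,
#'   vowel, class, duration_ms).
#' @export
syllable_bank <- function(sch, rate = 44100, seed = 1L,
                          isochronous = FALSE) {
  stopifnot(inherits(sch, "stimulus_schedule"))
  syls <- unique(c(unlist(sch$streams),
                   stats::na.omit(sch$presentations$deviant_syllable)))
  cons <- ifelse(nchar(syls) == 1L, "vowel",
                 substring(syls, 1L, nchar(syls) - 1L))
  vow <- substring(syls, nchar(syls))
  with_seed(seed, {
    dur <- if (isochronous) rep(250, length(syls)) else
      draw_durations(length(syls))
    tokens <- vector("list", length(syls))
    names(tokens) <- syls
    for (i in seq_along(syls)) {
      rec <- syllable_recipe(cons[i], vow[i], duration_ms = dur[i])
      tokens[[i]] <- synth_syllable(rec, rate = rate)
    }
    structure(list(tokens = tokens,
                   info = data.frame(syllable = syls, consonant = cons,
                                     vowel = vow,
                                     class = vapply(cons,
                                                    consonant_class,
                                                    character(1)),
                                     duration_ms = dur,
                                     stringsAsFactors = FALSE)),
              class = "syllable_bank")
  })
}

#' Render the audio of one stream presentation
#'
#' Concatenates the 20 syllable tokens of the requested stream; for filler
#' presentations the deviant syllable replaces the token at the stored
#' position.
#'
#' @param sch A `stimulus_schedule`.
#' @param bank A [syllable_bank()].
#' @param condition,stream Which stream to render.
#' @param deviant_pos,deviant_syllable Filler substitution (both `NULL`
#'   for target streams).
#' @return A [waveform] of roughly 5 s.
#' @export
render_stream <- function(sch, bank, condition, stream,
                          deviant_pos = NULL, deviant_syllable = NULL) {
  stopifnot(inherits(sch, "stimulus_schedule"),
            inherits(bank, "syllable_bank"))
  if (!condition %in% names(sch$streams))
    stop("unknown condition: ", condition)
  syl <- sch$streams[[condition]][[stream]]
  if (!is.null(deviant_pos)) syl[deviant_pos] <- deviant_syllable
  missing <- setdiff(syl, names(bank$tokens))
  if (length(missing))
    stop("syllable token(s) missing from the bank: ",
         paste(unique(missing), collapse = ", "))
  rate <- bank$tokens[[syl[1L]]]$rate
  waveform(unlist(lapply(bank$tokens[syl], `[[`, "samples"),
                  use.names = FALSE),
           rate, label = paste0(condition, "/", stream))
}
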