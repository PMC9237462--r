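#' Generate and analyse a full synthetic study
#'
#' The desk-scale stand-in for the complete experiment: builds the
#' stimulus schedule, synthesises the syllable bank, measures every
#' token's edge markers through the cochlear-envelope pipeline, couples
#' each condition's neural jitter to its mean maximum-derivative latency,
#' simulates every participant's EEG, and runs the preprocessing and ITPC
#' stages — returning the combined ITPC study table together with the
#' ground truth that generated it.
#'
#' The jitter model is `sd_ms = jitter_base_ms + coupling * md_latency_ms`
#' per condition; positive coupling makes late-edge (slow-attack)
#' conditions less phase-locked, which is the relationship the pipeline is
#' built to detect.
#'
#' @param n_participants Number of simulated participants (default 25).
#' @param conditions Condition labels (default all 15).
#' @param reps Stream repetitions = trials per ITPC cell (default 10).
#' @param fillers Unique filler presentations (default 50; use 0 for
#'   reduced designs).
#' @param blocks Blocks (default 5; `length(conditions)` must be divisible
#'   by it).
#' @param coupling Jitter-vs-MD-latency slope (ms of jitter sd per ms of
#'   latency; default 1).
#' @param jitter_base_ms Condition-independent jitter floor in ms.
#' @param cfg An [eeg_sim_config()].
#' @param audio_rate Audio sampling rate for the syllable bank.
#' @param fmax ITPC analysis ceiling in Hz.
#' @param seed Integer seed governing every random stage.
#' @param verbose Print progress?
#' @return An object of class `entrain_study`: list with `itpc` (an
#'   `itpc_study`), `markers` (condition-level edge-marker data frame),
#'   `token_markers`, `schedule`, `bank_info`, `ground_truth` (per-
#'   condition jitter sd, coupling, cfg), `seed`.
#' @export
make_study <- function(n_participants = 25L,
                       conditions = condition_labels(), reps = 10L,
                       fillers = 50L, blocks = 5L, coupling = 1,
                       jitter_base_ms = 2, cfg = eeg_sim_config(),
                       audio_rate = 44100, fmax = 26, seed = 1L,
                       verbose = FALSE) {
  sch <- build_schedule(conditions = conditions, reps = reps,
                        fillers = fillers, blocks = blocks, seed = seed)
  bank <- syllable_bank(sch, rate = audio_rate, seed = seed + 1L)
  tok_m <- token_markers(bank)
  cond_m <- condition_markers(tok_m, sch)
  jit <- stats::setNames(jitter_base_ms +
                           coupling * cond_m$md_latency,
                         cond_m$condition)
  ev <- study_events(sch, bank, tok_m, jit)
  pseeds <- with_seed(seed, sample.int(2^31 - 2L, n_participants))
  tables <- vector("list", n_participants)
  for (a in seq_len(n_participants)) {
    if (verbose) message("participant ", a, "/", n_participants)
    rec <- simulate_eeg(ev$presentations, ev$syllables, cfg,
                        seed = pseeds[a])
    ep <- preprocess_eeg(rec)
    tables[[a]] <- itpc_table(phase_spectrum(ep, fmax = fmax),
                              participant = a)
  }
  structure(list(itpc = combine_itpc(tables), markers = cond_m,
                 token_markers = tok_m, schedule = sch,
                 bank_info = bank$info,
                 ground_truth = list(jitter_sd_ms = jit,
                                     coupling = coupling,
                                     jitter_base_ms = jitter_base_ms,
                                     cfg = cfg, participant_seeds = pseeds),
                 seed = seed),
            class = "entrain_study")
}

#' Edge markers of every token in a syllable bank
#'
#' Runs each token through the cochlear-envelope chain and computes its
#' marker set on the bandpassed envelope.
#'
#' @param bank A [syllable_bank()].
#' @param stage Envelope stage for the markers; see [waveform_markers()].
#' @param ... Passed to [cochlear_envelope()].
#' @return Data frame: one row per token with its markers, consonant,
#'   vowel, class and duration.
#' @export
token_markers <- function(bank, stage = "summed", ...) {
  stopifnot(inherits(bank, "syllable_bank"))
  ms <- lapply(bank$tokens, function(w) waveform_markers(w, stage, ...))
  cbind(bank$info, do.call(rbind, lapply(ms, as.numeric)) |>
          (\(m) {colnames(m) <- names(ms[[1L]]); as.data.frame(m)})())
}

#' Condition-level edge markers
#'
#' Fieldwise mean of the marker sets of the five (non-deviant) syllables
#' of each condition.
#'
#' @param tok_m Output of [token_markers()].
#' @param sch The `stimulus_schedule` naming each condition's syllables.
#' @return Data frame: one row per condition.
#' @export
condition_markers <- function(tok_m, sch) {
  marker_cols <- c("sharpness", "ma", "ma_latency", "ma80_latency",
                   "plateau", "md", "md_latency", "gini")
  rows <- lapply(names(sch$streams), function(cond) {
    syls <- unique(unlist(sch$streams[[cond]]))
    sets <- lapply(syls, function(s)
      unlist(tok_m[tok_m$syllable == s, marker_cols]))
    cbind(data.frame(condition = cond, stringsAsFactors = FALSE),
          as.data.frame(as.list(condition_average(sets))))
  })
  do.call(rbind, rows)
}

## Absolute stream-onset and syllable-edge times for the whole schedule.
## Edge time of a syllable = stream onset + cumulative duration of the
## preceding tokens + the token's own MD latency.
study_events <- function(sch, bank, tok_m, jitter_sd_ms) {
  p <- sch$presentations
  p$stream_id <- paste0(p$condition, ".", p$stream)
  dur_of <- stats::setNames(bank$info$duration_ms / 1000,
                            bank$info$syllable)
  md_of <- stats::setNames(tok_m$md_latency / 1000, tok_m$syllable)
  syl_rows <- vector("list", nrow(p))
  for (i in seq_len(nrow(p))) {
    syl <- sch$streams[[p$condition[i]]][[p$stream[i]]]
    if (p$is_filler[i]) syl[p$deviant_pos[i]] <- p$deviant_syllable[i]
    onsets <- p$onset_s[i] + c(0, cumsum(dur_of[syl]))[seq_along(syl)]
    syl_rows[[i]] <- data.frame(
      time_s = onsets + md_of[syl],
      jitter_sd_ms = jitter_sd_ms[[p$condition[i]]]
    )
  }
  list(presentations = data.frame(onset_s = p$onset_s,
                                  stream = p$stream_id,
                                  condition = p$condition,
                                  is_filler = p$is_filler,
                                  stringsAsFactors = FALSE),
       syllables = do.call(rbind, syl_rows))
}

#' Participant-by-condition ITPC at the stimulus harmonics
#'
#' Condition-level ITPC (mean over electrodes and the condition's streams)
#' extracted at 4, 8, 12 and 16 Hz for every participant: the observation
#' table on which the ITPC PCA and the group statistics operate.
#'
#' @param study An `entrain_study` (or an `itpc_study`).
#' @param harmonics Frequencies to extract.
#' @return Data frame with columns `participant`, `condition`, `f4`,
#'   `f8`, `f12`, `f16`.
#' @export
study_itpc_conditions <- function(study, harmonics = c(4, 8, 12, 16)) {
  its <- if (inherits(study, "entrain_study")) study$itpc else study
  stopifnot(inherits(its, "itpc_study"))
  avg <- average_hierarchy(its)
  n_a <- dim(avg$R_fca)[3L]
  rows <- lapply(seq_len(n_a), function(a) {
    h <- harmonic_extract(avg$R_fca[, , a, drop = TRUE], avg$freqs,
                          harmonics)
    data.frame(participant = a, condition = avg$conditions,
               t(h), stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}
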