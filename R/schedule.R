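## The three master vowel orders open with the published first five
## syllables; positions 6-20 are generated under the design constraints.
.vowel_prefixes <- list(c("a", "u", "e", "a", "i"),
                        c("e", "a", "i", "u", "e"),
                        c("i", "o", "u", "o", "a"))

.vowels <- c("a", "e", "i", "o", "u")

#' Stimulus condition labels
#'
#' The 15 conditions: one vowel-only condition and 14 syllable-initial
#' consonants.
#'
#' @return Character vector of condition labels.
#' @export
condition_labels <- function() {
  c("vowel", "b", "d", "g", "k", "p", "t", "f", "v", "s", "z",
    "m", "n", "l", "r")
}

## Complete a 20-syllable vowel order: balanced (each vowel 4 times) and no
## vowel repeated in consecutive syllables. Rejection sampling on the
## remaining multiset; the constraint is loose so acceptance is fast.
complete_vowel_seq <- function(prefix, len = 20L) {
  counts <- stats::setNames(rep(len / length(.vowels), length(.vowels)),
                            .vowels)
  tab <- table(factor(prefix, levels = .vowels))
  rest <- rep(names(counts), counts - as.integer(tab))
  for (try in seq_len(10000L)) {
    cand <- sample(rest)
    seq_full <- c(prefix, cand)
    if (!any(seq_full[-1L] == seq_full[-length(seq_full)]))
      return(seq_full)
  }
  stop("could not complete a vowel sequence without adjacent repeats")
}

#' Build the full pseudo-randomised stimulus schedule
#'
#' Generates the experiment plan: for every condition, three 20-syllable
#' streams whose vowel orders are shared across conditions; conditions
#' assigned to blocks (`length(conditions) / blocks` per block); within a
#' block, `reps` repetitions of each of the block's streams plus the
#' block's share of unique filler presentations, in pseudo-random order
#' with a fixed inter-stimulus interval. Fillers replace one syllable in
#' the second half of a stream (positions 11-20) with a syllable starting
#' in a consonant from a different phoneme group.
#'
#' @param conditions Condition labels (default the 15 of
#'   [condition_labels()]). Must be divisible across `blocks`.
#' @param streams_per_condition Streams per condition (default 3).
#' @param reps Presentations of each stream (default 10).
#' @param fillers Total unique filler presentations (default 50; must be
#'   divisible by `blocks`).
#' @param blocks Number of blocks (default 5).
#' @param stream_s Stream duration used for onset bookkeeping (default 5).
#' @param isi_s Inter-stimulus interval in seconds (default 2).
#' @param break_s Pause between blocks (default 30).
#' @param seed Integer seed.
#' @return An object of class `stimulus_schedule`: list with
#'   `presentations` (one row per presentation: `block`, `slot`, `onset_s`,
#'   `condition`, `stream`, `is_filler`, `filler_id`, `deviant_pos`,
#'   `deviant_syllable`), `streams` (condition -> list of syllable-label
#'   vectors), `vowel_sequences`, `params`, `seed`.
#' @export
build_schedule <- function(conditions = condition_labels(),
                           streams_per_condition = 3L, reps = 10L,
                           fillers = 50L, blocks = 5L, stream_s = 5,
                           isi_s = 2, break_s = 30, seed = 1L) {
  nc <- length(conditions)
  if (nc %% blocks != 0L)
    stop("conditions (", nc, ") not divisible into ", blocks, " blocks")
  if (fillers %% blocks != 0L)
    stop("fillers (", fillers, ") not divisible into ", blocks, " blocks")
  if (anyDuplicated(conditions)) stop("duplicate condition labels")
  with_seed(seed, {
    vseqs <- lapply(seq_len(streams_per_condition), function(i) {
      pre <- .vowel_prefixes[[((i - 1L) %% 3L) + 1L]]
      complete_vowel_seq(pre)
    })
    streams <- lapply(conditions, function(cond) {
      lapply(vseqs, function(vs)
        if (cond == "vowel") vs else paste0(cond, vs))
    })
    names(streams) <- conditions
    cond_of_block <- split(sample(conditions), rep(seq_len(blocks),
                                                   each = nc / blocks))
    groups <- phoneme_groups()$three
    group_of <- unlist(lapply(names(groups), function(g)
      stats::setNames(rep(g, length(groups[[g]])), groups[[g]])))
    all_cons <- unname(unlist(groups))
    fpb <- fillers / blocks
    filler_id <- 0L
    block_rows <- lapply(seq_len(blocks), function(b) {
      conds <- cond_of_block[[b]]
      tgt <- expand.grid(condition = conds,
                         stream = seq_len(streams_per_condition),
                         rep = seq_len(reps), stringsAsFactors = FALSE)
      tgt$is_filler <- FALSE
      tgt$filler_id <- NA_integer_
      tgt$deviant_pos <- NA_integer_
      tgt$deviant_syllable <- NA_character_
      fil <- NULL
      if (fpb > 0L) {
        fc <- conds[((seq_len(fpb) - 1L) %% length(conds)) + 1L]
        fs <- ((seq_len(fpb) - 1L) %% streams_per_condition) + 1L
        pos <- sample(11:20, fpb, replace = TRUE)
        dev_syl <- character(fpb)
        for (i in seq_len(fpb)) {
          pool <- if (fc[i] == "vowel") all_cons else
            setdiff(all_cons, groups[[group_of[[fc[i]]]]])
          dev_cons <- sample(pool, 1L)
          vow <- vseqs[[fs[i]]][pos[i]]
          dev_syl[i] <- paste0(dev_cons, vow)
        }
        fil <- data.frame(condition = fc, stream = fs, rep = NA_integer_,
                          is_filler = TRUE,
                          filler_id = filler_id + seq_len(fpb),
                          deviant_pos = pos, deviant_syllable = dev_syl,
                          stringsAsFactors = FALSE)
        filler_id <<- filler_id + fpb
      }
      rows <- rbind(tgt, fil)
      rows <- rows[sample(nrow(rows)), , drop = FALSE]
      rows$block <- b
      rows$slot <- seq_len(nrow(rows))
      rows
    })
    pres <- do.call(rbind, block_rows)
    slot_dur <- stream_s + isi_s
    block_len <- max(table(pres$block)) * slot_dur
    pres$onset_s <- (pres$block - 1L) * (block_len + break_s) +
      (pres$slot - 1L) * slot_dur
    pres$rep <- NULL
    rownames(pres) <- NULL
    pres <- pres[, c("block", "slot", "onset_s", "condition", "stream",
                     "is_filler", "filler_id", "deviant_pos",
                     "deviant_syllable")]
    structure(list(presentations = pres, streams = streams,
                   vowel_sequences = vseqs,
                   params = list(conditions = conditions,
                                 streams_per_condition =
                                   streams_per_condition,
                                 reps = reps, fillers = fillers,
                                 blocks = blocks, stream_s = stream_s,
                                 isi_s = isi_s, break_s = break_s),
                   seed = seed),
              class = "stimulus_schedule")
  })
}

#' @export
print.stimulus_schedule <- function(x, ...) {
  p <- x$presentations
  cat(sprintf(paste0("<stimulus_schedule: %d conditions, %d target + %d ",
                     "filler presentations in %d blocks>\n"),
              length(x$params$conditions), sum(!p$is_filler),
              sum(p$is_filler), x$params$blocks))
  invisible(x)
}

#' Check every schedule invariant
#'
#' Verifies presentation counts, per-block composition, vowel-order
#' constraints (no consecutive repeats; orders shared across conditions),
#' filler uniqueness and deviant placement in the second half.
#'
#' @param sch A `stimulus_schedule`.
#' @return `TRUE` invisibly, or an error describing the first violation.
#' @export
validate_schedule <- function(sch) {
  stopifnot(inherits(sch, "stimulus_schedule"))
  p <- sch$presentations
  pr <- sch$params
  n_target <- length(pr$conditions) * pr$streams_per_condition * pr$reps
  if (sum(!p$is_filler) != n_target)
    stop("expected ", n_target, " target presentations, found ",
         sum(!p$is_filler))
  if (sum(p$is_filler) != pr$fillers)
    stop("expected ", pr$fillers, " filler presentations")
  fid <- p$filler_id[p$is_filler]
  if (anyDuplicated(fid)) stop("filler presented more than once")
  if (any(p$deviant_pos[p$is_filler] < 11L |
          p$deviant_pos[p$is_filler] > 20L))
    stop("filler deviant outside syllable positions 11-20")
  for (b in seq_len(pr$blocks)) {
    pb <- p[p$block == b, ]
    if (sum(!pb$is_filler) != n_target / pr$blocks)
      stop("block ", b, " target count wrong")
    if (sum(pb$is_filler) != pr$fillers / pr$blocks)
      stop("block ", b, " filler count wrong")
    tb <- table(pb$condition[!pb$is_filler], pb$stream[!pb$is_filler])
    if (any(tb != pr$reps))
      stop("block ", b, ": streams not repeated exactly ", pr$reps,
           " times")
  }
  cond_block <- unique(p[!p$is_filler, c("condition", "block")])
  if (anyDuplicated(cond_block$condition))
    stop("a condition appears in more than one block")
  for (vs in sch$vowel_sequences) {
    if (length(vs) != 20L) stop("vowel sequence not 20 syllables long")
    if (any(vs[-1L] == vs[-20L]))
      stop("vowel repeated in consecutive syllables")
  }
  for (cond in names(sch$streams)) {
    for (i in seq_along(sch$streams[[cond]])) {
      syl <- sch$streams[[cond]][[i]]
      vow <- substring(syl, nchar(syl))
      if (!identical(vow, sch$vowel_sequences[[i]]))
        stop("condition ", cond, " stream ", i,
             " does not share the master vowel order")
    }
  }
  invisible(TRUE)
}
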