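test_that("default schedule counts match the experimental design", {
  sch <- build_schedule(seed = 3)
  p <- sch$presentations
  expect_equal(sum(!p$is_filler), 450L)
  expect_equal(sum(p$is_filler), 50L)
  expect_equal(nrow(p), 500L)
  expect_equal(length(unique(p$block)), 5L)
  for (b in 1:5) {
    expect_equal(sum(p$block == b & !p$is_filler), 90L)
    expect_equal(sum(p$block == b & p$is_filler), 10L)
  }
  expect_true(validate_schedule(sch))
  # inter-stimulus interval: onsets within a block advance by 7 s
  b1 <- p[p$block == 1, ]
  expect_equal(unique(diff(b1$onset_s[order(b1$slot)])), 7)
})

test_that("schedule invariants survive many seeds", {
  for (seed in 1:25)
    expect_true(validate_schedule(build_schedule(seed = seed)))
})

test_that("printed vowel orders open the master sequences", {
  sch <- build_schedule(seed = 8)
  expect_equal(sch$vowel_sequences[[1]][1:5],
               c("a", "u", "e", "a", "i"))
  expect_equal(sch$vowel_sequences[[2]][1:5],
               c("e", "a", "i", "u", "e"))
  expect_equal(sch$vowel_sequences[[3]][1:5],
               c("i", "o", "u", "o", "a"))
  expect_equal(sch$streams[["vowel"]][[1]][1:5],
               c("a", "u", "e", "a", "i"))
  expect_equal(sch$streams[["b"]][[1]][1:5],
               c("ba", "bu", "be", "ba", "bi"))
  # orders are shared across conditions and balanced over vowels
  for (vs in sch$vowel_sequences)
    expect_true(all(table(vs) == 4))
})

test_that("schedule builder rejects infeasible parameter sets", {
  expect_error(build_schedule(conditions = letters[1:7], blocks = 5),
               "divisible")
  expect_error(build_schedule(fillers = 13, blocks = 5), "divisible")
  expect_error(build_schedule(conditions = c("b", "b", "d"), blocks = 3,
                              fillers = 0),
               "duplicate")
})

test_that("syllable durations emulate the near-isochronous design", {
  set.seed(41)
  d <- draw_durations(10000)
  expect_lt(abs(mean(d) - 249.05), 1)
  expect_lt(abs(stats::sd(d) - 2.42), 0.5)
  expect_gte(min(d), 241.63)
  expect_lte(max(d), 255.28)
})

test_that("syllable synthesis is seeded and validates its recipe", {
  r <- syllable_recipe("s", "i")
  w1 <- synth_syllable(r, seed = 7)
  w2 <- synth_syllable(r, seed = 7)
  expect_identical(w1$samples, w2$samples)
  expect_equal(sqrt(mean(w1$samples^2)), 0.1, tolerance = 1e-9)
  expect_error(syllable_recipe("s", "i", attack_ms = 300), "attack")
  expect_error(syllable_recipe("q", "a"), "unknown consonant")
  expect_error(syllable_recipe("b", "y"), "unknown vowel")
})

test_that("sharper recipes trigger earlier, larger maximum derivatives", {
  m10 <- waveform_markers(synth_syllable(
    syllable_recipe("vowel", "a", attack_ms = 10), seed = 5))
  m80 <- waveform_markers(synth_syllable(
    syllable_recipe("vowel", "a", attack_ms = 80), seed = 5))
  expect_gt(m10[["md"]], m80[["md"]])
  expect_lt(m10[["md_latency"]], m80[["md_latency"]])
  # a pure vowel rises immediately: early maximum derivative
  mv <- waveform_markers(synth_syllable(syllable_recipe("vowel", "e"),
                                        seed = 6))
  expect_lt(mv[["md_latency"]], 50)
})

test_that("rendered streams concatenate the right tokens", {
  sch <- build_schedule(seed = 9)
  bank <- syllable_bank(sch, seed = 10, isochronous = TRUE)
  w <- render_stream(sch, bank, "b", 1)
  expect_equal(length(w$samples), round(5 * 44100))
  fil <- sch$presentations[sch$presentations$is_filler, ][1, ]
  wf <- render_stream(sch, bank, fil$condition, fil$stream,
                      fil$deviant_pos, fil$deviant_syllable)
  syl <- sch$streams[[fil$condition]][[fil$stream]]
  expect_gte(fil$deviant_pos, 11L)
  expect_false(fil$deviant_syllable == syl[fil$deviant_pos])
  bank2 <- bank
  bank2$tokens[["ba"]] <- NULL
  expect_error(render_stream(sch, bank2, "b", 1), "missing")
  expect_error(render_stream(sch, bank, "q", 1), "unknown condition")
})

test_that("filler deviants come from a different phoneme group", {
  sch <- build_schedule(seed = 12)
  fil <- sch$presentations[sch$presentations$is_filler, ]
  grp <- phoneme_groups()$three
  group_of <- function(cons) names(grp)[vapply(grp, function(g)
    cons %in% g, logical(1))]
  for (i in seq_len(nrow(fil))) {
    dev_cons <- sub("[aeiou]$", "", fil$deviant_syllable[i])
    if (fil$condition[i] != "vowel")
      expect_false(identical(group_of(dev_cons),
                             group_of(fil$condition[i])))
  }
})

test_that("simulated EEG is reproducible and phase-locks as configured", {
  ev <- toy_events(10, 0)
  cfg <- eeg_sim_config(n_channels = 2, noise_amp = 0)
  r1 <- simulate_eeg(ev$presentations, ev$syllables, cfg, seed = 2)
  r2 <- simulate_eeg(ev$presentations, ev$syllables, cfg, seed = 2)
  expect_identical(r1$data, r2$data)
  tb <- itpc_table(phase_spectrum(preprocess_eeg(r1)))
  bin4 <- which.min(abs(tb$freqs - 4))
  expect_equal(mean(tb$R[bin4, , 1]), 1, tolerance = 1e-6)
})

test_that("kernel-free simulation stays inside the surrogate null band", {
  ev <- toy_events(10, 0)
  cfg <- eeg_sim_config(n_channels = 8, kernel_gain = 0, noise_amp = 8)
  rec <- simulate_eeg(ev$presentations, ev$syllables, cfg, seed = 3)
  tb <- itpc_table(phase_spectrum(preprocess_eeg(rec)))
  bin4 <- which.min(abs(tb$freqs - 4))
  part_mean <- mean(tb$R[bin4, , 1])
  null <- surrogate_null(1, 8, 10, n_fictive = 2000, seed = 4)
  expect_lt(part_mean, stats::quantile(null$values, 0.995))
  expect_gt(part_mean, stats::quantile(null$values, 0.005))
})

test_that("phase locking decreases monotonically with edge jitter", {
  cfg <- eeg_sim_config(n_channels = 8)
  itpc4 <- vapply(c(0, 25, 50, 80), function(j) {
    ev <- toy_events(10, j)
    tb <- itpc_table(phase_spectrum(preprocess_eeg(
      simulate_eeg(ev$presentations, ev$syllables, cfg, seed = 6))))
    mean(tb$R[which.min(abs(tb$freqs - 4)), , 1])
  }, numeric(1))
  expect_true(all(diff(itpc4) < 0))
})

test_that("pink noise has unit variance and a falling spectrum", {
  set.seed(44)
  x <- pink_noise(20000, 1)
  expect_equal(stats::sd(x), 1, tolerance = 1e-9)
  spec <- Mod(stats::fft(x))^2
  lo <- mean(spec[2:100])
  hi <- mean(spec[5000:6000])
  expect_gt(lo / hi, 10)
  w <- pink_noise(5001, 0)   # odd length, white
  expect_equal(stats::sd(w), 1, tolerance = 1e-9)
})
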