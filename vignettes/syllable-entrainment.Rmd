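---
title: "Acoustic edges and neural entrainment to syllable streams: the methods behind sylentrain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Acoustic edges and neural entrainment to syllable streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

When listeners hear a stream of consonant–vowel (CV) syllables presented at
a near-isochronous 4 Hz rate, EEG activity phase-locks to the syllable
rhythm. How strongly it locks appears to depend on the *acoustic edges* the
syllables offer — rapid rises in the amplitude envelope at syllable onset
or at the consonant–vowel transition. `sylentrain` implements the full
analysis chain needed to study this question: it turns syllable audio into
cochlear-style envelopes and scalar *edge markers*, turns multichannel EEG
into inter-trial phase coherence (ITPC) spectra with surrogate-based
significance, and links the two with condition-level statistics. A
synthetic-data generator reproduces the entire experiment — schedules,
audio, EEG — so that every stage can be exercised and validated without any
recordings.

The experimental design the package models: 15 conditions (14 syllable-
initial consonants plus a vowel-only condition), 3 streams per condition of
20 syllables each (5 s at 4 Hz), every stream repeated 10 times, plus 50
single-presentation filler streams carrying a deviant syllable for the
attention task; 32-channel EEG at 1 kHz; 25 participants.

## Envelope extraction

Audio is passed through a bank of 32 fourth-order gammatone filters,
log-spaced from 80 Hz to 8 kHz, with equivalent-rectangular-bandwidth
(ERB) bandwidths — a standard cochleagram front end. Each band's Hilbert
envelope is computed and the bands are summed. Two numerical choices
deserve comment:

* **Envelope processing rate.** The summed envelope is decimated to
  250 Hz (with a zero-phase anti-aliasing low-pass at 40% of the target
  rate) before modulation-rate filtering. The 2–10 Hz bandpass is a
  351-tap linear-phase Kaiser-window FIR (β = 5, ~−50 dB sidelobes); at
  250 Hz this kernel spans 1.4 s, which is what a 2 Hz lower band edge
  needs. We verified numerically that at a 1 kHz envelope rate the same
  kernel leaves DC attenuated by only 6 dB and 0.5 Hz by 6 dB — it cannot
  function as the intended bandpass — whereas at 250 Hz it attenuates both
  by more than 40 dB while passing 6 Hz within ±0.05 dB with exactly zero
  phase shift.
* **Padding.** A 250 ms syllable yields 63 envelope samples at 250 Hz,
  fewer than the filter's 351 taps, so the envelope is reflection-padded
  by 800 ms per side before filtering and cropped afterwards. Reflection
  avoids manufacturing a spurious onset edge at the syllable boundary.

## Edge markers

Eight scalar markers summarise the envelope's edginess: sharpness (the
mean of the positive discrete derivative), the maximum amplitude (MA) and
its latency, the latency to 80% of MA, the plateau width (time spent
above 80% of MA around the peak), the maximum derivative (MD) and its
latency, and the Gini index

$$G = \frac{\sum_i \sum_j |x_i - x_j|}{2 n \sum_i x_i},$$

which is 0 for a flat envelope and approaches 1 for a single prominent
peak. The implementation uses the sorted O(n log n) form; the test suite
pins it to the O(n²) double loop at 1e-12. All latency-of-maximum
definitions break ties by first occurrence, the discrete derivative is a
forward difference assigned to its left sample, and t = 0 is the syllable
audio onset.

**Which envelope stage the markers see.** By default the markers are
computed on the summed envelope (after anti-aliased decimation), not on
the 2–10 Hz bandpassed version, and this choice matters. The 2–10 Hz
filter removes precisely the spectral content that distinguishes a 10 ms
attack from an 80 ms attack (both are smoothed to band-limited rises), so
maximum-derivative markers computed post-bandpass are blind to fast
edges. On the summed envelope, MD and its latency cleanly track the
attack: sharper attacks give strictly larger MD at strictly earlier
latency. The bandpassed stage remains available (`stage = "bandpassed"`
in `waveform_markers()`) for comparison.

A related caveat, which the marker set inherits from its definitions: for
a single, RMS-normalised syllable, *sharpness* (the mean positive
derivative over the whole token) is governed mostly by how peaked the
envelope is, not by how fast it rises — a slow-onset syllable that
concentrates its energy late ends up with a taller peak after
normalisation, hence more total positive variation. Sharpness therefore
separates envelope *shapes*, not attack speeds, on isolated tokens; its
attack sensitivity is only recovered on controlled envelope families
(tested on logistic onsets of varying steepness, where range and rise
co-vary). The markers that carry attack information on realistic tokens
are MD and MD latency, and those drive the synthetic coupling below.

## EEG preprocessing

The recording is bandpass filtered between 1 and 50 Hz with a zero-phase
contract, realised by applying the squared-magnitude response of cascaded
Butterworth designs (order 8 low-pass, order 2 high-pass) in the
frequency domain — the forward–backward equivalent without edge
transients. Channels are re-referenced to the instantaneous average (an
idempotent operation that zeroes the channel mean at every sample).

Ocular artifacts are handled by a rejection rule over any blind-source-
separation decomposition supplied by the caller: a component is discarded
when the share of its back-projected broadband power that falls in the
designated frontal channels (default Fp1, Fp2, F7, F8) exceeds 12%. The
decomposition backend is deliberately exchangeable — the bespoke content
is the rejection criterion, and because back-projected power factors into
(mixing weights)² × (source power), the share reduces to a ratio of
squared mixing weights. The rejection is a linear, time-invariant channel
mixing, so applying it on the continuous recording commutes with the
epoching that follows.

Epochs of 5 s are cut at each (non-filler) stream onset and the first
500 ms are discarded to keep transient onset responses out of the
steady-state spectra, leaving 4.5 s — which puts 4 Hz and its harmonics
exactly on Fourier bins (bin spacing 2/9 Hz).

## ITPC and its surrogate null

Each epoch is Hann-tapered and Fourier transformed; at every bin the
phase is retained. For a cell (electrode, stream) with K = 10 trials, the
coherence statistic is the **squared** mean resultant

$$R = \left(\tfrac{1}{K}\sum_k \cos\theta_k\right)^2 +
      \left(\tfrac{1}{K}\sum_k \sin\theta_k\right)^2 ,$$

which for uniform random phases has expectation exactly 1/K = 0.1 — the
calibration that motivates the squared form (a `squared = FALSE` flag
exposes the conventional unsquared resultant). Cells are averaged over
electrodes and streams to the participant level R(f, a), then over
participants to R(f); condition-level values restrict the stream average
to each condition's three streams.

Significance of a spectral peak is assessed against fictive participants:
each is built by re-running the identical averaging over 45 streams × 32
electrodes with all phases drawn uniformly at random, 5000 times. With
1440 cells of mean 0.1 and standard deviation √(K−1)/K ≈ 0.095, the
fictive-participant distribution is approximately normal with standard
deviation 0.095/√1440 ≈ 0.0025, so its 95th percentile sits near
0.1 + 1.645 × 0.0025 ≈ 0.104 — the familiar ~0.105 threshold for this
design. Real participant values are compared with the fictive ones by a
one-sided Mann–Whitney U test (entrainment peaks are directional).

## Group statistics

ITPC values at 4, 8, 12 and 16 Hz (participant × condition rows) are
summarised by covariance PCA — the four variables share units and scale,
and centering-only PCA keeps the loadings interpretable as a weighted
average; the first component (ITPC1) is expected to weight all four
frequencies positively with 4 Hz heaviest, and the code warns if a fitted
solution violates that. Edge markers, which mix units (amplitude/s, ms,
unitless), are summarised by z-scored PCA over the retained set
(MD latency, MA latency, sharpness, Gini, plateau; the 80%-MA latency can
be added by argument). Component signs are fixed so each component's
largest-magnitude loading is positive.

Condition comparisons use one-way repeated-measures ANOVA with
participant as the blocking factor. The Greenhouse–Geisser ε is computed
from the double-centered covariance of the condition columns (the tests
pin it against the orthonormal-contrast eigenvalue formula) and applied
when Mauchly's test rejects sphericity at α = 0.05 — and always when
Mauchly's test cannot run for lack of participants, which is the
conservative choice. Both corrected and uncorrected p-values are
reported. Post-hoc comparisons are paired two-tailed t-tests with
Bonferroni correction over the family of all pairwise comparisons within
the tested partition. Condition clustering uses Lloyd's k-means, best of
100 seeded restarts. Marker–ITPC correlations are Pearson correlations
over condition means (n = 15), two-sided and uncorrected, as is usual for
post-hoc descriptive correlations of this kind.

The phoneme partitions are fixed by the design: stops {b d g k p t},
fricatives/sibilants {f v s z}, nasals/liquids {m n l r}; the five-group
refinement separates fricatives {f v} from sibilants {s z} and nasals
{m n} from liquids {l r}; voicing splits stops into {b d g} vs {k p t}
and fricatives/sibilants into {v z} vs {f s}. The vowel-only condition is
excluded from consonant partitions.

## The synthetic experiment

`build_schedule()` reproduces the experiment plan exactly: 450 target and
50 filler presentations in 5 blocks (each block: 10 repetitions of the 3
streams of 3 conditions plus 10 unique fillers), 2 s inter-stimulus
interval, vowel orders shared across conditions with no vowel repeated in
consecutive syllables, filler deviants in positions 11–20 drawn from a
different phoneme group. The three master vowel orders open with the
published first-five-syllable sequences; the remaining positions are
completed pseudo-randomly under the constraints, balanced at four
occurrences of each vowel per stream.

`synth_syllable()` builds caricature CV tokens: a class-dependent onset
(short silence + noise burst for stops, rising noise for fricatives and
sibilants, low murmur for nasals and liquids) followed by a two-formant
harmonic vowel with a raised-cosine attack. Class attack times are
ordered stops (20–25 ms) < nasals/liquids (55–65 ms) <
fricatives/sibilants (120–130 ms). Durations are drawn from a truncated
normal (mean 249.05 ms, sd 2.42 ms, range 241.6–255.3 ms), emulating the
scatter left by pitch-preserving duration modification; tokens are
RMS-normalised, emulating equal-SPL presentation.

`simulate_eeg()` instantiates the edge-triggered evoked account of
entrainment as a generative model: every syllable's MD latency marks an
edge; each edge triggers a damped 5 Hz oscillation (τ = 60 ms, 6 µV peak
— a P1–N1–P2-like slow wave whose spectrum straddles the 4 Hz bin),
jittered in time with a per-condition standard deviation; channels apply
a dipolar gain topography (signs alternate across the montage so the
evoked field survives average referencing, as real far-field potentials
do) and add independent 1/f noise of 8 µV RMS. Phase locking at 4 Hz is
then a monotonically decreasing function of the jitter. `make_study()`
couples the jitter to the *measured* MD latency of the synthesised audio
(sd = base + coupling × MD latency), which is exactly the relationship
the analysis pipeline is supposed to detect — making full
parameter-recovery runs possible: with positive coupling, the recovered
condition-level correlation between MD latency and 4 Hz ITPC is strongly
negative (r ≈ −0.9 at the default settings on a 5-participant,
5-condition, 10-trial design).

What the generator does *not* emulate: real phoneme acoustics (formant
transitions, aspiration detail), between-participant anatomy, artifacts
other than the modelled 1/f background, or oscillatory phase-reset
dynamics (the evoked-kernel mechanism was chosen because it ties ITPC
directly to edge-latency jitter; a phase-reset variant would be a
different generative hypothesis). Passing tests on these data therefore
validate the *pipeline's* correctness and sensitivity, not claims about
real cortex. In the same spirit, the synthetic classes reproduce the
latency ordering and the latency–coherence coupling, but not every sign
pattern a real stimulus set shows for the amplitude-dominated markers
(sharpness, MA); the honest carriers of attack information on these
tokens are MD and MD latency.

## Problem sizes and reproducibility

The package's own validation runs at desk scale, chosen once: the
surrogate calibration uses 10⁶ single-cell draws and 5000 fictive
participants at the full 45 × 32 structure; schedule invariants are
checked across 1000 seeds; the parameter-recovery study uses 5
participants × 5 conditions × 3 streams × 10 trials at 32 channels; the
ANOVA's type-I rate is estimated from 2000 null replicates of a 12 × 5
design. Every random stage accepts an explicit seed, seeded runs are
bit-reproducible, and pipeline artifacts carry a hash of the full
configuration so reruns can be verified byte for byte.

## Known limitations

* The gammatone filterbank is FIR-realised and causal; its small
  frequency-dependent group delay (≈14 ms at 80 Hz, less above) is not
  compensated, matching common cochleagram practice but shifting absolute
  latencies by a few milliseconds relative to an idealised zero-delay
  filterbank.
* Envelope decimation uses linear interpolation after anti-alias
  filtering; latency quantisation is one sample of the envelope grid
  (4 ms at 250 Hz).
* `read_brainvision()` covers the common multiplexed float32/int16 core
  format only.
* The Mann–Whitney comparison treats the 5000 fictive participants as a
  fixed reference sample; with 2 or more tied values the normal
  approximation with tie correction is used.
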