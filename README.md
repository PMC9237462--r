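# sylentrain

Analysis pipeline for frequency-tagged EEG experiments on **neural
entrainment to consonant–vowel syllable streams**, together with a
synthetic experiment generator that makes the whole chain testable
without recorded data.

The scientific question the package serves: when near-isochronous
20-syllable streams are played at a 4 Hz syllable rate, EEG phase-locks
to the rhythm — and the strength of that locking depends on the *acoustic
edges* of the syllables, i.e. on how rapidly their amplitude envelopes
rise at the syllable onset or consonant–vowel transition. The package is
aimed at auditory/speech neuroscientists who want to quantify that
relationship, and at methodologists who want a fully synthetic testbed
for entrainment pipelines.

## What it computes

**Envelopes and edge markers.** Syllable audio → 32-band log-spaced
gammatone (cochlear) filterbank spanning 80–8000 Hz → per-band Hilbert
envelopes → summed envelope (decimated to 250 Hz) → optional zero-phase
2–10 Hz Kaiser FIR smoothing. On the envelope, eight scalar *edge
markers*: sharpness (mean positive derivative), maximum amplitude (MA)
and its latency, latency to 80% of MA, plateau width, maximum derivative
(MD) and its latency, and the Gini index

    G = sum_ij |x_i − x_j| / (2 n sum_i x_i),

zero for a flat envelope, near one for a single prominent peak.

**Inter-trial phase coherence.** EEG → zero-phase 1–50 Hz bandpass →
average reference → (optional) ocular-component rejection by frontal
power share (> 12%) → 5 s epochs per stream presentation, first 500 ms
trimmed → Hann-tapered phase spectra. For K = 10 repetitions of a stream,
the ITPC at frequency f and electrode e is the **squared mean resultant**

    R(f, e, s) = (mean_k cos θ)² + (mean_k sin θ)²,

averaged over electrodes and streams to R(f, a) per participant and over
participants to R(f). Under random phases E[R] = 1/K = 0.1 exactly;
significance of spectral peaks is tested with a one-sided Mann–Whitney U
test against 5000 "fictive participants" built from uniform random phases
through the identical averaging.

**Group statistics.** Covariance PCA of ITPC at 4/8/12/16 Hz (→ ITPC1,
ITPC2), z-scored PCA of the edge markers, one-way repeated-measures ANOVA
with Greenhouse–Geisser correction, Bonferroni-corrected paired post-hoc
t-tests, k-means clustering of condition scores, and condition-level
Pearson correlations between markers and ITPC.

**Synthetic experiment.** A schedule builder (15 conditions × 3 streams ×
10 repetitions + 50 fillers in 5 blocks, all design constraints
enforced), a syllable synthesiser with class-controlled attack times, and
an EEG simulator in which every acoustic edge triggers a damped evoked
response jittered per condition, on 1/f noise — so phase locking is a
controlled, monotone function of edge-latency jitter.

## Worked example

```r
library(sylentrain)

# one synthetic /ta/ token through the envelope + marker chain
w <- synth_syllable(syllable_recipe("t", "a"), seed = 1)
round(waveform_markers(w), 3)
#>    sharpness           ma   ma_latency ma80_latency      plateau
#>        2.896        0.655       72.000       56.000      172.000
#>           md   md_latency         gini
#>       36.131       44.000        0.238

# a small synthetic study: 3 participants, 3 conditions, 10 trials/stream
st <- make_study(n_participants = 3, conditions = c("b", "m", "s"),
                 reps = 10, fillers = 0, blocks = 3,
                 cfg = eeg_sim_config(n_channels = 8), seed = 1)
df <- study_itpc_conditions(st)
f4 <- aggregate(f4 ~ condition, df, mean)   # condition-level 4 Hz ITPC
mk <- st$markers[match(f4$condition, st$markers$condition), ]
data.frame(condition = f4$condition, itpc4 = round(f4$f4, 3),
           md_latency_ms = round(mk$md_latency, 1))
#>  condition itpc4 md_latency_ms
#>          b 0.900          28.0
#>          m 0.163          72.0
#>          s 0.096         149.6
```

The pattern is the package's core phenomenon: /b/ syllables (fast attack,
MD latency 28 ms) entrain strongly (4 Hz ITPC 0.90), nasals are
intermediate, and sibilants (MD latency ~150 ms, hence large neural
jitter under the coupled generative model) sit at the random-phase floor
of ~0.1. Testing the 4 Hz peak against the surrogate null:

```r
null <- surrogate_null(n_streams = 9, n_electrodes = 8, K = 10,
                       n_fictive = 2000, seed = 2)
avg <- average_hierarchy(st$itpc)
r4 <- harmonic_extract(avg$R_fa, avg$freqs, harmonics = 4)
peak_significance(r4[1, ], null)
#> 4 Hz peak: U = 6000, one-sided p = 0.00137
```

`run_pipeline(run_config(...))` chains everything — synthesis,
preprocessing, ITPC, markers, statistics — and writes tidy CSVs and a
JSON report stamped with a hash of the configuration. A thin command-line
wrapper lives at `inst/cli/sylentrain.R`
(`envelope`, `edge-markers`, `synth`, `run` subcommands).

## Further reading

The methods vignette (`vignettes/syllable-entrainment.Rmd`) documents the
model and every numerical choice: filter designs and rates, marker
conventions and tie-breaks, the surrogate-null construction, the
statistics, what the synthetic generator does and does not emulate, and
known limitations.
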