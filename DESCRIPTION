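Package: sylentrain
Title: Neural Entrainment to Syllable Streams: Envelopes, Edge Markers and
    Inter-Trial Phase Coherence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for frequency-tagged EEG experiments in which
    near-isochronous streams of consonant-vowel syllables are presented at a
    4 Hz syllable rate. Computes cochlear-filterbank amplitude envelopes of
    syllable audio and scalar "edge markers" of envelope shape (sharpness,
    maximum amplitude and derivative with their latencies, plateau width,
    Gini index); preprocesses multichannel EEG and quantifies entrainment as
    the squared mean resultant of Fourier phases across trials (inter-trial
    phase coherence), with surrogate-phase null distributions for peak
    significance; and provides the group-level statistics linking edge
    markers to entrainment (PCA summaries, repeated-measures ANOVA with
    Greenhouse-Geisser correction, Bonferroni post-hoc tests, k-means
    condition clustering, condition-level correlations). A synthetic-data
    module generates the full experiment - stimulus schedules, syllable
    audio with controllable attack times, and EEG with edge-triggered evoked
    responses plus 1/f noise - so every stage is testable end to end without
    recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
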