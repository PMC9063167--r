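Package: megfc
Title: MEG Functional Connectivity of Familiar and Unfamiliar Music Listening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for source-space MEG functional connectivity
    analysis of a music-familiarity paradigm in autistic and typically
    developing children. Implements the experimental paradigm (stimulus
    matching, run structure), a coupled-oscillator synthetic-data generator
    with planted phase- and envelope-coupled edges and zero-lag leakage
    mixing, preprocessing (epoching, head-motion rejection, ICA artifact
    removal, two-pass FIR filterbank), LCMV beamforming with closest-method
    leakage orthogonalization, amplitude envelope correlation (AEC) and
    weighted phase lag index (wPLI) connectivity with resting-state
    baselining, Network-Based Statistics permutation testing (within-group,
    between-group and 2x2 interaction contrasts with Bonferroni correction),
    and network-strength/behavior correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    igraph,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
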