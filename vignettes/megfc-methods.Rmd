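---
title: "Methods: source-space MEG connectivity of music familiarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: source-space MEG connectivity of music familiarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`megfc` implements a complete source-space MEG functional-connectivity
analysis for a music-familiarity paradigm in autistic (ASD) and typically
developing (TD) children, together with a synthetic cohort generator that
makes every stage verifiable without access to raw recordings. This
vignette explains the models, the tunable parameters, and the design
choices made where the methodology was genuinely open.

## The experimental paradigm

Each participant hears 40 music excerpts of 30 s — 8 familiar liked, 8
familiar disliked and 24 unfamiliar — in 4 task runs of 10 excerpts, with
a 3 min resting-state run before and after. Familiar excerpts are matched
to unfamiliar candidates on five features: tempo class, mode, genre,
presence of lyrics, and lyric language. Tempo is binned as slow (40–72
bpm), moderate (72–120 bpm) and fast (120–208 bpm); because the printed
bin boundaries overlap at 72 and 120, `classify_tempo()` uses half-open
`[lo, hi)` bins with the top bin closed at 208, so each boundary belongs
to the upper class. This makes classification total and deterministic.
Matching is greedy first-fit in input order — the original matching
algorithm is not documented, and greedy matching is reproducible and
reports unmatched songs instead of failing.

Condition labels for analysis come from the in-scanner familiarity
response, not the pre-selected stimulus list. How often those disagree is
not documented, so `build_paradigm()` exposes a `response_flip_rate`
parameter, default 0; liked/disliked are collapsed into familiar vs
unfamiliar throughout.

## The synthetic cohort generator

`simulate_subject_timeseries()` produces trials × parcels × samples
arrays in which every parcel carries one band-limited oscillation per
configured band (theta 4–7, alpha 8–14, beta 15–29, gamma1 30–55, gamma2
65–80 Hz by default) plus `1/f` background noise. Three coupling
mechanisms are planted with known ground truth:

* **Phase coupling (wPLI targets).** A planted pair shares a common
  narrowband signal; the second node receives a copy delayed by a quarter
  period of the band's center frequency, mixed with weight equal to the
  effect size. The quarter-period lag guarantees a non-zero imaginary
  cross-spectrum — exactly the quantity wPLI detects. Edges that share a
  node are chained from the already-assigned node so an entire planted
  subnetwork remains coupled.
* **Envelope coupling (AEC targets).** Each involved node is a
  constant-envelope carrier — a tone at the band center with slow random
  frequency modulation (deviation ≤ 0.75 Hz, inside the band) — whose
  amplitude follows a slow (< 1 Hz) Gaussian modulator. Modulators are
  drawn jointly with a target correlation matrix factored by Cholesky, so
  the modulator correlation equals the planted effect size even when
  edges share nodes. Frequency-modulated carriers were chosen over
  band-limited noise carriers deliberately: independent FM carriers are
  instantaneously uncorrelated, so planted envelope couplings are *not*
  removed by leakage orthogonalization, while noise carriers would add
  Rayleigh envelope fluctuations that dilute the planted correlation.
  Modulators are clipped at ±2 SD and scaled by `envelope_depth`
  (default 0.4); depths ≥ 0.5 are rejected because they could drive the
  envelope non-positive.
* **Leakage.** Zero-lag field spread is emulated by post-multiplying the
  parcel signals with a row-normalized near-identity mixing matrix
  (identity plus a symmetric random perturbation of configurable
  strength). This is what wPLI must ignore and uncorrected AEC must not.

Per-trial head motion is log-normal (median 5 mm, log-SD 0.5 by default)
so that the 10 mm rejection rule is actually exercised: roughly 8% of
trials exceed threshold at the defaults. Sensor data are obtained by a
full-column-rank linear forward model (orthonormalized random leadfield,
one column per parcel — scalar sources, since dipole orientation
estimation is out of scope), ECG-like artifact components with known
loadings, and white sensor noise.

What the generator does *not* emulate: realistic forward physics (no
head model), spatially correlated cortical noise, non-stationary
artifacts, or inter-subject anatomical variability. Passing tests
therefore demonstrate the correctness and calibration of the analysis
machinery, not field-readiness for any particular scanner.

## Preprocessing

Trials are epoched into non-overlapping 10 s chunks (trailing remainders
discarded) so that excess motion rejects an epoch, not a whole trial.
Motion rejection is strict (`> 10 mm` dropped; a trial at exactly 10 mm
is kept, following the stated rule). Subjects need at least 3 trials per
condition to stay in the analysis.

Artifact removal automates the usual visual ICA inspection: a FastICA
decomposition (symmetric decorrelation, `tanh` contrast, implemented in
the package) is fitted per subject on concatenated epochs, capped at 60
components; components whose absolute correlation with any artifact
reference channel exceeds `r = 0.4` are zeroed and the data
reconstructed. The correlation criterion replaces visual inspection
because the latter is not reproducible; 0.4 is conservative enough that
clean data pass through nearly unchanged (per-channel correlation with
the input > 0.99 in tests).

Filtering uses two-pass (forward–backward, zero net phase) Hamming-window
FIR filters: a 60 Hz band-stop notch (±2 Hz) applied first, then one
band-pass per analysis band. The FIR order is 3 cycles of the band's low
edge, floored at one second of taps. The floor matters: a bare
3-cycles rule would give a 28-tap filter for gamma2 whose ~70 Hz
transition band destroys spectral concentration; with the floor, ≥ 95%
of white-noise output power falls within 1 Hz of every band (measured
≥ 98.9%) and the notch attenuates a 60 Hz tone by ~41 dB. The first and
last second of every epoch are excluded from connectivity estimation to
avoid Hilbert and filter edge effects.

## Source reconstruction and leakage correction

The LCMV beamformer computes, per parcel `i` with leadfield column `l_i`
and regularized covariance `C`, the weights
`w_i = (l_i' C^{-1} l_i)^{-1} l_i' C^{-1}`, which have unit gain on their
own parcel while minimizing variance from elsewhere. Covariance is
estimated over all of a subject's task epochs and regularized by 5% of
the mean sensor variance — both conventional defaults, chosen because the
original processing details are not documented. The pipeline also accepts
parcel-level input directly; the sensor route exists to exercise the
forward/inverse machinery on synthetic data.

Leakage correction uses the *closest* orthogonalization: the set of
mutually uncorrelated time series nearest the input in summed squared
distance, found by alternating an orthogonal-Procrustes rotation with
per-signal rescaling (tolerance 1e-8, max 100 iterations; signals are
centered first, since zero correlation is orthogonality of centered
vectors). It is applied per subject and band **before AEC only**; wPLI is
computed on uncorrected signals because its construction already ignores
zero-lag coupling. A two-signal brute-force grid search over rotation
angle and scales confirms the alternation reaches the global optimum.

## Connectivity

Within each 10 s epoch the Hilbert transform (FFT implementation) gives
envelope and phase per parcel. wPLI between two analytic signals is
`|Σ_t Im S(t)| / Σ_t |Im S(t)|` with `S(t) = z_A(t) conj(z_B(t))`; the
debiased variant is deliberately not used. AEC is the plain Pearson
correlation of the two envelopes (no log transform — the definition used
is plain correlation). Both metrics are computed within trials: per
epoch, averaged over the trial's epochs, then averaged over trials per
condition. Identical zero-lag signals make the wPLI denominator vanish;
that degenerate case returns 0 with a flag rather than NaN.

Whole-brain analysis uses all 92 parcels (90 AAL regions plus the two
accumbens nuclei); ROI analysis keeps the 13 seed columns of the same
matrix, so shared entries agree exactly. The trial-averaged matrix is
baselined by subtracting the mean resting-state matrix; rest epochs from
both rest runs are pooled, which is numerically identical to averaging
30 s triplet means when counts divide evenly. Unequal trial counts
between conditions are accepted as-is (no subsampling), mirroring the
observed imbalance between familiar and unfamiliar responses.

## Network-Based Statistics

Edgewise statistics: two-sample pooled-variance t (between groups),
paired t on familiar − unfamiliar (within group), or — for the 2×2 mixed
design — a two-sample t across groups on per-subject condition
differences, reported as `F = t²`. Edges above the primary threshold
(defaults t = 3.0, with 2.75/3.0/3.5 available for the amplitude metric,
and F = 7 for the interaction) form an undirected graph whose connected
components are scored by edge count; node counts are reported alongside.
The null distribution is the maximal component size over 5000 (default)
permutations — group-label permutations for between-group and
interaction contrasts, within-subject sign flips for the paired
contrast — and each observed component gets
`p_fwer = (1 + #{null ≥ observed}) / (1 + n_permutations)`, which cannot
be zero. When fewer distinct relabelings exist than requested, all of
them are enumerated exactly with a warning. One-sided contrasts run
separately per direction. Bonferroni correction is applied within metric
with family sizes 4 (between: 2 conditions × 2 directions → p < 0.0125)
and 2 (within: 2 directions → p < 0.025); the published thresholds pin
down only these family sizes, and this composition reproduces them.

Two scale effects discovered during calibration are worth recording. At
92 nodes and n = 24/24, a component-forming threshold of F = 7 admits
roughly 1% of null edges — about 46 per permutation — which puts the
suprathreshold graph near its percolation threshold and makes whole-brain
interaction components unstable. The seed-based (ROI) interaction, where
only seed-involving pairs carry statistics, stays far below percolation
and is stable; the demonstration analyses therefore run the interaction
on ROI maps, consistent with the interaction being a regions-of-interest
analysis. Second, planted demonstration networks are cliques rather than
trees: a tree splits into fragments whenever one edge fails its
threshold, so clique topologies make edge recall meaningful.

## Brain–behavior analysis

Network strength is the sum of a subject's baselined edge weights over a
significant component's edges, each edge counted once. Strengths are
correlated with behavioral scores (SCQ, RBS-R sameness subscale, ADOS
severity within the ASD group) by Pearson correlation with two-sided
t-transform p-values, uncorrected, with pairwise deletion of missing
scores. Cohort-table group tests are recomputed from printed summaries by
a pooled-variance two-sample t (`df = n1 + n2 − 2`, matching the printed
df = 46); Welch's correction is deliberately not used for that reason.

## Problem sizes and numerical choices

The test-suite and demonstration analyses run at desk scale, chosen so
each property is measured where it is statistically decidable rather
than at cohort dimensions: metric oracles use 4–6 parcels, one band,
150–200 Hz sampling and 30–100 trials; NBS calibration and recovery use
the full 92-node graph with n = 20–24 per group and 500 permutations
(100 replicates for the null false-positive rate); end-to-end pipeline
runs use 2 groups × 2–6 subjects, 10 music trials per subject and 50–200
permutations. Determinism is a contract: identical configuration and
seed give byte-identical result bundles, and every permutation stream is
seeded.

Degenerate inputs are handled explicitly: all-zero signals flag their
phase as undefined; zero-variance envelopes are excluded from trial
averages with a flag; zero within-cell variance sets the edge statistic
to 0; singular covariance without regularization, rank-deficient
leadfields, out-of-range tempi and malformed node tables raise
descriptive errors.

## Known limitations

The node-table fixture uses AAL-convention names with approximate,
synthetic centroid coordinates (the atlas itself is not redistributed),
and a seed set assembled from the regions named in the study text — both
are user-replaceable. The generator's linear mixing is a stand-in for
real field spread; beamformer performance on real data depends on head
modeling that is out of scope. The published group-level findings depend
on the study's raw recordings, which are not deposited, so they are not
reproducible here; what this package establishes is that the analysis
machinery is correct, calibrated and recovers planted effects of the
published geometry.
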