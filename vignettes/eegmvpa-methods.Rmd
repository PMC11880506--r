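---
title: "Cross-participant EEG decoding and RSA: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-participant EEG decoding and RSA: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# What the package computes

`eegmvpa` implements a complete time-resolved multivariate analysis of
multi-participant EEG recorded while observers judged facial expressions of a
32-image stimulus set (8 face identities, 4 per sex, each shown with happy,
angry, sad and neutral expressions). The analytic core is *cross-participant*
decoding: classifiers are trained on all participants but one and tested on
the held-out participant, so any accuracy above chance demonstrates neural
codes whose format is shared across observers, not merely within them.

The pipeline stages are:

1. **Design** — the two-alternative forced-choice session schedule (12
   presentations per image, each veridical expression paired with each of the
   three other expressions as foil 4 times, response keys balanced;
   error trials re-inserted later in the sequence until every image has 12
   correct trials) and behavioral summaries (confusion matrix from first
   presentations only, per-expression accuracies, paired Wilcoxon signed-rank
   tests on median response times, uncorrected).
2. **Synthesis** — a generative model of multi-participant epoched EEG with
   planted, ground-truth condition effects (below).
3. **Preprocessing** — zero-phase 0.1–40 Hz band-pass, epoching on the
   half-open grid [−200, 1200) ms at 200 Hz (280 samples), baseline
   correction to the 200 ms before stimulus onset, integer-decimation
   downsampling with anti-alias filtering, and averaging of random 3-trial
   same-image bins into pseudo-trials.
4. **Decoding** — leave-one-participant-out linear discriminant
   classification of identity (8-way, chance 0.125), sex (0.5), expression
   (4-way, 0.25) and expression pairs (0.5); bidirectional
   cross-classification between conditions with direction averaging;
   region-of-interest and spatio-temporal searchlight variants.
5. **RSA** — time-resolved 32 × 32 neural representational dissimilarity
   matrices from cross-participant pairwise decoding, compared with binary
   attribute models, image cross-correlation models and face-embedding
   distance models by (partial) Spearman correlation.
6. **Inference** — 35 ms moving-average smoothing, one-sample sign-flip
   cluster permutation tests against chance, interval-null Bayes factor time
   courses, per-timepoint Cohen's *d*, and onset/first-peak extraction.

# Condition generalization in the decoding schemes

Decoding never tests on a condition seen in training. The identity scheme
trains on three expressions and tests on the held-out fourth. The sex,
emotion and expression-pair schemes train on six identities — three per sex —
and test on the held-out identity. Because removing the held-out identity
leaves its own sex with exactly three members, the sixth training identity is
obtained by dropping one identity of the *opposite* sex; the dropped identity
rotates over all four candidates and the four rotation accuracies are
averaged. (Dropping a same-sex identity instead would leave training at a 2/4
sex imbalance, which measurably biases the constant-label test folds below
chance — with an imbalanced 1:2 training set and pure-noise inputs the
held-out-class accuracy falls to roughly 0.42.)

The classifier is a linear discriminant with a pooled within-class
covariance shrunk toward a scaled identity by the Ledoit–Wolf intensity
estimated from the class-centered training data. Shrinkage keeps the
discriminant well-conditioned at searchlight scale, where the channel count
approaches the per-class trial count; a plain pooled-covariance solver is
available via `classifier = list(shrinkage = "none")`. Priors are equal, as
every scheme is balanced by construction. Features at each timepoint are the
raw channel amplitudes of the pseudo-trials; no multi-sample windows are
used.

# The synthetic cohort generator

`generate_cohort()` is a first-class, tested module, not a fixture. Its
defaults are the study conditions the package emulates: 24 participants, 64
channels (standard 10-20-derived montage), 200 Hz, epochs −200..1200 ms, 12
repetitions of each of the 32 stimuli. Each trial is

> signal = Σ over effects [ amplitude × level-pattern(channel) ×
> topography(channel) × envelope(time) ] + noise,

where each effect targets one attribute (sex, identity, expression, or
image), each level of that attribute receives a random unit-RMS channel
pattern, and the envelope is a plateau over [onset, onset + duration) with
20 ms raised-cosine ramps — a stylized evoked component with a sharp,
well-defined onset (the ramp length is configurable). Patterns marked
`shared` are drawn once and reused by every participant; this is the
generative counterpart of the shared-code premise that cross-participant
decoding tests. Setting `shared = FALSE` re-draws patterns per participant
and is expected to defeat leave-one-participant-out decoding — a failure
mode the test suite demonstrates.

Noise is Gaussian, independent across trials and channels, temporally
smoothed by a Gaussian kernel (sd 20 ms by default) and re-scaled to keep its
marginal sd, mimicking the temporal autocorrelation of EEG background
activity. We deliberately do not model 1/f spectra, volume conduction
(leadfields), eye blinks or muscle artifacts: the generator's purpose is
calibration and parameter recovery, and for those goals the simple noise
model keeps every planted quantity analytically interpretable. Consequences:
passing tests demonstrate that the *pipeline* recovers what was planted under
EEG-like autocorrelation, not that it is robust to real-world artifacts,
channel covariance structure, or inter-individual latency jitter.

Synthetic stimulus images (Gaussian identity/sex/expression templates plus
pixel noise, weighted) and synthetic 128-dimensional face embeddings
(per-identity Gaussian clusters) stand in for the photographs and the face
network descriptors; both are labelled synthetic and exist so the
image-property RDMs have controllable attribute content.

# Statistical inference

**Smoothing.** Participant-level accuracy (or Fisher-z) series are smoothed
by a centered 35 ms moving average — 7 samples at 200 Hz — before testing;
edges use shrinking windows. Smoothing can be skipped by not calling
`moving_average()`, and whether it was applied is visible in the pipeline
provenance.

**Cluster permutation.** Per timepoint a one-sample t statistic of
(value − chance) is computed across participants; points with |t| above the
two-tailed p = 0.05 quantile at n−1 df form clusters by temporal contiguity
(plus channel adjacency for searchlight maps); cluster mass is the summed t.
The null distribution flips the sign of each participant's whole deviation
series (10,000 draws by default); positive and negative clusters are each
compared with the permutation distribution of the maximum absolute mass.
When the sign-flip space is small (2^n ≤ permutations) it is enumerated
exhaustively. The cluster-forming threshold is a design choice — the test
family fixes only the cluster statistic — and is exposed as
`cluster_threshold_p`.

**Interval-null Bayes factors.** Per timepoint the one-sample t is converted
into a Bayes factor comparing standardized effects outside the
practically-null interval |δ| ≤ 0.5 against effects inside it, both under a
Cauchy(0, 0.707) prior truncated to the respective region. The marginal
likelihood of the observed t under each truncated prior is computed by
adaptive quadrature of the noncentral-t density, with the integration split
around the likelihood peak so semi-infinite segments never straddle a narrow
mode; a genuine integration failure raises an error rather than falling back
silently. BF > 10 is the strong-evidence threshold. The point-null (JZS)
Bayes factor is exposed alongside (`bf_point_t()`) for comparison; the
interval form is the default because a non-directional null *interval* is
what the evidence thresholding is applied to. A dense inverse-CDF quadrature
oracle in the test suite pins the implementation to 3+ significant digits.

**Onsets and peaks.** The onset of an effect is the first timepoint of the
first run of at least `min_run` suprathreshold Bayes factors (default 1; the
debouncing length is configurable because no canonical rule exists), and the
peak is the first strict local maximum of the Bayes factor within that run
(a flat run falls back to the first occurrence of its maximum). A series
with no suprathreshold point yields an explicit NA onset, not an error.

# Numerical and degenerate-case choices

* Epochs use the half-open sample grid [tmin, tmax): 1400 ms at 200 Hz is
  exactly 280 samples; a closed grid would give 281 and shift every
  downstream shape.
* Filtering is forward–backward (zero-phase) Butterworth, high-pass order 2
  and low-pass order 4; input is demeaned first so constant offsets cannot
  excite the long high-pass edge transient.
* Incomplete pseudo-trial bins are dropped rather than averaged short,
  keeping pseudo-trial noise variance homogeneous; an image with fewer
  trials than the bin size is dropped with a warning.
* Spearman ties get average ranks; partial rank correlations are computed by
  residualizing the covariate ranks out of both vectors (equivalent to the
  recursive partial-correlation formula on ranks, which the tests verify).
* The maximum cross-correlation image metric z-scores both images, then
  takes the best Pearson correlation of the overlapping region over all
  integer 2-D translations with at least half the pixels overlapping
  (`min_overlap_frac = 0.5`; tiny overlaps produce degenerate correlations).
  Dissimilarity is 1 − max correlation. Because the phrase "Euclidean
  distance of maximum cross-correlation" admits a second reading, a
  Euclidean-distance-at-the-best-shift variant is provided behind
  `metric = "euclidean_at_best_shift"`. The FFT implementation equals the
  exhaustive shift loop to 1e−10.
* A zero-variance effect-size point is flagged ±Inf rather than raised; a
  zero-variance t in the Bayes series maps to an infinite Bayes factor.
* Neural RDM cells are leave-one-participant-out pairwise decoding
  accuracies; the diagonal is undefined and stored as NA. Fold-resolved
  matrices (one per held-out participant) are the default since group
  statistics consume them; cell-averaged matrices are available with
  `fold_resolved = FALSE`.
* Searchlight adjacency is built by distance thresholding on the nominal
  2-D layout grid (default radius 1.5 grid units, i.e. first-order neighbors
  including diagonals). The six scalp regions split the montage along the
  midline (midline channels belong to both hemispheres' region) and into
  anterior / central / posterior bands.

# Problem sizes used in tests and calibration

The test suite and the calibration script run the full pipeline at reduced,
desk-scale sizes chosen once: noise-only calibration uses 6 participants ×
16 channels × 50 timepoints with 12 repetitions (the reduced preset of
`run_config(reduced = TRUE)`); family-wise-error calibration uses 500 null
simulations of 8 participants × 50 timepoints with the sign-flip space
enumerated exhaustively; parameter recovery plants sex / identity /
expression effects at 100 / 115 / 160 ms (200 ms duration, amplitude 2, 8
participants, 16 channels) and requires each recovered onset within one
35 ms smoothing window of its planted value and in the planted order. At
these scales a full run completes in minutes on a single core; the same code
paths scale to the full 24 × 64 × 280 geometry unchanged.

Because leave-one-participant-out folds share training data, participant
accuracies are positively correlated; the Monte-Carlo standard error used in
the calibration checks therefore combines the participant-level and
fold-level variance components rather than treating all cells as
independent. The same sharing means one-sample t statistics on small cohorts
can drift at baseline; this is a property of the fold structure, shrinks as
the training set grows, and is one reason the reduced recovery cohort uses
8 participants and 12 repetitions.

# Known limitations

* No artifact rejection, re-referencing or ICA: the preprocessing contract
  is filter → epoch → baseline → downsample → bin, matching the analysis
  the package reproduces.
* Temporal generalization matrices, nonlinear classifiers, cross-validated
  RDM distances (crossnobis), noise ceilings and reweighted RSA are out of
  scope.
* The generator's channel "topographies" are weights on a nominal grid, not
  physically projected dipole fields; searchlight localization tests should
  be read accordingly.
* Bayes factors assume the t statistic's sampling model; with very small
  cohorts (n < 5) both the permutation grid and the t model are coarse, and
  the package warns accordingly.
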