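---
title: "Decoding emotion from prefrontal EEG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding emotion from prefrontal EEG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegaffect)
```

## The problem and the estimators

The package analyses a longitudinal two-group emotion-identification study:
children view emotional face stimuli (happy, sad, angry, fear) in three
conditions per weekly session; the experimental group's middle condition
pairs each face with emotion-congruent music. Two outcome families are
analysed: verbal identification accuracy, and the affective content of
prefrontal EEG recorded during stimulus presentation.

Affect is summarized by two window-wise scalars computed from the band
powers of AF3, AF4, F3 and F4:

- **arousal** — the beta/alpha power ratio
  `(βF3 + βF4 + βAF3 + βAF4) / (αF3 + αF4 + αAF3 + αAF4)`, a dimensionless
  activation index (beta rises and alpha desynchronizes with activation);
- **valence** — frontal alpha asymmetry `αF4 − αF3` in µV², on the
  approach/withdrawal account of frontal asymmetry: relatively more
  right-hemisphere alpha (less right activation) reads as positive valence.

The arousal ratio is invariant to any common gain applied to all eight band
powers; valence scales linearly with gain, which is one reason features are
z-scored per participant-session before modelling (below).

## Signal processing choices

*Bands and filter.* Alpha is 8–12 Hz, beta 12–28 Hz. Filtering is an
order-4 Butterworth band-pass applied forward–backward (`filtfilt`), so the
effective response is the squared magnitude and the phase is zero —
stimulus-locked windows keep their alignment. Measured on a 128 Hz 10 Hz
sinusoid, passband gain is 0.9999; a 20 Hz tone leaks less than 0.01% RMS
through the alpha filter.

*"Instantaneous" values.* Window-based: 1.0 s windows stepped by 0.25 s.
One second covers ≥ 8 alpha cycles (stable power estimates) while 4 values/s
still tracks within-stimulus dynamics. Band power is the time-domain mean of
squared band-filtered samples per window; a property test confirms it agrees
with periodogram integration over the band within 10% on stationary inputs
(Parseval consistency). The estimator and window length are package choices
— reasonable alternatives (Welch spectra, longer windows) would shift
absolute powers slightly but cancel in the arousal ratio and in z-scored
features.

*Edges.* Windows overlapping the first or last second of a recording are
dropped (filter warm-up). A consequence worth knowing: windows whose 1 s
support straddles a stimulus onset or offset include some signal-free
samples, which biases per-event mean valence a few percent toward zero on
synthetic data; the bias is well inside the 5–10% recovery tolerances used
throughout.

*Artifact handling.* In place of manual visual inspection the package uses a
reproducible automated surrogate: a window is rejected if any frontal
channel exceeds ±100 µV raw amplitude inside it, or if its total frontal
(alpha + beta) power has a z-score above 5 across the recording. Both
thresholds are standard EEG practice and are exposed in
`pipeline_config()`; `Inf` disables a rule. Windows with a zero alpha
denominator are dropped (not clamped) so the arousal ratio stays
interpretable; the count is reported via a warning.

## Normalization

The protocol compares conditions within sessions and sessions within
participants, and consumer-headset recordings drift in gain and impedance
between sessions. The default scope therefore z-scores arousal and valence
independently **per participant-session** (a `participant_study` scope is
available). Normalization happens after epoching; because z-scoring is an
affine map and epoching is row selection, applying it before or after
epoching differs only through the windows excluded by the mask, and the
per-session scope keeps that difference negligible. The chosen order keeps
raw, physically interpretable features available up to the last step.

## The decoder

The four-class classifier is a feed-forward network with the fixed topology
2 (arousal, valence) → 3 → 3 → 4, tanh hidden activations, and a softmax
output trained on cross-entropy. Training details are package choices made
once: full-batch gradient descent with momentum 0.9 and a bold-driver step
adaptation, at most 2,000 iterations, relative loss tolerance 1e-6, weights
initialized uniformly in ±0.5 from the fold seed. This is the smallest
standard training recipe compatible with the stated topology; it reaches
100% on 10σ-separated Gaussian clusters and ~25% on label-permuted data.

Evaluation is stratified k-fold cross-validation (default k = 10): folds are
disjoint, exhaustive, and preserve class proportions to within one instance
per class (a property test covers all seeds tried). One instance is one
feature window, mirroring the "instantaneous values train the model" design;
`instance = "epoch_mean"` aggregates per stimulus and `fold_unit = "epoch"`
keeps all windows of one stimulus in the same fold for leakage-free folding
(off by default to mirror the instantaneous-instance design). Models are fit
per participant in `run_pipeline()`; pooled fits are a one-line change.

The linear-kernel SVM (`e1071::svm`, cost 1) probes linear separability. On
a four-class layout where every class occupies two antipodal clusters (a
four-class XOR), the best linear rule cannot exceed ~50–60% while the
network solves it — the qualitative signature of non-linearly distributed
classes in the arousal–valence plane.

Two cross-validated models are compared with an exact paired sign-flip
permutation test over per-fold accuracy differences (1,024 flips at 10
folds; Monte-Carlo beyond 20 folds). Its empirical false-positive rate
matches its level in simulation.

## Centroids

Per emotion, the centroid is the mean z-scored (valence, arousal) of all
retained windows of the requested condition/session across participants
(EG by default; a flag pools both groups). "Normalized averages" is realized
as a joint max-abs rescale of the four centroids into the unit square: it
preserves the geometry and the rank order on both axes, and matches plotting
conventions for the Thayer plane. Agreement scoring compares coordinate
signs against the expected layout — happy (+v, +a), sad (−v, −a), angry and
fear (−v, +a) — with exactly-on-axis centroids flagged indeterminate rather
than counted either way.

## Verbal-response statistics

Counts of correct answers per participant-session-condition cell (integers
out of 12) are the analysis unit — fractions would only rescale, and
integers keep signed ranks exact. The Shapiro–Wilk gate routes at p = 0.05
between the parametric and non-parametric branches, mirroring the study's
procedure.

The within-session NM1 vs NM3 comparison is a Wilcoxon matched-pairs
signed-rank test with Wilcoxon's zero-handling (zeros dropped, effective n
reported). The p-value uses the exact conditional null distribution of the
positive-rank sum given the observed mid-ranks, computed by polynomial
convolution over doubled ranks — exact under ties, where the classical
tabulated distribution does not apply; tests verify it against full 2^n sign
enumeration up to n = 12 and against `wilcox.test` in the tie-free case.

The across-session comparison (first session's NM1 vs the post-study NM1
assessment, per group) uses the paired t-test: with exactly two repeated
measures the repeated-measures ANOVA is the paired t-test (F = t²), an
identity asserted against `aov` in the tests. Mean, SD and SE of the paired
differences are all reported, since summary tables in this literature are
ambiguous about which dispersion they print.

## The synthetic-data module

The generator exists so that every downstream stage has ground truth. It
emulates:

- the session protocol — per condition, 12 stimuli (3 per emotion, 6 male +
  6 female faces) in seeded random order, 10 s each with 5 s transitions;
  EG sessions run NM1/M/NM3, CG sessions NM1/NM2/NM3 (the EG's third
  condition is canonically named NM3 here); 4 weekly sessions plus a
  follow-up NM1-only assessment modelled as session 5; group sizes EG 14,
  CG 11 with EEG attached to 6 per group by default;
- the EEG — 1/f-spectrum background (default RMS 10 µV, a typical resting
  broadband level) on all 14 channels; during each stimulus,
  amplitude-stable 10 Hz and 20 Hz oscillators with slow random phase drift
  on the four frontal channels. Constant envelopes make window power exactly
  A²/2, so planted targets are recovered analytically. The target inversion
  is under-determined; it is made unique by fixing AF-channel alpha to the
  mean of F3/F4 alpha, equal beta on all four channels, and a total F3+F4
  alpha of 4 µV² as the scale anchor (which bounds plantable |valence| below
  4 µV²). Default planted targets place the emotions in their conventional
  Thayer quadrants: arousal 2.0/0.5/2.5/2.2 and valence +1.0/−0.5/−1.0/−0.8
  µV² for happy/sad/angry/fear;
- verbal responses — Bernoulli correctness at a baseline probability
  (default 0.5), plus a per-session increment (default 0.1) for EG only;
  errors are uniform over the three remaining emotions;
- optional gross artifacts — raised-cosine excursions of 0.25–1 s at
  Poisson times, with ground-truth intervals retained for detector checks.

What it deliberately does **not** model: ERP morphology, ocular/EMG
physiology, volume conduction, electrode re-referencing (signals are treated
as already referenced), emotion-incongruent stimulus pairings, or any image
or audio content. Passing tests on this generator therefore demonstrate that
the pipeline is correct and sensitive under its own assumptions — not that
real paediatric EEG carries affect this cleanly; real-data effect sizes are
far smaller than the planted ones.

## Problem sizes and determinism

Every stochastic step takes an explicit integer seed and is reproducible
bit-for-bit; sub-seeds are derived deterministically from a master seed in
`run_pipeline()`, and each serialized result embeds the configuration hash
and seed. The test suite exercises: schedule invariants over 1,000 seeds;
full-chain parameter recovery at 10% background noise over seeds 1–5 (with
centroid quadrant agreement over 10 seeds); chance-level convergence at
1,000 and 4,000 instances; and 500-replicate null simulations for both
response tests' type-I error (both land within ±0.02 of the 0.05 level).
Single-condition (follow-up) sessions are used as the unit of synthesis in
most tests — the cheapest schedule that still exercises every stage.

## Known limitations

- The valence estimator is the raw alpha difference, not a log-ratio; very
  different overall alpha levels between participants are handled by
  z-scoring, not by the estimator itself.
- The fixed 2–3–3–4 topology has limited capacity by design; it is the
  study's model, not a recommendation for new work.
- The exact Wilcoxon enumeration is conditional on observed ranks; its
  attainable significance levels are discrete, so small-n rejection rates
  sit slightly below nominal alpha.
- EDF export quantizes to 16 bits of the per-channel physical range; CSV is
  the lossless interchange format.
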