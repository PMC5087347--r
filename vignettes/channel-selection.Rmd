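---
title: "ReliefF-based EEG channel selection: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ReliefF-based EEG channel selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Emotion recognition from scalp EEG typically records 32 or more sensor
channels, but many channels are noisy or redundant: they add computational
cost, hurt wearability, and can even degrade classification. This package
implements a family of channel-selection strategies built on ReliefF
feature weighting, for the four-quadrant emotion classification task
(joy, fear, sadness, relaxation) defined by thresholding valence and
arousal ratings at 5 on a 1–9 scale (the threshold is inclusive on the
`>= 5` side).

The processing chain is:

1. **Features.** Each 60-s trial is cut into fifteen non-overlapping 4-s
   segments. Per segment and channel, the signal is band-pass filtered to
   the four canonical bands (theta 4–8, alpha 8–13, beta 13–30, gamma
   30–45 Hz) and the band power is computed as the mean squared magnitude
   over all N bins of the N-point FFT of the filtered segment
   (`N = 512` at 128 Hz). With 32 channels this yields 128 features per
   sample and 600 samples per subject. Features are z-scored.
2. **Feature weighting.** Multi-class ReliefF scores each feature by how
   well it separates a sample from its `k = 10` nearest other-class
   neighbours (misses, prior-weighted) relative to its `k` nearest
   same-class neighbours (hits), iterating over every sample of the
   channel-selection set. The F-score filter (between-class over pooled
   within-class scatter) is provided for comparison.
3. **Channel selection.** Three strategies: (a) channels owning the top-N
   features; (b) MRCS — a channel's weight is the mean weight of its four
   features; (c) X-MRCS — starting from MRCS, a wrapped classifier (RBF
   SVM, one-vs-one, default `C` and `gamma`, five 10-fold
   cross-validations) evaluates the accuracy curve S(n) over top-n channel
   prefixes, each channel's relative marginal contribution
   `C(n) = (S(n) − S(n−1))/S(n−1)` multiplies its weight via
   `W_i = W_{i−1}(1 + C_{i−1})`, and the loop repeats until the largest
   negative contribution is below `epsilon = 0.01` or 50 iterations.
   Per-subject MRCS weights summed across subjects give a
   subject-independent ranking.
4. **Validation.** Accuracy curves on a held-out, trial-disjoint
   validation half, mean ± sd over 50 fold evaluations, with paired
   t-tests between strategies.

## What the synthetic generator emulates

Real affective-EEG benchmarks of this layout are access-gated, so the
package ships a generator reproducing their geometry exactly: trials ×
channels × time arrays (default 40 × 32 × 7680 at 128 Hz), valence and
arousal ratings in 1–9, four quadrant classes with configurable trial
counts. Class-discriminative structure is planted as *band-limited
Gaussian noise* components (filtered white noise, not pure tones — tones
would make band power degenerate and trivially separable) whose standard
deviation is `base_amplitude × multiplier`, with a per-(class, channel,
band) multiplier map. Background noise is white by default; a 1/f option
exists but white noise keeps analytic band-power expectations simple
(in-band variance share of white noise is just the relative bandwidth).
Ratings are drawn uniformly inside the class's quadrant, since only the
quadrant, never the rating value, enters the analysis.

What it deliberately does **not** emulate: volume conduction and
inter-electrode correlation, 1/f-dominated spectra with oscillatory
peaks, non-stationarity within trials, and ocular/muscular artifacts.
Passing tests therefore demonstrate that the algorithms recover planted
band-power structure under realistic noise levels and sample sizes — not
that any particular accuracy level transfers to real recordings.

```{r}
library(eegsel)
spec <- planted_generator_spec(informative = c(4, 18), strength = 2,
                               seed = 1)
ts <- generate_subject(spec)
ft <- zscore_features(extract_features(ts))
halves <- split_dataset(ft, seed = 2)
fw <- relieff(halves$selection, k = 10)
cw <- mrcs(fw)
summary(cw)[1:5, ]
fit <- xmrcs(halves$selection, cw, classifier_spec(seed = 3))
curve <- validate_selection(fit, halves$validation,
                            selection_table = halves$selection)
plot(curve)
```

## Parameters that matter

| parameter | default | role |
|---|---|---|
| window, overlap | 4 s, 0 | segment length (512 samples at 128 Hz) and spacing |
| bands | 4–8, 8–13, 13–30, 30–45 Hz | theta/alpha/beta/gamma definitions |
| `k` | 10 | ReliefF neighbours; must be below every class size |
| `epsilon` | 0.01 | X-MRCS stop threshold on the largest negative contribution |
| `max_iterations` | 50 | X-MRCS iteration cap (non-convergence is flagged, not an error) |
| CV scheme | 5 × 10-fold, stratified | accuracy estimation; per-fold values retained |
| SVM | RBF, `C = 1`, `gamma = 1/p`, one-vs-one | libsvm defaults via e1071, `scale = FALSE` (features already z-scored) |
| split | trial-level, stratified, ~50/50 | selection vs validation halves |

## Numerical choices

* **Filtering.** The band-pass filter is a 4th-order Butterworth applied
  forward and backward (zero phase, squared magnitude response),
  coefficients from `signal::butter`, with odd-reflection edge padding of
  three filter lengths. The forward–backward kernel is implemented in
  compiled code and is bit-exact against `signal::filter` per pass.
  Consequences worth knowing: the effective power gain is `|H|⁴`, so at
  each band crossover (where `|H|² = 1/2`) the summed response of
  adjacent bands dips to 1/2 — the four band powers of a 4–45 Hz
  band-limited signal recover its total power only to within roughly
  10% (tested tolerance 0.85–1.02). A mid-band pure tone's band power
  matches the literal DFT evaluation to 0.5% in alpha/beta/gamma; in the
  narrow theta band the pass-band gain alone costs ~1.1%, so theta-tone
  agreement is asserted at 2%.
* **Band power.** The mean squared FFT magnitude over *all* N bins of the
  filtered segment equals, by Parseval, the sum of squared filtered
  samples; the bulk extractor uses that identity, and a test pins it to
  the per-segment FFT path. No taper is applied (none is part of the
  procedure); segmentation is rectangular.
* **Filter scope.** By default each whole trial is filtered once per
  (channel, band) and then segmented, which avoids re-paying the filter
  transient in every 4-s window and is 15× cheaper; a per-segment mode
  (`filter_scope = "segment"`) matches `band_power()` exactly and is used
  in its equivalence test.
* **Z-scoring** uses the population (divide-by-n) standard deviation over
  all samples, and by default is fitted on the combined table *before*
  the selection/validation split, mirroring the reference procedure of
  normalising over all samples; this leaks means and scales (not labels)
  across the split, so a fit-on-selection-only mode
  (`normalize_scope = "train"`) is provided. Constant features are zeroed
  with a warning.
* **ReliefF conventions.** A sample is never its own hit; distance ties
  break by lowest sample index, making weights invariant to sample order;
  `diff` ranges (`max(f) − min(f)`) and class priors are computed on the
  scoring set only, which is the set the loop iterates; `m` equals the
  scoring-set size (no subsampling); distances use all normalized
  features. Every weight lies in [−1, 1].
* **X-MRCS conventions.** `C(1)` has no predecessor and is defined as 0,
  so the top channel is never updated through its own slot. The update is
  applied literally even to negative weights — where it inverts the
  intended direction — with a warning, preserving fidelity to the stated
  formula while making the regime visible. The "largest negative
  contribution" reads as the largest `|C(n)|` among negative `C(n)`; with
  no negative contribution the criterion is vacuously met and the loop
  stops. One fold partition (fixed by the classifier seed) is used across
  all iterations so curve differences reflect ranking changes, not fold
  noise, and identical channel prefixes are memoized across iterations.
  `C_{i−1}` in the update is the contribution computed under the previous
  ranking, as the iteration indices indicate. Only the channel-selection
  half ever enters the loop.
* **Folds** are stratified by class (plain k-fold can produce class-empty
  folds at these sizes); repetitions use distinct seeded partitions. By
  default folds split at the sample level, so sibling segments of one
  trial can fall in train and test folds of the *validation-internal*
  CV — a trial-grouped mode (`group_by_trial = TRUE`) is provided for a
  stricter reading. The selection/validation split itself is always at
  the trial level.
* **Ties** in channel weights break by lower channel index, everywhere,
  so rankings and curves are deterministic.

## Problem sizes used by the test suites

The statistical suites run at desk scale, chosen once as realistic for
the planted effects (a ×2 band-power multiplier on two channels, roughly
a 3:1 in-band power ratio against baseline):

* MRCS planted recovery: 50 seeds, 16 channels × 16 trials × 60 s
  (240 samples), both planted channels in the top 3.
* Subject-independent aggregation: 30 seeds × 8 subjects, 16 channels ×
  8 trials × 40 s each, both planted channels in the top 2.
* Chance-level control: 8 channels × 40 trials (600 samples), no planted
  effects, sample-level label permutation, accuracy averaged over 8
  permutations. A single permutation carries ~1.8 percentage points of
  dataset-level standard deviation — noise that fold-averaging cannot
  remove because the permuted labels are fixed across folds — so the
  permutation-averaged curve is the faithful estimator of chance
  accuracy.
* X-MRCS demotion: 20 seeds, 8 channels × 16 trials × 40 s, two planted
  channels, one pure-noise channel handed the top initial weight
  (emulating a noisy MRCS estimate that over-ranks a junk channel; this
  is the controllable realisation of the scenario — ReliefF itself
  cannot be made to over-score a classifier-useless channel reliably),
  2 CV repetitions, 6 iterations.

## Limitations

* Selection quality is bounded by the band-power feature family; phase,
  connectivity and time-domain structure are invisible to it.
* X-MRCS is classifier-specific by construction: a ranking tuned for the
  RBF SVM need not be optimal for another classifier.
* The accuracy curve is noisy at small n; `epsilon` below the curve's
  fold-to-fold noise floor makes the stopping rule effectively the
  iteration cap.
* The default normalization scope mirrors the reference procedure and
  mildly leaks scale information across the split; switch to
  `normalize_scope = "train"` for strict separation.
* Wrapper search over arbitrary channel subsets, spatial constraints
  (symmetric pairs, lobe quotas), and classifier hyperparameter tuning
  are out of scope.
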