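---
title: "Mixed-strategy whale optimization for sensor-behavior feature selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-strategy whale optimization for sensor-behavior feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iwoaselect)
```

## The problem

Neck-mounted inertial sensors are a standard tool for recognizing
livestock and poultry behaviors such as feeding and drinking. A typical
pipeline collapses the triaxial acceleration and angular-velocity streams
into resultant magnitudes, denoises them, cuts them into short overlapping
windows, and summarizes each window by a few dozen time- and
frequency-domain statistics that a classifier then maps to a behavior.
Many of those statistics are redundant, and redundancy measurably hurts
recognition accuracy. `iwoaselect` addresses the resulting subset-search
problem with a wrapper method: candidate feature subsets are scored by the
cross-validated accuracy of an actual classifier, and the search over the
$2^{44}$ subsets is driven by a mixed-strategy improved Whale Optimization
Algorithm (IWOA).

## The pipeline

1. **Resultant magnitudes.** Each sample's three acceleration axes are
   collapsed to $a = \sqrt{a_x^2 + a_y^2 + a_z^2}$ and likewise
   $j = \sqrt{j_x^2 + j_y^2 + j_z^2}$ for angular velocity
   (`resultant_magnitude()`). Orientation is deliberately discarded.
2. **Denoising.** An 8th-order low-pass Butterworth filter
   (`lowpass_filter()`) removes high-frequency sensor noise.
3. **Windowing.** Sliding windows of 14 samples with 50% overlap
   (`segment_windows()`); labeled bouts shorter than 3 s are excluded
   first (`exclude_short_bouts()`).
4. **Features.** 22 statistics per resultant signal — 11 time-domain and
   11 frequency-domain — giving 44 features per window
   (`window_features()`, `build_feature_table()`).
5. **Selection.** The IWOA searches $[0,1]^{44}$; positions decode to
   binary masks and are scored by the subset-penalized CV fitness
   (`select_features()`).
6. **Evaluation.** Confusion-matrix metrics, pairwise Kendall
   $\tau_b$ / approximate MIC redundancy, permutation importance and
   drop-one analyses (`classification_report()`, `kendall_tau_b()`,
   `mic_grid()`, `permutation_importance()`, `drop_one_report()`).

## The optimizer

The canonical whale optimizer moves each of $N$ whales by one of three
rules, chosen by random draws $p \sim U[0,1]$ and
$A = 2ar - a$ with $a = 2(1 - t/t_{\max})$ and $r \sim U[0,1]$:

* shrinking encirclement of the best
  ($p < 0.5$, $|A| < 1$): $X \leftarrow \omega X^* - A\,|C X^* - X|$;
* random-whale exploration ($p < 0.5$, $|A| \ge 1$):
  $X \leftarrow \omega X_{rand} - A\,|C X_{rand} - X|$;
* logarithmic spiral ($p \ge 0.5$):
  $X \leftarrow \omega X^* + |X^* - X|\, e^{bl} \cos 2\pi l$,
  $l \sim U[-1,1]$.

`variant = "woa"` fixes $\omega \equiv 1$. The IWOA variant adds three
strategies:

* **Good-point-set initialization** (`good_point_set_init()`): with $q$
  the smallest prime satisfying $(q-3)/2 \ge s$, point $k$ has unit-cube
  coordinates $\{2\cos(2\pi i/q)\, k\}$, a deterministic low-discrepancy
  spread that covers the box more evenly than uniform draws.
* **Adaptive inertia weight** (`adaptive_weight()`):
  $\omega(t) = \sin(\pi t / 2 t_{\max} + \pi) + 1$, decaying from 1 to 0,
  so early iterations explore with large steps and late iterations refine
  locally.
* **Dimension-wise lens-imaging opposition**
  (`dimensionwise_lens_refine()`): each iteration, every coordinate of the
  incumbent best is tentatively replaced by its convex-lens reverse point
  $r_1 \frac{a+b}{2} + r_2 \frac{a+b}{2n} - r_3 \frac{x}{n}$, accepted
  only on strict improvement. The schedules
  $r_1 = 1 - \log_2(1 + t/t_{\max})$, $r_2 = 1 - (t/t_{\max})^2$,
  $r_3 = 1 - (t/t_{\max})^3$ move the reverse point from a wide
  exploration of the box toward the bound midpoint as the run ends. With
  $n = 1$ and unit weights this is classical opposition $a + b - x$. The
  step costs $s$ extra evaluations per iteration; total evaluation count
  is $N t_{\max} + s\, t_{\max}$.

### The wrapper fitness

A mask selecting `feasel` of `numfea` features is scored by
$$\mathrm{Fitn} = \alpha\,(1 - \mathrm{Acc}) + \beta\,\frac{feasel}{numfea},
\qquad \alpha = 0.99,\ \beta = 0.01,$$
where Acc is the stratified five-fold CV accuracy of the configured
classifier on the masked training columns (`cv_accuracy()`). Accuracy
dominates; the size term discriminates among subsets of equal accuracy.
Because the continuous-to-binary decoding is not dictated by the method
itself, the package uses a documented threshold rule: bit $j$ is set iff
the coordinate exceeds 0.5, with a fall-back to the largest coordinate so
the mask is never empty (`decode_mask()`). Mask scores are memoized, so
re-visited subsets cost no classifier fits.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| sampling rate `fs` | 5 | Hz | the neck sensor's collection frequency |
| filter order | 8 | – | steep roll-off at short windows |
| filter cutoff | 1.0 | Hz | not dictated by the method; passes sub-2 Hz behavioral motion, removes noise near Nyquist (2.5 Hz); exposed in `filter_spec()` |
| filter mode | zero-phase | – | no phase lag, so window labels stay aligned; squares the gain (documented); causal single-pass mode provided |
| window size / overlap | 14 / 50% | samples / – | 2.8 s windows balance feature stability against bout resolution |
| min bout duration | 3 | s | shorter labeled runs carry too little signal |
| population / iterations | 15 / 50 | – | the standard small-budget protocol for this method family |
| spiral constant `b` | 1 | – | canonical value |
| lens scale `n` | 1000 | – | not dictated by the method; a large `n` keeps late-run reverse points near the bound midpoint while the $r$ schedules supply coarse-to-fine movement; configurable |
| $\alpha$ / $\beta$ | 0.99 / 0.01 | – | accuracy-dominated fitness |
| CV folds | 5 | – | wrapper convention |
| train fraction | 0.6 | – | 6:4 stratified split; per-class test size `round(0.4 n_c)` |

## Numerical conventions

Estimator conventions that the feature definitions leave open are pinned
as follows (all deterministic):

* Quantiles use linear interpolation (R type 7); the window variance is
  the **population** variance ($1/N$); `over_mean_count` counts samples
  strictly above the window mean; the mode bins values at 2 decimals and
  breaks count ties toward the smallest value.
* The DFT features use the DC-exclusive half-spectrum
  $A_k = |X_k|,\ k = 1..\lfloor N/2\rfloor$; `dc` is $|X_0|/N$, equal to
  the window mean. Amplitude statistics are sample moments of $\{A_k\}$
  (variance with $K-1$); the "slope" statistics of the moment family are
  implemented as skewness, and both kurtoses are reported as **excess**
  kurtosis. Shape statistics treat $p_k = A_k/\sum A$ as a probability
  mass over bin frequencies $f_k = k f_s / N$ (spectral centroid and its
  central moments). Zero-variance spectra yield zeros.
* The zero-phase filter pads with constant-held endpoints sized from the
  filter's slowest pole (transient below $10^{-13}$), so constants pass
  exactly and edges are clean. The filter's magnitude response follows
  the bilinear-transform closed form
  $(1 + (\tan(\pi f/f_s)/\tan(\pi f_c/f_s))^{2n})^{-1/2}$, which matches
  the analog prototype $(1 + (f/f_c)^{2n})^{-1/2}$ when the cutoff sits
  well below Nyquist.
* Window labels are the majority vote over samples, ties broken toward
  the label appearing earlier in the window. Windows are 0-based,
  half-open, step `round(size * (1 - overlap))`.
* In the optimizer, $A$ is a scalar draw per whale (the
  exploration/exploitation branch is a scalar condition) while $C$ is
  drawn per dimension; positions are clipped to the bounds; the update
  schedules are evaluated at $t/t_{\max}$ for iteration
  $t = 1..t_{\max}$; whales update in index order from a single seeded
  generator, and the caller's RNG state is untouched.
* Report percentages are rounded **half-up** to 2 decimals, and macro
  rows average the rounded per-class percentages — the convention that
  reproduces how such tables are commonly printed. Per-class F1 is
  computed from the unrounded precision and recall.
* Kendall $\tau_b$ delegates to `stats::cor(method = "kendall")` (the
  tie-corrected form); all-tied input returns 0 with a warning. The MIC
  is an equal-frequency-grid approximation maximized over shapes
  $k \times l \le n^{0.6}$, not the published dynamic-programming
  estimator; by construction it is symmetric and invariant under strictly
  monotone transforms.

## The synthetic generator

No public recording of the target system exists, so the package ships a
two-level generator. `simulate_recording()` emulates the two behaviors'
signal morphology: feeding as a fast (2.2 Hz), high-amplitude, duty-cycled
peck train with vigorous head rotation; drinking as slower (0.5 Hz),
lower-amplitude sip cycles; both share a 1 g baseline with Gaussian
sensor noise. The frozen defaults (`default_behavior_specs()`) were
calibrated once so that the two classes' resultant-magnitude
distributions overlap substantially (Bhattacharyya coefficient ≈ 0.9 —
magnitude alone cannot separate them) while the windowed 44-feature
representation is separable (CV accuracy > 0.99). `reference_schedule()`
sizes one feeding and one drinking bout (8380 and 5460 samples at 5 Hz)
so that majority-vote windowing yields exactly 1197 feeding and 779
drinking windows, the class balance at which the full pipeline and its
6:4 split (479 + 312 = 791 test rows) are exercised.

`make_table()` generates feature tables with known structure for
parameter-recovery experiments: class-shifted informative Gaussians,
noisy copies of them (redundant), and class-independent noise, plus the
ground-truth mask for `recovery_score()`.

What the generator does **not** emulate: real pecking kinematics,
posture-dependent gravity components, sensor drift, inter-animal
variability, or transitional behaviors. Passing tests therefore
demonstrate that the pipeline and optimizer behave correctly on data with
the stated statistical structure, not that any particular accuracy will
be attained on real recordings.

## Design choices on open questions

* Whether the CV fitness should see all rows or only the training split
  is ambiguous in wrapper practice; the package computes it on the
  training split only and reserves the test split for the final report —
  the leakage-safe reading.
* The lens refinement runs every iteration (its cost, $+s$ evaluations
  per iteration, is recorded in `eval_count`); greedy per-dimension
  acceptance requires strict improvement, so plateaus do not drift.
* The adaptive weight multiplies the incumbent (or random whale) exactly
  as the update rules are stated, including the exploration rule.
* Classifiers are pluggable behind one fit/predict interface
  (`make_classifier()`): gradient-boosted trees (default), logistic
  regression, LDA, CART, naive Bayes. The experiments in the test suite
  use LDA, whose closed-form fit makes the wrapper loop fast; the
  benchmark problem sizes there (e.g. 240-row, 30-feature recovery
  tables; 10-D benchmark functions at the 15-whale / 50-iteration
  budget over 10–20 seeds) are the package's chosen reference
  experiment sizes.

## Known limitations

* The lens opposition pulls coordinates toward the bound midpoint, which
  flatters benchmark functions whose optimum sits at the box center;
  directional WOA-vs-IWOA comparisons in the tests should be read with
  that geometry in mind. On the selection hypercube the optimum is not at
  the center, and the directional advantage persists there.
* The grid MIC is an approximation; its absolute values are comparable
  within this package but not to published MIC tables.
* The wrapper re-scores every distinct mask with a full CV loop; for
  classifiers much slower than the provided backends, expect the
  optimizer budget, not the data size, to dominate runtime.
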