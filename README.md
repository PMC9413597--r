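# iwoaselect

Wrapper feature selection for accelerometer-based animal behavior
recognition, built around a mixed-strategy **improved Whale Optimization
Algorithm (IWOA)**.

Neck-mounted inertial sensors turn livestock and poultry behaviors —
feeding, drinking — into triaxial acceleration and angular-velocity
streams. The standard recognition pipeline collapses each stream to its
resultant magnitude ($a=\sqrt{a_x^2+a_y^2+a_z^2}$), denoises it with a
Butterworth low-pass, windows it (14 samples, 50% overlap at 5 Hz), and
summarizes each window by 44 time/frequency statistics. Many of those
features are redundant, and redundancy costs accuracy. `iwoaselect`
searches the $2^{44}$ feature subsets with a wrapper: each candidate mask
is scored by the stratified five-fold cross-validated accuracy of a real
classifier, penalized by subset size,

$$\mathrm{Fitn} \;=\; \alpha\,(1-\mathrm{Acc}) \;+\;
\beta\,\frac{feasel}{numfea}, \qquad \alpha=0.99,\; \beta=0.01 ,$$

and the search is driven by a whale optimizer improved with three mixed
strategies: **good-point-set** low-discrepancy initialization, an
**adaptive inertia weight** $\omega(t)=\sin(\pi t/2t_{\max}+\pi)+1$, and
**dimension-wise lens-imaging opposition** of the incumbent best with
decaying weights $r_1,r_2,r_3$. The package also ships the full pipeline
around the optimizer — preprocessing, the 44-feature extractor,
evaluation metrics with Kendall $\tau_b$ / approximate-MIC redundancy
analysis, permutation importance — and seeded synthetic-data generators,
since no public recording of the target system exists.

## Worked example

Evaluation arithmetic on a held-out confusion matrix (counts indexed
`[true, predicted]`):

```r
library(iwoaselect)
cm <- matrix(c(458, 14, 21, 298), 2,
             dimnames = list(true = c("eating", "drinking"),
                             predicted = c("eating", "drinking")))
classification_report(cm)
#>          precision recall    f1 accuracy
#> eating       97.03  95.62 96.32    95.58
#> drinking     93.42  95.51 94.45    95.58
#> macro: precision 95.23  recall 95.57  F1 95.39  (n = 791)
```

Of 479 true feeding windows, 458 were recognized (recall 95.62%); of the
472 windows predicted as feeding, 458 were right (precision 97.03%);
overall accuracy is 756/791 = 95.58%. A candidate subset with five-fold
CV accuracy 0.9558 using 12 of 44 features scores

```r
selection_fitness(0.9558, 12, 44)
#> [1] 0.04648527
```

(0.0465 at four decimals — lower is better). A complete synthetic
experiment, from raw simulated sensor streams to a selected subset:

```r
cfg <- pipeline_config(
  seed = 3,
  schedule = data.frame(label = rep(c("eating", "drinking"), 3),
                        duration_s = rep(c(80, 60), 3)),
  opt = optimizer_config(pop_size = 8, max_iter = 8, seed = 3),
  fit = fitness_config(classifier = "lda", cv_seed = 3))
run_pipeline(cfg)
#> <pipeline run>
#>   299 windows; selected 2/44 features
#>   held-out accuracy 99.16% (all-feature baseline 100.00%)
```

The optimizer finds that two angular-velocity features (`gyr_dc`,
`gyr_amp_mean`) almost perfectly separate the two simulated behaviors —
a 44 → 2 reduction at a 0.84-point accuracy cost on this easy synthetic
preset. `reference_schedule()` scales the same experiment to 1197
feeding + 779 drinking windows with a 6:4 stratified split (791 test
rows).

A command-line front-end over the same functions lives at
`inst/cli/iwoaselect.R` (subcommands `simulate`, `preprocess`, `extract`,
`select`, `evaluate`, `benchmark`, `compare`, `pipeline`).

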