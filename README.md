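# otter

Analysis of **opto-thermal transient emission radiometry (OTTER)**
signals in R: physical forward models of the emission decay, hydration
inversion, segmented least-squares (SLS) depth profiling, and a
train/test benchmarking study of standard machine-learning estimators on
raw signal features.

OTTER heats a sample — most often in-vivo skin — with a short
mid-infrared laser pulse and records the decay of the resulting blackbody
emission. For a semi-infinite, optically homogeneous sample the signal is

$$S(t) = A\,e^{t/\tau}\,\mathrm{erfc}\sqrt{t/\tau},
\qquad \tau = \frac{1}{\beta^{2} D},$$

where $A$ is the amplitude, $\beta$ the emission absorption coefficient
(1/m) at the detection wavelength, and $D$ the thermal diffusivity
(m²/s). Fitting $\tau$ and converting $\beta$ through
$H = (\beta_w - \beta)/(\beta_w - \beta_d)$ yields the water content of
roughly the top 20 µm of the stratum corneum. A closed-form extension
handles a linear absorption depth gradient
$\beta(z) = \beta_0 + w_\beta z$ through the effective gradient
$W = w_\beta D$, and SLS fitting of cumulatively growing early-time
windows resolves $\beta$ (hence hydration) against probing depth
$z = \sqrt{D t}$.

Because the underlying volunteer measurements are not distributed, the
package ships a seeded synthetic-signal generator that emulates the
study campaigns (a 97-signal hydration-regression set and a 20-signal,
4-subject classification set), so every stage — fitting, profiling,
benchmarking, embeddings, feature attribution — is fully testable and
reproducible offline. It is intended for photothermal/biomedical-optics
researchers who want a tested reference implementation of the decay
models and of the benchmarking protocol.

## Worked example

```r
library(otter)

# a 97-signal synthetic hydration campaign (512 samples per decay, 1% noise)
ds <- generate_regression_dataset(regression_spec(), acquisition_config(), seed = 1)
ds
#> <otter_dataset: regression>
#>   97 signals x 512 time samples (t in [0, 0.00962] s)
#>   labels: hydration | seed: 1

# invert one decay: amplitude, lifetime, absorption coefficient
fit_homogeneous(dataset_signal(ds, 1))
#> <otter_fit: homogeneous model>
#>   A = 0.966001  tau = 0.000416003 s
#>   beta = 155043 1/m  residual rms = 0.00953  converged (4 iter)
```

The generating truth for that row was A = 0.9687, τ = 4.109e-4 s: at 1%
detector noise the lifetime comes back within ~1%. SLS profiling of the
same record gives β (and hydration) against probing depth in microns:

```r
sls_profile(dataset_signal(ds, 1), beta_w = 2.5e5, beta_d = 5e4)
#> # A tibble: 10 x 7
#>   slice  t_end_s        z_m  z_um    beta converged hydration
#> 1     1 0.000962 0.00000981  9.81 151750. TRUE          0.491
#> 2     2 0.00192  0.0000139  13.9  155166. TRUE          0.474
#> 3     3 0.00289  0.0000170  17.0  155409. TRUE          0.473
#> # 7 more rows
```

This signal was generated homogeneous, so the profile is flat around the
true β ≈ 1.55e5 1/m (hydration ≈ 0.47). The benchmark suites take a
dataset and a split specification and return tidy reports:

```r
run_regression_suite(ds, split_spec(seed = 1),
                     models = c("linear", "pls", "knn", "random_forest"))
#>           model r2_train r2_test rmse_test
#> 1        linear    1.000   0.968    0.0283
#> 2           pls    0.963   0.952    0.0344
#> 3           knn    0.980   0.974    0.0256
#> 4 random_forest    0.994   0.968    0.0282

dc <- generate_classification_dataset(classification_spec(),
                                      acquisition_config(), seed = 1)
run_classification_suite(dc, split_spec(seed = 1, stratify = TRUE))
#>               model accuracy_train_pct accuracy_test_pct
#> 1          logistic                100               100
#> 2       naive_bayes                100               100
#> 3               svc                100               100
#> 4     random_forest                100               100
#> 5           bagging                100               100
#> 6          adaboost                100               100
#> 7 gradient_boosting                100               100
#> 8     deep_learning                100                75
#> 9               lda                100               100
```

Test R² ≈ 0.97 for ordinary linear regression on the hydration labels,
and near-perfect subject classification on the well-separated synthetic
subjects, echo the pattern reported for the real campaigns: hydration is
a smooth functional of the decay shape, and a handful of repeated decays
per subject is enough to separate subjects. `embed_signals()` (PCA/LDA),
`pca_then_classify()`, and `feature_importance()` cover the
dimensionality-reduction and attribution parts of the study;
`autoplot()` methods plot datasets, depth profiles, embeddings, and
reports.

A command-line pipeline wraps the same functions
(`inst/cli/otter simulate | fit | profile | bench-reg | bench-clf |
report`), driven by a YAML configuration with full seed logging;
identical configuration and seed reproduce byte-identical outputs.

## Method details

See the methods vignette (`vignettes/otter-methods.Rmd`) for the model
derivations and assumptions, the numerical conventions (depth
assignment, slice partition, optimizer settings, degenerate-input
handling), the synthetic generator's population choices, and known
limitations.
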