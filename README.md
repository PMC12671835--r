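# fpfd

Tools for the **Fréchet–Power Function (FPF) distribution** — a
two-shape-parameter family on a bounded support $(a, b)$ for lifetime,
reliability and environmental data that are boxed into a known interval
yet skewed and tail-heavy. It is built by passing the Power Function
baseline $F_0(x) = \left(\frac{x-a}{b-a}\right)^\theta$ through a
Fréchet-type generator:

$$
F(x) = \frac{e^{-F_0(x)^\alpha} - 1}{e^{-1} - 1},
\qquad
f(x) = \frac{\lambda\, v^{\lambda-1} e^{-v^\lambda}}{(b-a)(1-e^{-1})},
\qquad v = \tfrac{x-a}{b-a},\ \ \lambda = \alpha\theta .
$$

The density depends on $(\alpha,\theta)$ only through $\lambda =
\alpha\theta$ — an exact likelihood ridge — so inference here is
one-dimensional in $\lambda$, with per-parameter estimates available
once the partner is fixed.

The package provides:

* `dfpf` / `pfpf` / `qfpf` / `rfpf` plus survival `sfpf`, hazard `hfpf`,
  and a hazard-shape classifier (`classify_hazard_shape`);
* exact moments, skewness/kurtosis and the MGF series via the lower
  incomplete gamma function (`fpf_mean`, `fpf_moments`, `fpf_mgf`);
* maximum likelihood (`fit_fpf`) with Wald and bootstrap intervals,
  observed information with a ridge-singularity diagnostic, and
  broom-style `tidy()` / `glance()` methods;
* an acceptance–rejection sampler with a Power Function proposal
  (`rfpf_ar`), analytic bound $c = 1/(1-e^{-1})$ at the default
  proposal;
* seven competitor bounded-lifetime models and a model-comparison table
  (`compare_models`) with AIC/BIC/AICc/HQIC, KS/Cramér–von Mises/
  Anderson–Darling statistics and LR/Vuong tests;
* a Monte-Carlo harness for estimator bias, MSE and coverage
  (`fpf_sim_cell`, `fpf_sim_grid`);
* three embedded benchmark datasets (`fpf_data`): 76 kidney-infection
  frailty values, 30 repair times, 100 Fort Collins annual-maximum
  precipitation values;
* a command-line interface (`fpf_cli`; script at
  `system.file("cli", "fpf.R", package = "fpfd")`).

## Worked example

Fit the FPF model to the repair-times benchmark and compare it with the
exponential and Power Function models:

```r
library(fpfd)

x <- fpf_data("repair-times")
fit <- fit_fpf(x, mode = "alpha-fixed", fixed = 1)
tidy(fit)
#> # A tibble: 2 × 5
#>   term   estimate std.error conf.low conf.high
#>   <chr>     <dbl>     <dbl>    <dbl>     <dbl>
#> 1 lambda    0.929     0.145    0.646      1.21
#> 2 theta     0.929     0.145    0.646      1.21

compare_models(x, models = c("FPFD", "ED", "PFD"))
#> Model comparison (support (0, 4.73)), sorted by AIC:
#> # A tibble: 3 × 13
#>   model     k loglik   aic   bic  caic  hqic   ks_d   ks_p cvm_w  ad_a ...
#> 1 ED        1  -43.0  88.0  89.4  88.2  88.5 0.184  0.259  0.232  1.33
#> 2 FPFD      2  -42.5  89.1  91.9  89.5  89.9 0.204  0.164  0.345  2.02
#> 3 PFD       1  -44.8  91.5  92.9  91.7  92.0 0.244  0.0569 0.494  2.71
```

Reading the output: `lambda` is the identifying product $\alpha\theta$;
with $\alpha$ fixed at 1 the `theta` row is the same estimate
transported to the $\theta$ scale. In the comparison table the
exponential row reproduces the published benchmark values for this
dataset ($\hat\lambda = 0.6482$, $\ell = -43.0054$, AIC $= 88.01$,
BIC $= 89.41$) because the exponential fit is closed-form and
convention-free; the bounded models' log-likelihoods depend on the
support convention (here $a = 0$, $b$ just above the sample maximum),
which the table header reports.

Draws and quantiles:

```r
qfpf(c(0.1, 0.25), alpha = 0.5, theta = 1, a = 0, b = 10)
#> [1] 0.04263873 0.29587805        # 0.04 and 0.30 at 2 dp

x <- rfpf(5, alpha = 3, theta = 2, seed = 1)
classify_hazard_shape(alpha = 3, theta = 2)$label
#> [1] "increasing"
```

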