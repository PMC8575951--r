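# grsmix

Estimating disease prevalence within a cohort from the distribution of a
polygenic **genetic risk score (GRS)**.

Estimating how much disease a cohort contains usually requires clinical
classification of every member — investigations that population-scale
datasets rarely include, and self-report is unreliable. grsmix takes a
different route: if the GRS distributions of known cases (R<sub>C</sub>) and
known non-cases (R<sub>N</sub>) are available, the GRS distribution of any
mixed cohort M&#771; must lie between them, and its position determines the
mixing fraction p<sub>C</sub> — the prevalence of the disease in that
cohort. No individual is classified; only the cohort-level fraction is
estimated. The package is aimed at epidemiologists and clinical researchers
working with population biobank data and published GRS weights.

## Methods at its core

Four estimators of p<sub>C</sub> from the three score samples:

* **Excess** — with m the reference median closest to the mixture median,
  p̂<sub>C</sub> = |(#{x &gt; m} − #{x ≤ m}) / n|; the baseline method, which
  systematically underestimates.
* **Means** — p̂<sub>C</sub> = |(μ<sub>M</sub> − μ<sub>R<sub>N</sub></sub>) /
  (μ<sub>R<sub>C</sub></sub> − μ<sub>R<sub>N</sub></sub>)|, with mixture
  means outside the reference means mapped to 0/1 by the closest reference.
* **EMD** — p<sub>x</sub><sup>EMD</sup> = 1 − EMD(R<sub>x</sub>, M&#771;) /
  EMD(R<sub>C</sub>, R<sub>N</sub>) for x ∈ {C, N}, where EMD is the 1-D
  Wasserstein distance ∫|CDF₁ − CDF₂|dz on a shared Freedman–Diaconis grid;
  the reported estimate averages the two, (p<sub>C</sub><sup>EMD</sup> + 1 −
  p<sub>N</sub><sup>EMD</sup>)/2, and |p<sub>C</sub><sup>EMD</sup> +
  p<sub>N</sub><sup>EMD</sup> − 1| diagnoses the two-component assumption.
* **KDE** — Gaussian kernel density templates of the references are fitted
  to the mixture's template by bounded Levenberg–Marquardt least squares;
  p̂<sub>C</sub> = w<sub>C</sub>/(w<sub>C</sub> + w<sub>N</sub>).

Uncertainty comes from a combined Monte-Carlo + bootstrap scheme:
N<sub>M</sub> modelled mixtures are recomposed from the references at the
point estimate, each resampled N<sub>B</sub> times, and the N<sub>M</sub>·
N<sub>B</sub> re-estimates feed a bias-corrected and accelerated (BCa)
interval with jackknife acceleration and a Student-t narrowness-bias
expansion of the nominal level.

Also included: synthetic GRS generators calibrated to a target AUC via
d = √2·Φ⁻¹(AUC), GRS computation from dosage matrices and ln-odds-ratio
weights, proportion-by-size sweeps, a minimum-mixture-size search, and
reconstruction of clinical trait means in the genetically defined case
group.

## Worked example

```r
library(grsmix)

# synthetic cohorts: references of 2000 each at AUC 0.88,
# a mixture of 5000 with a true case fraction of 0.15
d <- simulate_grs_cohorts(auc = 0.88, n_ref = 2000, n_mix = 5000,
                          p_case = 0.15, seed = 42)

fit <- estimate_prevalence(d)
fit
#> Mixture proportion estimates (mixture n = 5000; references 2000 cases / 2000 non-cases; reference AUC = 0.118)
#> # A tibble: 4 × 3
#>   method p_case p_noncase
#>   <chr>   <dbl>     <dbl>
#> 1 excess 0.0784     0.922
#> 2 means  0.130      0.870
#> 3 emd    0.129      0.871
#> 4 kde    0.125      0.875
```

Means, EMD and KDE land close to the true 0.15 (the remaining gap is the
sampling noise of one mixture draw); the Excess method underestimates by
design. The printed reference AUC is directional — P(case score &gt;
non-case score) — and is below 0.5 here because this synthetic design
shifts the *non-case* generator upward; discriminability is max(AUC, 1 −
AUC) = 0.88.

```r
ci <- prevalence_ci(d, method = "emd", n_mixtures = 10, n_boot = 100, seed = 42)
ci
#> emd method: p_case = 0.1289, 95% BCa CI [0.1043, 0.1521]
#>   bias = 0.0005, z0 = -0.050, acceleration = 0.0007 (n = 5000, 10 x 100 bootstrap estimates)

tidy(ci)
#> # A tibble: 1 × 8
#>   method estimate     bias conf_low conf_high ci_defined      z0 acceleration
#>   <chr>     <dbl>    <dbl>    <dbl>     <dbl> <lgl>        <dbl>        <dbl>
#> 1 emd       0.129 0.000544    0.104     0.152 TRUE       -0.0502     0.000686
```

The interval (here at reduced replication for speed; defaults are
`n_mixtures = 100, n_boot = 1000`) covers the true fraction 0.15; `bias` is
the Monte-Carlo median bias of the method at this configuration, essentially
zero for EMD. `autoplot()` methods visualise the
fitted distributions, the bootstrap violin with its interval, sweep
heatmaps and diagnostic nulls; `tidy()`/`glance()` return tibbles
throughout. A thin command-line wrapper is installed at
`system.file("cli", "grsmix.R", package = "grsmix")` with `estimate`, `ci`
and `synth` subcommands.

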