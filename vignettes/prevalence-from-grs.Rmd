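---
title: "Estimating disease prevalence from genetic risk score distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating disease prevalence from genetic risk score distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grsmix)
library(dplyr)
```

## The problem

A polygenic genetic risk score (GRS) — the sum of risk-allele dosages
weighted by log odds ratios — is rarely informative enough to classify an
*individual* as having a disease. At the *group* level, however, the GRS
distribution of a cohort that mixes cases and non-cases must lie between the
GRS distributions of pure case and pure non-case reference cohorts, and its
position pins down the mixing fraction. grsmix estimates that fraction
$p_C$ — the disease prevalence within the cohort — from three samples of
scores: a case reference $R_C$, a non-case reference $R_N$, and the mixture
$\tilde M$. All estimators assume the mixture contains only individuals
drawn from the two reference distributions ($p_C + p_N = 1$), and that cases
and non-cases in the mixture are genetically equivalent to their reference
cohorts.

## The four estimators

**Excess.** Let $m$ be the reference median (of $R_C$ or $R_N$) closest to
the mixture median. The estimate is the absolute normalised imbalance of
mixture scores around it:
$\hat p_C = \left|\frac{\#\{x > m\} - \#\{x \le m\}}{n}\right|$.
A pure non-case cohort is balanced around its own median, so the surplus on
one side measures the admixed cases. Because part of the case distribution
always falls below $m$, the method systematically underestimates $p_C$; it
is included as the baseline it is.

Two conventions are fixed for reproducibility: scores exactly equal to $m$
count on the "below" side (as the formula's $\le$ states), and an exact tie
in median distance selects the non-case reference.

**Means.** $\hat p_C = \left|\frac{\mu_M - \mu_{R_N}}{\mu_{R_C} -
\mu_{R_N}}\right|$, the mixture mean linearly interpolated between the
reference means. A mixture mean outside the interval spanned by the
reference means is mapped to 1 or 0 according to the closest reference
mean. Equal reference means leave the method undefined (an error).

**EMD.** The Earth Mover's Distance between one-dimensional distributions is
the integral of the absolute difference of their CDFs. On a shared grid
(below) we compute
$p_x^{EMD} = 1 - EMD(R_x, \tilde M) / EMD(R_C, R_N)$ for $x \in \{C, N\}$.
The two estimates are independent, so their sum's deviation from one,
$|p_C^{EMD} + p_N^{EMD} - 1|$, doubles as a diagnostic of the two-component
assumption; under that assumption the reported estimate is the average
$\hat p_C = (p_C^{EMD} + 1 - p_N^{EMD})/2$, clipped to $[0,1]$.

**KDE.** Each cohort is smoothed with a Gaussian kernel into a density
template on the shared grid; the mixture template is fitted by a weighted
sum $w_C\,KDE_C + w_N\,KDE_N$ with damped least squares
(Levenberg–Marquardt, both weights initialised at 1 and constrained to
$[0,1]$), and $\hat p_C = w_C/(w_C + w_N)$. The objective is linear in the
weights, hence convex with a constant Jacobian; the fixed initialisation
keeps runs deterministic, and the local-minimum caveat of damped least
squares is immaterial here. Templates are normalised to unit area on the
grid before fitting so the weights are directly comparable mixture
fractions — any common normalisation cancels in $w_C/(w_C+w_N)$.

### The shared grid

EMD and KDE evaluate distributions at the centres of histogram bins whose
width follows the Freedman–Diaconis rule, $h = 2\,\mathrm{IQR}/n^{1/3}$,
computed on the two reference cohorts pooled (IQR uses linear-interpolation
type-7 quantiles, the default of mainstream numeric stacks; grid resolution
absorbs the convention's small sensitivity). The support runs from the
minimum to the maximum score over all three cohorts; the first bin centre
sits at the support minimum plus $h/2$ and the final partial bin is
retained. The same $h$ is the KDE bandwidth. Empirical CDFs are evaluated
stepwise (right-continuous) at bin centres; raw scores are used throughout —
Means is scale-invariant and EMD/KDE are scale-covariant, so standardising
would change nothing but the grid.

## Uncertainty: Monte-Carlo modelled mixtures and BCa intervals

The sampling noise of an estimate has two sources: the composition of the
mixture cohort itself, and the finite reference samples. Both are captured
by a two-stage scheme. First, $N_M$ new mixtures of the observed size $n$
are *modelled*: each contains $\mathrm{round}(\hat p_C\, n)$ scores drawn
with replacement from $R_C$ and the remainder from $R_N$ (rounding is R's
round-half-to-even; it changes the composition by at most one individual).
Each modelled mixture is then resampled with replacement $N_B$ times and
re-estimated, giving $N_M \cdot N_B$ bootstrap estimates $p'_C$.

From these, the systematic median bias is
$B = \mathrm{med}(p'_C) - \hat p_C$, and a bias-corrected and accelerated
(BCa) interval is built:

* median-bias factor $z_0 = \Phi^{-1}\!\big(\#(p'_C \le \hat p_C)/(N_M
  N_B)\big)$;
* acceleration $\hat a = \tfrac{1}{6}\sum U_i^3 / (\sum U_i^2)^{3/2}$ with
  jackknife influence values $U_i = (n-1)(\hat p_C - \hat p_i)$, where
  $\hat p_i$ is the full estimator re-run on the observed mixture with score
  $i$ removed (references held fixed; for Excess the reference median is
  re-selected on each reduced sample);
* narrowness-bias expansion
  $\alpha' = \Phi\!\big(\mathcal T^{-1}_{n-1}(\alpha)\sqrt{n/(n-1)}\big)$,
  applied to each one-sided level, with $n$ the mixture size;
* adjusted levels $\alpha_{BCa}(\alpha) = \Phi\!\big(z_0 + \frac{z_0 +
  \Phi^{-1}(\alpha')}{1 - \hat a\,(z_0 + \Phi^{-1}(\alpha'))}\big)$, and the
  interval limits are the corresponding linear-interpolation quantiles of
  $p'_C$.

With $z_0 = \hat a = 0$ the adjusted level reduces exactly to $\alpha'$. If
every bootstrap estimate falls on one side of $\hat p_C$, $z_0$ is infinite:
the interval is reported as undefined, with both limits collapsed onto the
corresponding extreme of the bootstrap distribution (this happens routinely
when $\hat p_C$ is exactly 0 or 1). If all jackknife estimates coincide the
acceleration denominator vanishes; $\hat a$ is set to 0 with a warning and
the interval reduces to the expanded-percentile form.

Determinism: one master seed is supplied; per-mixture and per-bootstrap
sub-streams are derived from it arithmetically, so identical calls are
bit-identical.

For speed, the bootstrap and jackknife loops reuse the grid, reference CDFs
and KDE templates computed once from the references and the observed
mixture: resamples only contain values already present there, so the grid
still covers them. Leave-one-out estimates use closed-form updates (running
means, bin-count decrements, kernel-matrix row removal); each fast path is
tested for exact agreement with naive re-estimation.

## Synthetic data

The generator reproduces a binormal study design. The case reference is
drawn from $N(0,1)$ and the non-case reference from $N(d,1)$, with the
offset calibrated to a target discriminability via
$d = \sqrt{2}\,\Phi^{-1}(AUC)$ (0.74 at AUC 0.7, 1.81 at AUC 0.9). Complete
separation (AUC = 1) is emulated with a sentinel offset of 7. Mixtures draw
$\mathrm{round}(p_C n)$ scores from the case generator and the rest from the
shifted generator, independently of the reference draws. Defaults follow the
design the estimators were characterised under: $n_{ref} = 2000$ per
reference, mixtures of 5000, $p_C = 0.1$.

Real GRS distributions can be skewed (a few large-effect loci, e.g. HLA) or
heavy-tailed; the Gaussian generator does not emulate that, so passing
synthetic tests demonstrates correctness of the machinery under the
equal-SD binormal model, not robustness to arbitrary score distributions.
EMD and KDE, which use whole distributions rather than single moments, are
the methods expected to benefit from such features in real data.

For experiments that freeze one reference draw and reuse it everywhere
(`min_mixture_size()`), the frozen samples are recentred and rescaled to the
exact generator moments (`moment_match = TRUE`). A single $n = 2000$ draw
can sit two standard errors off its generator mean — enough to visibly
distort the Excess method, whose estimate depends on a single empirical
median. Moment matching makes the frozen draw representative of its
generator, which is precisely what reusing "one good draw" is meant to
achieve; the default for ordinary generation remains unmatched raw draws.

## Study-design experiments

`sweep_proportion_size()` maps estimator behaviour over a grid of true
proportions and mixture sizes (one resampled mixture per cell, with a
derived per-cell seed), recording estimate, bias, deviation and CI width,
with a miss flag when the interval excludes the truth, collapses, or is
undefined.

`min_mixture_size()` walks a ladder of mixture sizes (default steps of 100,
optionally coarsening above a crossover for the costlier KDE method) and
reports, per run, the first size whose interval is defined and narrower than
the target width. A run whose selected interval excludes the true proportion
is disregarded as a miss; the summary reports the median and quartiles over
the remaining runs plus both counts. When no run covers the truth the search
is flagged non-convergent — the estimator is converging to the wrong value,
which is how the Excess method behaves at low AUC.

`check_mixture_assumption()` turns the EMD sum-deviation and the KDE fit
residual into a calibrated diagnostic: mixtures are re-generated from the
references under the two-component assumption at the estimated composition,
and the observed statistics are located within those null distributions as
empirical percentiles. Each statistic uses its own method's composition
estimate for the null, so the diagnostic remains interpretable when the two
methods disagree.

`case_trait_mean()` reconstructs the mean of a clinical characteristic in
the genetically defined case subgroup from the mixture and non-case trait
means, $\bar x_C = (\bar x_M - (1-\hat p_C)\bar x_N)/\hat p_C$ — undefined
at $\hat p_C = 0$. It inherits every limitation of the Means method;
reconstruction of full trait distributions is out of scope.

## Replication sizes and numerical choices

Default replication is $N_M = 100$, $N_B = 1000$ bootstrap estimates per
interval. The test-suite and example settings use $N_M = 10$, $N_B = 100$
and 20 search runs, which keeps every experiment in the package runnable in
minutes on a single core. Two consequences of the reduced replication are
worth knowing. Extreme adjusted quantiles (the upper BCa level can approach
$1 - 10^{-3}$ when $z_0$ is large, as for the Excess method) are truncated
by a 1000-sample empirical distribution, so intervals come out a few percent
narrower than at full replication; and selecting the *first* ladder rung
whose noisy width estimate drops below the target biases the minimum-size
search low — by a rung or two for Means/EMD/KDE, and by considerably more
for Excess, whose large median-bias correction pushes one interval limit
into the truncated tail. Both effects shrink as $N_M
\cdot N_B$ grows; width checks at full replication place the crossing sizes
at the values the reduced search slightly undershoots.

Other fixed choices: type-7 quantiles everywhere a quantile is taken;
KDE fit tolerances `ftol = ptol = 1e-10` with at most 200 iterations;
clipping of estimates to $[0,1]$ before interval construction; and errors
(rather than silent fallbacks) for degenerate inputs — empty cohorts,
non-finite scores, zero pooled-reference IQR, equal reference means for
Means, identical reference distributions for EMD, an all-zero KDE fit.

## Limitations

Estimates are only as good as the equivalence between mixture and reference
cohorts; selection-enriched references shift every method. The framework is
univariate and two-component by construction. The Excess method is retained
for comparison but underestimates by design, and at AUC $\lesssim 0.75$ its
intervals concentrate away from the truth. Bootstrap intervals at estimates
of exactly 0 or 1 collapse and are flagged rather than repaired.
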