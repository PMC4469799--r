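---
title: "Methods: MR-Egger regression and the two-sample simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MR-Egger regression and the two-sample simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mregger)
```

## The estimators

All estimators consume per-variant summary statistics: the association
γ̂ⱼ (SE included) of variant j with the exposure, and Γ̂ⱼ (SE σ_Yⱼ) with
the outcome, typically estimated in non-overlapping samples. The
per-variant Wald ratio β̂ⱼ = Γ̂ⱼ/γ̂ⱼ estimates the causal effect from
variant j alone; its first-order standard error σ_Yⱼ/|γ̂ⱼ| ignores
uncertainty in γ̂ⱼ, which is the convention throughout this package
(second-order weights are deliberately out of scope).

The **IVW** estimator is the fixed-effect meta-analysis of the ratio
estimates with weights wⱼ = γ̂ⱼ²σ_Yⱼ⁻², computed here as the numerically
identical weighted regression of Γ̂ on γ̂ through the origin with weights
σ_Yⱼ⁻². **MR-Egger** frees the intercept of that regression. Its intercept
is the average direct (pleiotropic) effect of the variants on the outcome;
its slope is consistent for the causal effect under InSIDE — the
distribution of the direct effects αⱼ is independent of the instrument
strengths γⱼ — a strictly weaker requirement than αⱼ = 0 for all j.
Because an allele relabelling (γ̂ⱼ, Γ̂ⱼ) → (−γ̂ⱼ, −Γ̂ⱼ) changes the Egger
intercept but not the IVW slope, `mr_egger()` refuses unoriented data;
`orient()` canonicalizes to γ̂ⱼ ≥ 0, warning on (and not flipping) exact
zeros, which are harmless here but fatal later in any ratio estimate.

Both fits are solved in closed form from the weighted normal equations
rather than through a generic least-squares routine; the test suite
verifies exact agreement with `lm(..., weights = )` as an independent
oracle, and that constraining the Egger intercept to zero reproduces the
IVW fit bit for bit.

### Standard errors: the `se_model` switch

The default, `"regression-output"`, takes SEs and p-values directly from
the weighted-regression output: the residual variance is estimated from
the weighted residual sum of squares on J−1 (IVW) or J−2 (Egger) degrees
of freedom and inference uses the t distribution at those df. Confidence
intervals use the same t quantiles. This is the convention under which the
simulation tables in this package are produced. The alternative `"fixed"`
is the known-variance fixed-effect meta-analysis convention (residual
variance pinned at 1, normal reference); it is provided because later
summary-data MR literature often uses it, and it admits J = 1 for the IVW
point estimate. Point estimates are identical under both models. Whether
historical applied analyses used t or normal quantiles for their intervals
is not always stated; this package fixes t as the default and leaves
`"fixed"` as the explicit alternative rather than guessing per dataset.

### Diagnostics

`cochran_q()` computes Q = Σ wⱼ(β̂ⱼ − β̂_IVW)² with the same first-order
weights and a χ²(J−1) reference — the meta-analytic heterogeneity test,
equivalently an over-identification test. `mean_f_statistic()` averages
(γ̂ⱼ/seⱼ)², the standard weak-instrument indicator.
`maf_corrected_strength()` rescales γ̂ⱼ by the Hardy–Weinberg genotype
standard deviation √(2pⱼ(1−pⱼ)); when outcome associations come from a
common sample this is proportional to σ_Yⱼ⁻¹, so the corrected strengths
are the natural funnel-plot axis while the regressions always use σ_Yⱼ⁻²
weights directly. The funnel plot (`mr_funnel()`) puts the per-variant
ratio estimates on the horizontal axis and strength on the vertical axis —
the meta-analysis convention transplanted to MR, so weak instruments sit
low and directional pleiotropy shows as low-end asymmetry about the IVW
line. Plot functions never recompute statistics: they call the estimator
functions and return the plotted coordinates and line coefficients
invisibly so callers (and tests) can read back exactly what was drawn.

## The generative model

The simulator draws individual-level data from the linear structural
model

* Xᵢ = Σⱼ γⱼGᵢⱼ + Uᵢ + εₓᵢ
* Yᵢ = Σⱼ αⱼGᵢⱼ + βXᵢ + Uᵢ + ε_Yᵢ

with genotypes Gᵢⱼ ~ Binomial(2, pⱼ) under Hardy–Weinberg equilibrium, a
single unit-coefficient confounder U and standard normal errors, then
summarizes each variant by univariate least squares — exposure
associations in one cohort, outcome associations in an independent cohort
of the same size (the two-sample design, implemented as separately derived
random streams from one parent seed via a stable hash, so grids and
replicates are order-independent and bit-reproducible).

The four pleiotropy scenarios are: (a) αⱼ = 0; (b) αⱼ ~ U(−c, c);
(c) αⱼ ~ U(0, c) drawn independently of γ (InSIDE holds);
(d) as (c) plus a per-variant path into the shared confounder with
coefficient 2.5αⱼ, which correlates effective instrument strength with
effective direct effects and so violates InSIDE. The confounder
construction in (d) is implemented as per-variant paths feeding the single
U — one of several readings of "pleiotropy acting through a confounder";
this interpretation is the package's choice and is stated here once.

### Default parameter values

The defaults are the package's fixed study conditions, chosen once:

| parameter | default | rationale |
|---|---|---|
| J (`n_variants`) | 25 | typical mid-size multi-instrument analysis |
| N (`n_per_sample`) | 250 | small-cohort regime where weak-instrument behaviour is visible |
| MAF law | U(0.1, 0.5) | common variants, HWE genotype variance 2p(1−p) |
| γ law | U(0.5, 1.5) × strength | heterogeneous but bounded instrument strengths |
| c (`pleiotropy_scale`) | 0.1 | direct effects an order of magnitude below the γ scale; at β = 0 this makes the scenario (c) IVW bias clearly visible against its SE |
| confounder, εₓ, ε_Y variances | 1 | unit-coefficient confounder convention |

The `strength` multiplier is not a free dial but the calibration handle:
`calibrate_strength(target_f, params)` root-finds the multiplier so the
*expected* mean F statistic — using the analytic approximation
E[Fⱼ] ≈ 1 + Nγⱼ²vⱼ/(var(X) − γⱼ²vⱼ) with vⱼ = 2pⱼ(1−pⱼ), averaged over
the γ and MAF laws by quadrature — hits the target, optionally verified by
a pilot simulation within ±5%. Calibrating once to mean F = 10.4 at
N = 250, J = 25 and holding the multiplier fixed makes mean F scale to
≈ 19.8, 29.2, 38.6 at N = 500, 750, 1000 and fall from ≈ 400 to ≈ 14 as J
grows from 3 to 150 at N = 2000 — F − 1 is linear in N and the per-variant
share of exposure variance shrinks with J. These are properties of the
design, not tuned outcomes.

### What the generator does and does not emulate

It emulates: two-sample summary-data MR with uncorrelated common variants,
HWE genotypes, linear homoscedastic phenotypes, balanced/directional
pleiotropy, and confounder-mediated InSIDE violations. It does **not**
emulate linkage disequilibrium between instruments, winner's-curse
selection of variants in overlapping data, binary outcomes / logistic
reduced forms, non-linear exposure–outcome relationships, or effect
heterogeneity. Passing tests therefore certify the estimators' behaviour
under the stated linear model, not robustness to those real-data
complications.

## The Monte Carlo study layer

`run_cell()` simulates `n_reps` dataset pairs, orients, fits both
estimators, and records mean F, the mean/SD of each slope estimate, mean
SEs, and rejection proportions of the causal null (slope = 0) and of the
no-pleiotropy null (Egger intercept = 0), all by two-sided tests at the
estimators' own t references (df J−1 / J−2) — the same reference the
estimators use, in preference to a normal approximation. Replicates whose
simulation degenerates (e.g. a monomorphic variant) are rerun on a fresh
derived sub-seed, bounded and counted in `n_retried`; at the default MAF
range this is effectively never triggered. `run_grid()` derives each
cell's seed by hashing the master seed with the cell coordinates, so
results are invariant to grid order.

Problem sizes used by the shipped checks, chosen as the package's own
desk-scale defaults: 2000 replicates per verification cell (tolerances are
stated as 3 Monte Carlo SEs at that count), 10 000 replicates for the
headline type-I-error computation in `scripts/acceptance.R` (matching the
reference tables' replicate count), and 10 replicates of N = 10⁵ for the
consistency check that both estimators recover β = 0.05.

The quantities this design reproduces quantitatively are the
calibration-robust ones: type-I error of all three tests under scenarios
(a)–(b), null unbiasedness, and the qualitative contrasts (IVW bias and
rejection inflation under (c), worse under (d), growing with N and J,
Egger SEs roughly twice IVW's). Exact bias magnitudes under (c)–(d)
depend on the α-scale convention; with the defaults above the asymptotic
IVW bias Σγⱼwⱼαⱼ/Σγⱼ²wⱼ (`theoretical_bias()`) is ≈ 0.034 under (c) and
≈ 0.115 under (d), but these magnitudes are sensitive to c and are not
certified by the test suite.

## Numerical choices and degenerate inputs

* Closed-form weighted least squares; the Egger solve guards against a
  degenerate design (no spread in γ̂) explicitly.
* J = 1 admits an IVW point estimate only under `se_model = "fixed"`;
  residual-df conventions make J ≥ 2 (IVW) and J ≥ 3 (Egger) hard
  requirements otherwise.
* Exact zeros in γ̂: tolerated by `orient()` (warning), fatal in
  `ratio_estimates()`, `cochran_q()` and `mr_funnel()` with the offending
  variants named.
* Estimates are kept at full precision internally; rounding happens only
  in `print()` methods.
* All file I/O is locale-independent (C decimal point, tab-delimited
  canonical form, CSV accepted on read).

## Limitations

MR-Egger's robustness is bought with precision: its SEs are typically
about twice IVW's, so power to detect a true causal effect is much lower,
and with weak instruments its slope attenuates toward the null more than
IVW's in the two-sample design. The InSIDE assumption itself fails
whenever pleiotropy routes through a confounder (scenario (d) quantifies
the resulting, still-moderate, bias). No universally reliable SE method is
established for the Egger slope far from the null, so intervals there
deserve caution; bootstrap alternatives are intentionally not provided.
Correlated instruments, multivariable extensions, and individual-level
estimators (TSLS and relatives) are out of scope.
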