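---
title: "Hybrid MFA-PLS: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid MFA-PLS: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxpls)
```

## The estimation model

`fluxpls` works on the pseudo-steady-state balance system `A·v = 0`,
where `A` is the stoichiometric matrix over *balanced* (intracellular)
metabolites and `v` the flux vector in per-cell rate units (e.g.
nmol/(10^6 cells · h)). External species — medium nutrients, secreted
products, biomass sinks — are declared by an `_ext` suffix or an
`@external` header and are excluded from balancing. Conserved moieties
(NADH+NAD, NADPH+NADP, FADH2+FAD) appear as left-null-space vectors of
`A`; each reduces the number of independent balances by one, so the
degrees of freedom are `dof = fluxes − rank(A)`.

With measured fluxes `V_m` (columns `A_m`) in excess of `dof`, the
system is overdetermined. The unweighted estimator is
`V_e = −A_e⁺ · A_m · V_m`. The redundancy matrix
`R = (I − A_e·A_e⁺)·A_m`, reduced to independent rows, annihilates every
measurement vector consistent with some steady state; its residual
`ε = R·V_m` carries all the information about measurement conflict.
Balancing distributes `ε` over the measurements in proportion to their
variances, `V_m_adj = V_m − Σ·Rᵀ(R·Σ·Rᵀ)⁻¹·ε`, and the consistency index
`h = εᵀ(R·Σ·Rᵀ)⁻¹·ε` is compared with the 95% chi-squared quantile at
`nrow(R)` degrees of freedom. `h` equals the minimized weighted
sum-of-squares of the adjustment — the package's test suite verifies this
equivalence against a brute-force null-space minimizer. Estimates are
reported even when the test rejects; the `consistent` flag records the
verdict, since an inconsistent scenario is itself a result.

The variance model defaults to independent errors with
`sd = cv·|v_m|` (cv = 0.16) and an absolute floor of `1e-6` rate units so
zero-valued measurements keep finite weight; per-flux standard deviations
can be supplied in `<id>_sd` columns instead.

## The statistical bridge

The estimated fluxome table (cultures × estimated fluxes) is autoscaled
per flux; the target is centered but not scaled, so coefficients keep the
target's units. PLS1 extracts latent variables sequentially: each weight
vector maximizes covariance between the deflated predictor block and the
current target residual; scores are mutually orthogonal and the
coefficient vector `B = W(PᵀW)⁻¹q` reproduces the fitted values exactly.
At full rank the fit coincides with ordinary least squares, which the
tests use as an oracle. Weight vectors follow a deterministic sign
convention (largest-magnitude element positive), so repeated runs are
bit-identical.

Monte Carlo intervals: the measured-flux error (cv_flux) is propagated
through the estimator's total Jacobian to per-culture covariances of
`V_e`; `n_samples` perturbed tables are drawn (independently per flux by
default) together with a target perturbed at cv_target, each is refit
with the same number of latent variables, and the per-flux standard
deviation over the (n_samples + 1)-sized population gives
`ci = σ̂(B)·t(0.975, dg)`, `dg = population − fluxes`. The strength of
association is `α = |B|/ci`; `α < 1` means the interval contains zero and
the flux is screened out. Two published descriptions of `α` are mutual
reciprocals; this package uses coefficient-over-interval because only
that direction makes "exclude α < 1" mean "interval contains zero"; the
reciprocal is available via `alpha_mode = "ci_over_coef"` with an
identical meaningful flag.

Three sampling modes are shipped. `marginal` (default) perturbs each
estimated flux independently — the cheapest reading of error propagation
through the MFA. `covariance` draws jointly per culture from the
propagated covariance, preserving the correlations the estimator induces.
`re-estimate` perturbs the raw measurements and re-runs the balancing per
draw, capturing the full (still linear) mapping. The default is marginal;
for linear estimators the three agree in distribution up to the
between-flux correlations.

What the α filter can and cannot do: it removes associations that are
*unstable under measurement error*. A chance correlation present in the
original data — likely when cultures are few — is reproduced in every
perturbed replicate and therefore survives the filter. With 15 cultures
this is visible in simulation: occasional null fluxes pass in individual
runs even though, on average, over 80% of them are screened out. More
cultures, not more Monte Carlo samples, is the remedy.

## Clustering diagnostics

Retained fluxes are clustered with Euclidean distances in the
(B, ci) plane — both coordinates share standardized-coefficient units, so
they are used raw by default (`scale_coords` exists). The default linkage
is single, the convention of the statistics environments this analysis
style originated in; average/complete/ward are selectable, and the
cophenetic correlation is linkage-dependent, so reported values name the
linkage. The inconsistency coefficient of a link compares its height with
the mean and standard deviation of link heights in its depth-limited
neighbourhood (default depth 2); a sweep over decreasing thresholds
reports emerging cluster counts and flags the largest discontinuity, but
the final choice of cut is deliberately left to the user. Degenerate
cases are explicit: a two-point tree has an undefined cophenetic
correlation (reported `NA` with a warning, never a fake 1), and a
zero-spread neighbourhood gives inconsistency 0 by convention.

## Latent-variable choice

The fitting cap is 3 latent variables. For validation runs the count is
chosen by maximum total (calibration + validation) explained target
variance — a criterion that knowingly leaks validation information into
selection; the diagnostics table exposes both components so the leak is
visible. Near-ties go to the smaller count: an additional latent variable
must raise the total by more than `tol = 0.02` (2% of variance) to be
kept. This parsimony tolerance is the package's own refinement of
"ties go to the smaller count": with a strict argmax, improvements of
order 10⁻³ from fitting noise would regularly add a useless component,
which contradicts the purpose of capping the latent space.

## The synthetic generator

`generate_network()` builds four steady-state-consistent templates —
a linear chain, a branched hub (the default study network, 10 branches:
one measured uptake, 10 measured branch exits, 10 estimated intracellular
fluxes, one redundancy), a conservation-free cycle with a respiration
branch (whose internal cycle flux is unobservable from exchange rates
unless one cycle edge is measured — the preset measures one), and a
cofactor variant with an NADH/NAD pair contributing exactly one
conservation relation.

`simulate_cultures()` parameterizes each network's flux space by its free
positive fluxes and draws them log-normally (branch flows: median 10,
sdlog 0.5; scale fluxes: sdlog 0.4), so cultures differ mainly in flux
partitioning, the way supplementation experiments do, while all rates stay
positive and the balances hold exactly. The target is
`Σ effect_i · z(driver_i)` plus Gaussian noise at cv_target relative to
each culture's magnitude; measured fluxes get multiplicative Gaussian
noise at cv_flux. Defaults are 15 cultures, drivers with standardized
effects 1.5 and 1, cv_flux 0.16, cv_target 0.22 — the error magnitudes of
the measurement model above — and every file is stamped with its seed.

What the generator does *not* emulate: correlated measurement errors
(shared analytics, plate effects), non-Gaussian or heteroscedastic-beyond-CV
noise, model misspecification (missing reactions), targets spanning
orders of magnitude, or any kinetic/time-course structure. Passing the
recovery tests therefore demonstrates correctness of the machinery under
its own assumptions, not robustness to violations of them.

## Numerical choices

* Rank decisions use singular values thresholded at
  `max(dim)·eps·σ_max`; the pseudo-inverse shares the same threshold so
  solves and rank checks never disagree.
* The number of independent redundancies is computed structurally as
  `rank([A_m A_e]) − rank(A_e)`, not by thresholding singular values of
  `(I − A_e·A_e⁺)A_m`, whose roundoff can straddle any tolerance. The
  reduced `R` uses orthonormal rows, keeping `R·Σ·Rᵀ` well conditioned.
* Rank-deficient `A_e` is an error that names the unidentifiable flux
  combination (a null-space basis), not a silent minimum-norm answer.
* Fractional sensitivities with a near-zero reference estimate are
  reported missing (`NA`), never 0 — a zero would fake insensitivity.
* The scenario divergence metric is
  `100·mean(|V_e′ − V_e| / max(|V_e|, floor))` over shared fluxes. It is
  this package's own definition (configurable via `change_metric`), chosen
  because the scenario API needs *some* scalar summary; no equivalence
  with any published "fluxome variation" figure is claimed.

## Problem sizes

The test suite runs randomized oracle comparisons on networks of up to 10
metabolites, a 5000-replicate calibration check of the chi-squared test's
size, and a 50-seed recovery study (15 cultures × 1000 Monte Carlo
replicates each) on the default branched network; the whole suite
completes in well under two minutes on one core. These sizes were chosen
as the smallest that make the stochastic assertions stable across seeds.

## Known limitations

* Unconstrained least squares only: no irreversibility or bound
  constraints, no isotopomer balancing, no flux-balance objectives.
* The Monte Carlo filter quantifies estimation-error-driven uncertainty
  only (see above); it is not a multiplicity-controlled significance
  test.
* Validation-based latent-variable selection shares the original
  analysis's information leak, flagged in the diagnostics.
* With two meaningful fluxes the clustering stage is a single link and
  its diagnostics are vacuous; with fewer than two it is skipped with a
  notice.
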