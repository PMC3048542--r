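---
title: "Stepwise alcohol-attributable fractions for HIV/AIDS mortality: model, variance propagation, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stepwise alcohol-attributable fractions for HIV/AIDS mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aafhiv)
```

## The causal model and its assumptions

`aafhiv` quantifies one specific causal pathway: alcohol consumption
reduces adherence to antiretroviral therapy, and nonadherence (taking
fewer than 95% of doses) increases HIV/AIDS mortality. Any direct effect
of alcohol on disease progression in untreated people is deliberately
outside the model, as are morbidity outcomes and burden (DALY)
multiplication. Exposure is dichotomous on both axes — current drinker
vs abstainer, adherent vs nonadherent — because the published risk
relations come in that form; a continuous dose–response model of
consumption and adherence would be preferable where data permit, but is
out of scope here.

Three fractions compose the estimate:

* **AdAF**, the fraction of deaths among *treated* patients attributable
  to nonadherence, is the Levin attributable fraction
  $\mathrm{AdAF} = \frac{P_{na}(RR_{na}-1)}{1+P_{na}(RR_{na}-1)}$, where
  $P_{na}$ is the prevalence of nonadherence among people on therapy and
  $RR_{na}$ the mortality risk ratio of nonadherent vs adherent
  patients.
* **NAAAF**, the fraction of nonadherence attributable to current
  drinking, has the same form in $(P_{drink}, RR_{drink})$.
* **PDT**, the share of *all* HIV/AIDS deaths that occur among people on
  therapy, is not directly observed and is reconstructed from treatment
  coverage $P_{treat}$ and the mortality hazard ratio of the untreated:
  $\mathrm{PDT} = \frac{P_{treat}}{P_{treat} + HR_{nontreat}(1-P_{treat})}$.

Their product, $\mathrm{AAF} = \mathrm{AdAF}\cdot\mathrm{NAAAF}\cdot
\mathrm{PDT}$, is the fraction of all HIV/AIDS deaths attributable to
alcohol through nonadherence. The chain requires that the risk
parameters be transportable across strata: $P_{na}$, $RR_{na}$,
$RR_{drink}$ and $HR_{nontreat}$ are treated as universal, so within a
region only $P_{drink}$ varies by sex and age, and AdAF and PDT are
constant across a region's six strata. The prevalence of nonadherence
*among drinkers*, needed to convert an odds ratio of nonadherence into a
risk ratio, is not published; the whole-population nonadherence
prevalence is used as a conservative stand-in (`odds_to_risk()` takes
any proportion the user prefers).

We compute AdAF in the algebraically simplified form
$P(RR-1)/(1+P(RR-1))$ rather than the equivalent complement form
$(P_{adher}+P_{na}RR_{na}-1)/(P_{adher}+P_{na}RR_{na})$: the two are
identical (a test asserts equality to $10^{-12}$ relative on random
inputs), but the simplified form avoids the cancellation $x - 1$ near
$x = 1$. The complement $P_{adher} = 1 - P_{na}$ is treated as
deterministic given $P_{na}$; no separate variance is attached to it.

## Input conventions

All proportions are stored as fractions in $[0,1]$; input files declare
their unit explicitly (`unit: fraction` or `unit: percent`), which
removes the percent-vs-fraction ambiguity that plagues transcribed
tables. Published ratio confidence intervals are assumed symmetric on
the **log** scale — the scale on which regression-based RR/OR/HR
estimates are produced — so the CI is converted first to
$\mathrm{Var}[\ln X] = \left(\frac{\ln U - \ln L}{2z}\right)^2$ and then
to the linear scale via the first-order relation
$\mathrm{Var}[X] \approx X^2 \mathrm{Var}[\ln X]$. Proportion CIs are
assumed symmetric on the linear scale. When an interval is asymmetric
around the point estimate on its assumed scale, the half-width is taken
as half the full width; this is a documented convention, not a claim
about the underlying sampling distribution, and it makes results
reproducible from `(value, lower, upper)` alone. The interval multiplier
defaults to $z = 1.959964$ (the 97.5% normal quantile) and is
configurable everywhere.

Ratio inversion (`invert_ratio()`) maps $(X, L, U)$ to
$(1/X, 1/U, 1/L)$ and leaves $\mathrm{Var}[\ln X]$ unchanged — inversion
is exact on the log scale — so the published treated-vs-untreated rate
ratio 0.38 (0.28, 0.52) becomes the no-treatment hazard ratio 2.63
(1.92, 3.57) used by PDT.

Two bundled-data decisions deserve flagging. First, the bundled
$RR_{drink} = 1.82$ (1.63, 2.04) is taken as published. It is *not*
reproduced by applying the odds-to-risk conversion to the published
adherence odds ratio 0.604 (inverting and converting gives $\approx
1.31$; plain inversion gives $\approx 1.66$); the value's derivation is
not recoverable, so it is treated as an opaque input while
`odds_to_risk()` remains available for user-supplied odds ratios.
Second, the drinker-prevalence table publishes no uncertainty, so those
cells carry variance 0 by default — the only faithful choice — although
the schema accepts optional bounds; NAAAF uncertainty is therefore
driven entirely by $RR_{drink}$ for the bundled data, and stratum
variances would grow if survey sampling error were supplied.

Regional aggregation of country-level coverage goes through
`weighted_coverage()` with *explicit* user weights (population sizes);
the bundled regional coverage values are shipped as given because the
population weights that produced them are not recoverable.

## Variance propagation

For independent $X, Y$ the variance of the product is exactly
$\mathrm{Var}[XY] = \mathrm{Var}[X]\mathrm{Var}[Y] +
\mathbb{E}[Y]^2\mathrm{Var}[X] + \mathbb{E}[X]^2\mathrm{Var}[Y]$
(`product_variance()`). Each Levin-type fraction then gets the
delta-method variance
$\mathrm{Var}[\mathrm{AF}] \approx
\frac{\mathrm{Var}[P \cdot RR]}{(1+P(RR-1))^4}$; PDT gets the
two-variable first-order expansion
$\mathrm{Var}[\mathrm{PDT}] \approx D_{P_{treat}}^2\mathrm{Var}[P_{treat}]
+ D_{HR}^2\mathrm{Var}[HR_{nontreat}]$ with
$D_{P_{treat}} = HR/(P_{treat}+HR(1-P_{treat}))^2$ and
$D_{HR} = P_{treat}(1-P_{treat})/(P_{treat}+HR(1-P_{treat}))^2$ (the
partials enter squared, so only their magnitudes matter); and the final
AAF variance applies the product identity twice, to
$\mathrm{AdAF}\cdot\mathrm{NAAAF}$ and then to that product with PDT.
Independence of all inputs is assumed throughout — they come from
different studies — and correlated-parameter sampling is deliberately
not offered.

Uncertainty intervals are Wald-type, $\hat\theta \pm z\sqrt{\mathrm{Var}}$,
and **not truncated** to $[0,1]$: a lower bound below zero is the
signal that a stratum's detrimental effect is not statistically
significant (this occurs in the bundled North Africa/Middle East
region), and truncation would hide exactly that.

All of this is first-order machinery: it is accurate while the
coefficient of variation of each input is small, and degrades as input
variances grow — a caveat that applies equally to the point estimate
itself (the mean of a nonlinear function is not the function of the
means). The package makes the caveat measurable rather than rhetorical,
via the Monte Carlo oracle.

## The Monte Carlo oracle

`mc_aaf()` samples every input independently and pushes each draw
through the deterministic chain. Distributions must be *chosen* — no
convention fixes them — and the choices are declared rather than
inferred: ratios are log-normal with log-mean $\ln(\text{value})$ and
log-SD $\sqrt{\mathrm{Var}[\ln X]}$ (matching the log-symmetric CI
assumption); proportions are, by default, normal on the linear scale
truncated to $[0,1]$ and renormalised (matching the linear-symmetric CI
assumption), with a moment-matched beta (`proportion_model =
"beta_matched"`) available for sensitivity analysis. Zero-variance
inputs become constant columns. The seed is mandatory in the library
API; the command line defaults to `--seed 20210214`. Default draws:
200,000, a size at which the empirical variance of the bundled strata is
stable to well under 1% while a full 30-stratum sweep runs in seconds.

`mc_compare()` reports the relative difference between the analytic and
empirical variances and between the Wald width and the 2.5%–97.5%
percentile width (percentile intervals are reported precisely because
they expose asymmetry the delta method cannot represent); a comparison
passes when both are within `rel_tol` (default 10%). For the bundled
inputs all 30 strata agree to within ~2% on variance and ~1% on width,
and the test suite also verifies the expected degradation: scaling all
input variances up makes the discrepancy grow, and shrinking them toward
zero drives the empirical mean onto the analytic point estimate.

## Numerical and degenerate-input choices

* `P_treat = 0` yields PDT 0 with a warning (no treated deaths, so the
  mediated AAF is zero), rather than an error.
* `P_drink = 0` or a null ratio gives a zero fraction whose variance
  retains the surviving delta-method terms; with *all* input variances
  zero, every output variance is exactly zero and intervals collapse to
  the point.
* Displayed percentages are rounded to two decimals in formatted output
  only; stored and written values keep full double precision (results
  CSV/JSON round-trip bit-exactly, using 17 significant digits).
* The truncated-normal sampler uses inverse-CDF sampling between the
  CDF values at 0 and 1, i.e. the renormalised truncated distribution;
  for the bundled inputs the truncation mass is negligible, so the
  sampled mean and variance remain effectively the moment-matched ones.

## Scope of the bundled data, and what passing tests show

The bundled tables describe the five GBD regions of Africa in 2005 at
the region × sex × age-band level, with drinker prevalence treated as
exact. They are faithful transcriptions of published regional summaries,
not raw data: real country-level inputs carry survey design effects,
correlated coverage estimates, and drinker-prevalence uncertainty that
the bundled set does not represent. Passing the validation sweep
demonstrates that the analytic variance machinery matches simulation
*under the stated distributional assumptions and published input
uncertainties* — it does not validate the input estimates themselves,
nor the transportability assumptions above.

The test problem sizes are chosen to keep the full suite fast while
leaving Monte Carlo error far below the tolerances tested: 200,000
draws per stratum for the validation sweep, $10^6$ draws for the
product-variance identity checks, 100 random inputs for algebraic
equivalences.

## Design choices in the interface

The command line is a single dispatcher (`aaf_cli()`) with `compute`,
`validate-mc` and `show-data` subcommands, configured purely by flags;
a config-file layer was considered and dropped since the flag set is
small and every run's resolved configuration is already echoed into its
output artifacts (JSON outputs embed it; CSV runs log it), which is
what reproducibility actually requires. The forest-style `plot_aaf()`
is a display convenience and carries no normative weight.

## Known limitations

* Single mediation pathway, dichotomous exposure and adherence; no
  effect of alcohol in untreated people; conservative by construction.
* First-order variance approximation; accuracy degrades for large input
  CVs (quantified, not merely asserted, via `validate_mc()`).
* Independence of inputs is assumed, as they originate from separate
  studies; no correlated sampling.
* $RR_{drink}$ is an opaque published input (see above); analyses that
  instead start from an adherence odds ratio should use
  `invert_ratio()` + `odds_to_risk()` and will obtain smaller NAAAFs.
* The bundled drinker prevalences carry no uncertainty, so bundled AAF
  intervals understate total uncertainty to the extent that survey
  error matters.
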