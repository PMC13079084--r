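---
title: "Apportioning lake DIC among peat, modern carbon and the atmosphere"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Apportioning lake DIC among peat, modern carbon and the atmosphere}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peatmix)
```

## The problem

Humic lakes embedded in peatland complexes are strong CO2 sources. Whether
the evaded carbon is modern (recently fixed organic matter respired in the
water column) or ancient (peat-derived CO2 transported into the lake) cannot
be decided from concentrations alone, but the two origins carry distinct
isotopic fingerprints: radiocarbon activity (F14C, fraction modern; ancient
peat is strongly depleted) and stable carbon isotope ratios (delta 13C,
permil VPDB; C3-plant-derived carbon near -28 permil vs. dissolved
atmospheric CO2 near -9.8 permil). `peatmix` implements the full inference
chain that turns replicate isotopic measurements of a dissolved inorganic
carbon (DIC) pool into fractional source contributions with uncertainties,
and scales the result to an annual carbon mass.

## The mixing model

A mixture of $k$ sources with $k-1$ conservative tracers is exactly
identified. Writing $S_{tj}$ for tracer $t$ of source $j$, $m_t$ for the
mixture, and $f_j$ for the fractional contributions:

$$\begin{bmatrix} S \\ \mathbf{1}^\top \end{bmatrix} f =
  \begin{bmatrix} m \\ 1 \end{bmatrix},$$

the last row being mass balance. `solve_exact()` returns the unique
solution without clamping; infeasibility (entries outside $[0,1]$) is
meaningful and is handled by the sampler, not the solver.

Two conceptual gas-exchange scenarios bracket reality:

* **Equilibration** — DIC exchanges freely with the atmosphere, so it is a
  three-way mixture of *peat*, *modern* organic carbon and *atmosphere*,
  constrained by both delta 13C and F14C.
* **Outgassing** — CO2 evasion is so vigorous that atmospheric
  equilibration is negligible; DIC is a two-way peat/modern mixture. Since
  kinetic fractionation during evasion perturbs delta 13C, this model uses
  F14C alone, which is by construction fractionation-corrected.

`run_monte_carlo()` wraps the exact solver: in each of `n_iter` iterations
(default 100,000) every end-member tracer *and* every mixture tracer is
drawn independently from a normal distribution with its stated mean and
standard deviation, the system is solved, and the draw is retained iff all
fractions lie in the closed interval $[0, 1]$. Posterior means and sample
standard deviations are computed over retained draws only.

When the two models agree within uncertainty
(`consistency_check()`: $|m_a - m_b| \le k\sqrt{s_a^2 + s_b^2}$, default
$k = 1$), they are pooled by inverse-variance weighting
(`combine_inverse_variance()`): $w_x = 1/s_x^2$,
$\bar f = \sum w_x m_x / \sum w_x$.

## Parameters that matter

| parameter | units | default | rationale |
|---|---|---|---|
| `n_iter` | draws | 100,000 | resolves posterior s.d. to ~0.2% relative |
| rejection interval | — | closed $[0,1]$ | boundary draws are physical (pure-source mixtures) |
| `k` (consistency) | combined s.d. | 1 | agreement within one joint standard deviation |
| `sd_mode` | — | `"analytic"` | see *Numerical choices* |
| Libby mean life | yr | 8033 | fixed by the radiocarbon reporting convention |
| molar mass of C | g/mol | 12.011 | flux counted as CO2-C |
| year length | d | 365 | equatorial lakes, one-significant-figure budgets |

## Radiocarbon conventions

Conventional age is $-8033\ln F$ (yr BP). Uncertainty is propagated through
the log transform exactly, giving asymmetric offsets
($\mathrm{err}^+ = \mathrm{age}(F-\sigma)-\mathrm{age}(F) \ge
\mathrm{err}^- $) for symmetric $\sigma$. Ages are presented rounded to the
nearest year, but the unrounded value is available (`round = FALSE`) and is
what round-trips with `age_to_fm()` to better than 1e-9 relative. F14C > 1
(post-bomb carbon) yields a negative age, returned as-is with a
`post_bomb` flag. Printed ages in the literature are often computed from
unrounded mean F14C values: re-deriving an age from a two-decimal F14C can
therefore disagree with the printed age by 1-2% (and the 1-sigma *offsets*
by up to ~3%), which is rounding propagation, not a computational
discrepancy. Calendar calibration is out of scope.

Ages for a pool are computed from the averaged F14C, not averaged over
per-sample ages; both orderings are possible with the exposed primitives,
but the averaged-F14C route is the default documented behaviour.

## Miller-Tans regression

For a pool whose concentration varies because a single source is added to a
background, mass balance gives $C\delta = \delta_s C + C_{bg}(\delta_{bg} -
\delta_s)$, so the OLS slope of $C\delta$ on $C$ estimates the source
signature $\delta_s$ with the background absorbed into the intercept (which
is therefore retained). OLS is the default flavour and is recorded in the
fit object; the slope standard error is reported as 1 s.e. The slope and
$R^2$ are invariant to rescaling concentration units.

## Flux upscaling

`annual_carbon_mass()` converts an areal CO2 evasion flux (mmol m^-2 d^-1)
over a lake area (km^2), attributed to a source fraction, into Gg C yr^-1;
the factor decomposition is returned for audit and the arithmetic is
exactly linear in each input. `residence_time()` is volume over outflow.

## What the synthetic generator emulates — and what it does not

`generate_mixture_table()` simulates the statistical world the Monte Carlo
assumes: normally distributed end-member tracers, a mixture formed as the
fraction-weighted blend of *freshly drawn* end-member values per replicate
(not of the end-member means — matching the sampler's generative
assumption), plus independent replicate measurement noise. The shipped
`default_scenario()` uses peat (-28 ± 1 permil, F14C 0.35 ± 0.15 — the wide
spread stands in for peat-depth heterogeneity), modern OC (-29 ± 1,
1.02 ± 0.02), dissolved atmospheric CO2 (-9.80 ± 0.10, 1.01 ± 0.01), true
fractions 0.40/0.50/0.10, noise 0.5 permil and 0.01, and 10 replicates per
pool (a realistic campaign size). These values are chosen to straddle
plausible humic-lake observations; they are synthetic, not any study's
data.

The generator does **not** emulate: hydrological transport or residence
dynamics, depth-resolved peat profiles, seasonality, tracer covariance
within a source, or measurement physics (AMS blanks, IRMS drift). A green
recovery test therefore establishes that the inference is correct *when
its distributional assumptions hold*, not that those assumptions hold in
any particular lake.

`recovery_experiment()` closes the loop: simulate, summarize pools
empirically, run both models, combine, and score bias, RMSE and the
fraction of datasets whose mean ± 2 s.d. covers the truth.

## Numerical choices

* **Shared kernels.** The vectorized Monte Carlo and the scalar exact
  solver use the same elementwise Cramer-rule kernels for the 2- and
  3-source systems, so a degenerate run (all s.d.s zero) equals
  `solve_exact()` *bit for bit*, not merely to tolerance.
* **No truncation on the inference side.** Tracer draws may transiently be
  non-physical (F14C < 0); feasibility is enforced solely by the $[0,1]$
  rejection on fractions — the single filter the method defines. Draws
  yielding a singular system are counted as rejected. The *generator*, by
  contrast, truncates F14C at 0, because physical measurements cannot be
  negative.
* **Closed rejection interval.** "Between 0 and 1" includes the
  boundaries; a draw landing exactly on a vertex is a physically valid
  pure-source solution.
* **Degenerate combination.** Inverse-variance weights are undefined at
  s.d. 0; if *both* models are exact and agree to 1e-12 the combination
  returns their common mean with s.d. 0 (the limit of the weighting);
  any other zero-s.d. case is an error. Coverage comparisons carry 1e-9
  absolute slack so the exact world is not failed on float residue.
* **Combined s.d. modes.** `"analytic"` is $\sqrt{1/\sum w}$ — the
  precision of the weighted mean, appropriate when the models are two
  estimators of one quantity. `"pooled"` is the s.d. of the
  inverse-variance-weighted union of the two posterior sample sets about
  the combined mean, computed deterministically (each sample weighted
  $w_x/n_x$, the expectation of weight-resampling); it preserves
  non-normal posterior shape and is typically wider. The headline-style
  "± n%" of a combined estimate does not pin down which was meant, so
  both are exposed and the mode is recorded in the result.
* **Seeds.** Every stochastic entry point takes an explicit seed and
  records it. Pipelines derive: table seed $s$, equilibration $s+1$,
  outgassing $s+2$, so `recovery_experiment()` datasets are exactly
  reproducible through `run_full_analysis()`.
* **Singularity.** `solve_exact()` refuses systems with reciprocal
  condition below 1e-12, naming the collinear end members.

## Known limitations

* End-member definitions are inputs; the package cannot validate that a
  user's peat or modern signature is representative of their system.
* The two conceptual models share the same mixture data, so the combined
  estimate's analytic s.d. treats them as independent, which they are not;
  the consistency check and the pooled mode partially mitigate this.
* A 2-s.e. interval has nominal coverage below 95% at small n (it is a
  t-interval: $P(|t_{18}| \le 2) \approx 93.9\%$ at n = 20), and the
  Miller-Tans product regression is mildly heteroscedastic (noise on
  $\delta$ scales with $C$ in $C\delta$), lowering empirical coverage
  slightly further. Validation thresholds that assume Gaussian 95%
  behaviour at small n will sit just below their target; the acceptance
  suite documents exactly this.
* DIC is treated as a single CO2-dominated pool; carbonate speciation,
  hydrological transport and gas-transfer-velocity modelling are out of
  scope.
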