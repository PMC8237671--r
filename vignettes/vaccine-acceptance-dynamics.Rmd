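---
title: "Modelling vaccine acceptance under voluntary and enforced policies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling vaccine acceptance under voluntary and enforced policies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaxpref)
```

## The problem

Vaccination campaigns depend on voluntary citizen compliance even when
vaccination is legally required. Two socio-psychological forces make the
share of citizens who *prefer* being vaccinated endogenous to the policy
itself:

* **Conformism** — people adopt a novel practice conditionally on how many
  others have already adopted it, so the preference share rises with the
  fraction already vaccinated.
* **Crowding out** — enforcement can displace intrinsic and social
  motivation (reactance against restricted freedom, moral disengagement,
  the distrust signalled by a mandate), so at any coverage level fewer
  people prefer vaccination under a mandate than under a recommendation,
  and the conformist signal of an observed vaccination is weaker because it
  may have been coerced.

`vaxpref` implements a discrete-time model of these forces together with a
two-wave panel-survey analysis pipeline and a synthetic panel generator, so
the whole chain — micro survey evidence, regime-specific adoption curves,
coverage dynamics, policy classification — can be exercised and tested
end-to-end without access to any proprietary survey data.

## The model

An **adoption curve** $p_r(f)$ gives the share of the population preferring
being vaccinated when a fraction $f$ was vaccinated by the end of the
previous period, under regime $r \in \{v, e\}$ (voluntary, enforced). The
S-shaped `gaussian_threshold` family arises from normally distributed
conformity thresholds, truncated to $[0,1]$ and renormalized so the anchors
are exact:

$$p(f) = p_0 + (p_1 - p_0)\,
  \frac{\Phi\!\left(\tfrac{f-\mu}{\sigma}\right) - \Phi\!\left(\tfrac{-\mu}{\sigma}\right)}
       {\Phi\!\left(\tfrac{1-\mu}{\sigma}\right) - \Phi\!\left(\tfrac{-\mu}{\sigma}\right)},$$

with $p(0)=p_0$ (the share preferring vaccination before anyone is
vaccinated) and $p(1)=p_1$. A `linear` family (uniform thresholds) is also
provided. Crowding out is encoded as a regime pair in which the enforced
curve lies weakly below the voluntary one and has the weakly lower
*maximum* slope; both conditions are verified on a dense grid at
construction. We interpret "less steep" as lower maximum slope rather than
a uniformly lower derivative, since two anchored S-curves with different
spreads necessarily cross in derivative somewhere.

Because vaccination is irreversible, voluntary coverage follows the ratchet
map $f_{t+1} = \max(f_t, p(f_t))$. Its rest points are the intersections of
the curve with the 45° line; `fixed_points()` locates them by a sign-change
scan (4,097-point grid) plus bisection, and classifies each as attracting
(`stable_low` / `stable_high`) or as a **tipping point** where the curve
crosses the line from below — just above it conformist growth resumes
unaided, just below it coverage stalls.

Under an enforced plan the state vaccinates unwilling citizens only when
voluntary uptake has stalled below the target $f_T$, up to `capacity` per
period, and only as far as necessary: to the lowest tipping point whose
basin reaches the target, or to the target itself when no such tipping
point exists. The **enforcement burden** is the total mass vaccinated
against their preference, $f^{e,\min} - f^{e,L*}$ in the tipping case.

## Numerical choices

* Fixed-point scan grid 4,097 points, classification tolerance `tol = 1e-8`;
  bisection itself refines each bracket essentially to machine precision
  (~50 halvings per root, negligible cost), which keeps the closed-form
  linear-curve check ($f^* = p_0/(1-s)$) accurate to below 1e-9 and the
  enforcement-conservation identity accurate to a few nano-units of
  coverage.
* A *touching* (tangent) intersection is conservatively classified as a
  tipping point: it is not a safely attracting state for policy purposes.
* A curve with $|p(f)-f| < tol$ on more than half the grid (identity-like)
  has no isolated equilibria and raises a `degenerate-continuum` error.
* Enforcement pushes to the located tipping point nudged upward in steps of
  `tol/4` until the curve is strictly above the line, so growth genuinely
  resumes; the overshoot is bounded by a few times `tol`.
* Two subtleties in convergence detection: a state freshly nudged past a
  tipping point grows more slowly than `tol` at first but is escaping, so
  the simulator declares convergence (and re-triggers enforcement) only
  when the willing growth is also non-increasing; and because the stall
  trigger fires within `tol` of a rest point — slightly below it — doses
  administered between the trigger level and the rest point are counted as
  willing, not enforced.
* Coverage and preference shares are fractions in $[0,1]$ everywhere in
  code; percentages appear only in human-readable reports.

The default illustrative curve pair mirrors the published diagram's stated
gaps (intercepts 5 points apart, endpoints 15 points apart); the survey
itself implies a larger vertical distance of about 25 points
(`gap_from_survey_shares(2/3, 0.42)` = 24.7), which the synthetic panel's
default threshold configuration uses.

## The synthetic panel generator

The generator is a latent-variable ordered-response model — the minimal
structure that can carry Likert marginals, cross-sectional covariate
effects, and within-person change at the same time. For respondent $i$,
regime $r$, wave $w$ the latent support index is

$$y_{irw} = \beta^{T}_r T_{iw} + \beta^{S}_r S_i + \beta^{A}_r A_i +
\beta^{F}_r F_i + \beta^{E}_r E_i + \beta^{Ef}_r \mathit{Eff}_i +
\beta^{Fr}_r \mathit{Free}_i + \beta^{C}_r C_i + u_i -
\mathbb{1}[r=e]\,\kappa + \varepsilon_{irw},$$

cut at four ascending regime-and-wave-specific cutpoints into the observed
0–4 Likert level. Trust has a stable component $S_i$ and wave shocks;
the *current* standardized trust level $T_{iw}$ carries the causal loading
while $S_i$ also enters directly as a time-invariant confounder. This
reproduces the key identification pattern of two-wave panels: cross-section
trust coefficients (confounded, default implied value ≈ 0.35 SD for the
enforced item) exceed the first-difference estimates (causal, ≈ 0.10 SD
before discretization attenuation) by more than a factor of three.

Stated-world defaults, chosen once:

* Effect loadings (per SD): trust 0.10/0.05 (enforced/voluntary, causal) +
  0.25/0.15 (stable confound); altruism 0 / +0.15; female −0.15 / 0;
  East German origin +0.10 / −0.10; effectiveness belief +0.30 / +0.15;
  freedom-restriction −0.25 / 0; pandemic severity +0.15 / +0.10. These
  reproduce the published sign pattern and relative magnitudes.
* Crowding-out shift $\kappa = 0.4$ latent SD; individual propensity SD
  0.8; item-wave noise SD 0.6; trust shock N(−0.05, 0.6²) on the latent
  scale (average trust stays essentially flat, as observed); trust
  composite mapped to the 1–6.6 scale as $4.8 + 0.9\,T$ (clipped).
* Respondent shares: 47% female (the published sample share); 30% born in
  East Germany (the survey used double quota for the East; the exact share
  is not printed, so 0.30 is a stated-world choice).
* Effectiveness and freedom measured in wave 2 only, as in the survey.
* Default cutpoints are frozen output of `calibrate_to_marginals()` against
  the published enforced-item cumulative distributions (44/56/71/77% in
  wave 1, 28/42/58/70% in wave 2) and voluntary targets with a 2/3
  supporter share in both waves (only the two-thirds figure is published;
  the remaining voluntary levels are a choice).

Each respondent also carries conformity thresholds drawn from the inverse
of the configured adoption curves with a *shared* uniform draw across
regimes, so the enforced threshold never lies below the voluntary one and
`implied_adoption_curve()` recovers the configured curves exactly in
expectation — the micro-to-macro link.

Calibration itself exploits that the Likert response is a deterministic cut
of the latent index: the matching cutpoints are latent quantiles at the
target cumulative shares, computed from one large deterministic draw
(n = 200,000, fixed calibration seed) and verified against that draw; a
refinement loop and an iteration cap guard the degenerate cases, where
cutpoints are clamped to ±8 latent SD with a warning flag.

**What a green test does not establish.** The generator emulates marginal
distributions, effect signs and magnitudes, and within-person dynamics — it
does not emulate quota sampling, item-level trust structure, response-time
exclusions, attrition, or any real dependence between the conformity
thresholds and the survey covariates (thresholds are drawn independently of
the latent support index). Agreement of the pipeline with generated data
therefore validates the *computations*, not the substantive survey
findings.

## The analysis pipeline

`likert_summary()` (means, normal-approximation 95% CIs, cumulative
shares), `transition_stats()` (supporter = level 3–4, opposition = 0–1),
`standardized_ols()` (z-scoring on the estimation sample after list-wise
exclusion; QR least squares; classical homoskedastic CIs by default with an
HC1 option, since the source analysis does not state a covariance
estimator), and `change_regression()` (standardized first differences,
removing time-invariant confounders). `trust_attribution()` isolates the
reconstructed attribution arithmetic
$(\beta_{raw} \times \Delta T)/|\overline{\Delta y}|$ — the published 37%
figure corresponds to $\beta_{raw}=0.1$, a one-point drop, and an observed
mean change of −0.27 — because the exact formula used in the original
supplement is not reproduced in the available text; it is documented as an
interpretation and kept in one operation.

## Scenario pipeline

```{r, eval = FALSE}
cfg <- system.file("extdata", "scenario_pessimistic.yaml", package = "vaxpref")
rep <- cmd_scenario(cfg, out_dir = "results")
rep$classification    # "pessimistic"
rep$enforcement_burden
```

The CLI layer (`vaxpref_main()`, wrapped by `inst/cli/vaxpref.R`) exposes
`scenario`, `generate`, `analyze` and `calibrate` subcommands, YAML
configuration in, JSON/CSV out, with a provenance record (config echo,
seed, package version) written beside every output.

## Known limitations

* The dynamic model has no epidemiological layer: the target $f_T$ is an
  exogenous policy input, and feedback such as distrust cascades under
  sustained enforcement is discussed in the literature but not modelled.
* Preferences respond to *total* coverage and the regime only; the split of
  coverage into willing and enforced doses affects preferences solely
  through the flatter enforced curve.
* Ordinal outcomes are analysed with linear OLS (as in the source
  analysis), not ordered-response models.
* Curve estimation from historical uptake data is out of scope; curves are
  configured, not fitted.
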