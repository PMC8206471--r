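---
title: "Probing work-environment by stress-reactivity interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probing work-environment by stress-reactivity interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The scientific question

Occupational-health studies in the job demands-control-support (JDCS)
tradition ask whether a *moderator* — here hair cortisol content (HCC,
pg/mg in the proximal 1-cm segment), a biomarker of roughly one month of
HPA-axis activity and hence of individual stress reactivity — changes how
strongly work-environment scales (job control, psychological demands,
supervisor and coworker support, from the Job Content Questionnaire)
predict burnout outcomes (emotional exhaustion, depersonalization,
professional efficiency, from the Maslach Burnout Inventory).  Three
theoretical models make distinct predictions about *where* along the
environment axis high- and low-reactivity groups differ:

* **diathesis stress** — the susceptible group does worse only under
  adversity; no group difference in supportive environments;
* **differential susceptibility** — the susceptible group does worse under
  adversity *and* better under support ("for better and for worse");
* **vantage sensitivity** — the sensitive group does better only under
  support; no difference under adversity.

`rosmod` implements the full decision pipeline: scale scoring, data
preparation, moderated hierarchical regression, region-of-significance
(RoS) probing, the PoI/PA descriptive indices, and the classification
rules — plus a synthetic-cohort generator so every stage is testable
without access to the original (undeposited) data.

## The model

For one environment scale $E$, log moderator $M$ and outcome $Y$, the
final (step-4) model on centered predictors is

$$Y = b_0 + \mathbf{c}'\gamma + b_E\,E_c + b_M\,M_c + b_{EM}\,E_c M_c + \varepsilon,$$

with $\mathbf{c}$ the demographic covariates (six department dummies
against the "other" reference, a shift-pattern indicator, tenure in
years).  Four OLS steps enter (1) demographics, (2) $E_c$, (3) $M_c$,
(4) $E_cM_c$; each increment is tested with
$F = (\Delta R^2/df_1)\,/\,((1-R^2_{\text{step}})/df_2)$,
$df_2 = n - p_{\text{step}} - 1$.  JCQ exposures enter as their
unit-interval standard scores ($(x-24)/72$ for job control,
$(x-12)/36$ for psychological demands) so coefficients land on the
published scale.

Probing works off the final model's coefficient triple and its covariance
block:

* **simple slopes** at $M \pm 1\,SD$: $b_E + b_{EM}z$, with
  $SE^2 = v_{EE} + z^2 v_{II} + 2z\,c_{EI}$;
* **crossover**: $x_c = -b_M/b_{EM}$, reported in environment-SD units;
* **RoS** (Johnson-Neyman on the environment axis): the high-vs-low
  moderator difference is $2\,SD_M(b_M + b_{EM}x)$; its $t$-ratio is
  invariant to the $2\,SD_M$ factor, so the significance boundary solves
  $(b_M + b_{EM}x)^2 = t_{crit}^2\,(v_{MM} + 2x\,c_{MI} + x^2 v_{II})$,
  a quadratic whose real roots are converted to SD units.  The default
  evaluation window is $[-2, +2]$ SD.
* **PoI** — the share of the area between the two simple-slope lines lying
  on the side of the crossover where the susceptible group is better off;
  for straight lines this is $d_v^2/(d_v^2+d_r^2)$ with $d_v, d_r$ the
  distances from the (clamped) crossover to the window edges.  **PA** —
  the empirical fraction of subjects on the vantage side.

## Classification rules

An interaction with step-4 $p \ge \alpha$ is `none`.  Otherwise the label
follows RoS sidedness at the window ends, with supportive/adverse ends
resolved from the declared environment polarity (psychological demands is
adverse-coded; control and the supports are supportive-coded; professional
efficiency is higher-better, exhaustion and depersonalization
higher-worse):

* significant at both ends **and** the group ordering reverses across the
  crossover → differential susceptibility;
* significant only toward the supportive end → vantage sensitivity;
* significant only toward the adverse end → diathesis stress;
* otherwise none.  Both-ends significance *without* a reversal (one group
  uniformly ahead, the gap merely growing) fits none of the three
  definitions and is labelled none.

PoI and PA are reported as descriptive diagnostics, not gates: published
analyses classify differential susceptibility even with PoI outside
Roisman's 0.40-0.60 band, so RoS sidedness is evidently the operative
criterion.  An optional `poi_gate` restores the stricter convention.  The
susceptible group is the moderator level with the larger absolute simple
slope (the group whose outcomes span the wider range across the window).
A RoS bound landing exactly on a window edge counts as significant at that
end.

## The synthetic cohort

The generator states one fixed world, chosen once from the published
cohort description, and the tests interrogate that world:

* $n = 341$ female hospital nurses; seven departments at proportions
  (emergency .3255, ICU .1525, other .1584, rehabilitation .1202,
  psychology .0880, radiotherapy .0792, EICU .0762); two shift patterns
  (.9003/.0997); tenure drawn from the published three-band mix
  (48.99% under 5 years, 32.26% 5-15, 18.77% over 15), uniform within
  band with caps 0.5-30 years (bands are what was published; the uniform
  fill and caps are our choice of a realistic continuous version).
* the seven scales and the log10 moderator form a multivariate normal
  matched to the published means, SDs and 8x8 correlation matrix through
  the symmetric square root of the correlation matrix (the matrix is
  positive definite as printed; smallest eigenvalue 0.297);
* HCC is lognormal: log10 median fixed by the published median 3.3 pg/mg;
  `hcc_logsd = 0.334` is the spread consistent with the published
  simple-slope separations through
  $\text{slope}_{high} - \text{slope}_{low} = 2\,b_{EM}\,SD_M$ across all
  three probed interactions.  This reproduces the qualitative strong right
  skew of raw HCC (sample skewness ~2-3), though not the published
  extreme 5.6 — a single lognormal cannot match median, range and
  published slope separation simultaneously, and the moderator enters the
  analysis only through its log;
* a planted regime regenerates one outcome from
  $b_0 + b_E E_c + b_M M_c + b_{EM} E_c M_c + \mathcal{N}(0, 1.2^2)$.
  Effect sizes are stated in residual-SD units: the environment main
  effect 0.30 per environment SD, the interaction 0.15 per moderator SD
  (the spec's "strongly planted" floor).  The crossover is placed at 0 SD
  (differential susceptibility), at the supportive edge $+2\,SD \times$
  polarity (diathesis stress: zero group difference under maximal
  support), or at the adverse edge (vantage sensitivity) — so the planted
  difference is *exactly* zero at the relevant window edge.  The `null`
  regime sets $b_{EM} = 0$.  Planting an outcome necessarily overrides
  that outcome's target correlations: an arbitrary marginal correlation
  matrix and a fixed interaction cannot be imposed simultaneously.

What a green test does establish: the estimator recovers planted
coefficients with nominal CI coverage, holds its type-I rate, and returns
the planted label for strongly planted regimes at large $n$.  What it does
not: anything about non-normal scale marginals, item-level measurement
error, informative missingness, or department-correlated exposures — the
generator draws demographics independently of the continuous block.

## Numerical and design choices

* **JCQ weights** are not printed in the source; weights 2/4 (skill
  discretion / decision authority) and 3/2 (first two / remaining three
  demand items) are adopted because they uniquely reproduce the published
  ranges 24-96 and 12-48 from 4-point items.  The weighting is a config
  block (`jcq_weights()`), so another user's-guide convention is a
  declaration away.
* **Log base** for the moderator is 10 — classification is affine
  invariant, so the base only fixes reproducibility of printed numbers.
* **Kurtosis** is excess kurtosis (normal = 0), the convention under which
  the published post-transform value 1.139 is "near normal".
* **KS normality** uses the estimated-parameter (Lilliefors-style)
  Monte-Carlo p-value, seeded, 10,000 replicates by default (2,000 in the
  pipeline); the display value can be capped at 0.200 to mirror legacy
  reporting.  The estimated-parameter p is stochastically smaller than the
  naive fully-specified p, and tests verify that ordering.
* **EM imputation** runs on the joint normal of the seven scale/outcome
  scores; demographics and the moderator are excluded (the moderator must
  be complete).  Convergence: max absolute parameter change < 1e-6, cap
  500 iterations, error with the delta trace on failure.  Per-variable
  missingness cap defaults to 25% — generous against the published "<1%"
  but a guard against imputing structure that is not there.
* **Tenure** enters regressions as continuous years; published tables show
  a single working-duration coefficient, so banding is treated as a
  reporting view, not storage.
* **Dependent-correlation comparison**: both the Meng-Rosenthal-Rubin Z
  and Steiger's pooled-r Z* are provided.  The published Z values could
  not be reproduced from the printed correlation matrix under either
  formula, so neither variant is asserted against them.
* **CFA**: one-factor ML fit by BFGS with analytic gradient on loadings
  and log-uniquenesses (uniquenesses bounded above 1e-6, Heywood cases
  flagged); baseline for CFI/TLI is independence with free variances.
  At a diagonal truth the loading vector is not identified (any
  single-item loading with matching uniqueness reproduces a diagonal
  matrix), so tests assert fit, not loadings, there.
* **Hierarchical tables** report coefficients both at the step of entry
  (the convention of published four-step tables) and from the final model;
  probing always uses the final model and its covariance.
* **Probing window** is $[-2, +2]$ SD, the published RoS convention; the
  PoI area convention and the window are exposed as configuration because
  the published PoI values (0.62 for the job-control model) are not
  recoverable from the printed coefficients under the closed-form ±2 SD
  convention (which gives ≈0.55).

## Known limitations

* Classification by end-point significance degrades at very large $n$:
  with enough power, any nonzero difference at an end becomes significant,
  so edge cases drift toward both-ends significance.  With the crossover
  planted exactly on a window edge, end-point significance at the
  planted-null end is an irreducible ~α-level event (~5-7% observed),
  which bounds attainable recovery rates near 93-95% there.
* The RoS non-significance window is reported as a single interval; when
  significance is instead confined *between* the two roots (tiny
  interaction variance geometry) the bounds are NA and the sub-interval
  table carries the full picture.
* No robust or clustered standard errors, no multilevel structure, no
  non-MCAR missingness — matching the scope of the analysis this package
  operationalizes.
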