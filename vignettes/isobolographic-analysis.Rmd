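---
title: "Non-linear isobolographic analysis of fixed-ratio drug combinations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-linear isobolographic analysis of fixed-ratio drug combinations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(isobolr)
library(dplyr)
```

## The problem

Two analgesics given together may achieve a target effect at a lower total
dose than either alone. Whether that is *synergy*, or just the expected sum
of two active drugs, depends entirely on what "expected" means. isobolr
implements Loewe-additivity (dose-equivalence) analysis for the hard case
where the two drugs have **different maximal effects and different Hill
slopes**, so the classical straight-line isobole is wrong, together with the
behavioral normalization, curve fitting, uncertainty propagation and
hypothesis test that surround it in a typical rodent neuropathic-pain study
(chronic constriction injury, intrathecal dosing, von Frey and acetone
read-outs).

## Normalization to %MPE

Raw behavioral measurements are mapped to the percent of maximum possible
effect so that assays with different units and directions share one scale:

* threshold assays (mechanical paw withdrawal threshold, instrument ceiling
  6.84 g): `100 (post − pre) / (cutoff − pre)`;
* response-reduction assays (acetone-evoked responses, rotarod latency):
  `100 (pre − post) / pre`;
* the bar (catalepsy) test, whose baseline is near zero, is normalized
  against its 120 s cut-off: `100 (post − pre) / cutoff`;
* open-field crossings have no %MPE definition and are carried through raw.

Negative scores (worsening) are **retained**, not clipped: group means near
zero can only average out with signed values. A `clip_negative` switch
exists for sensitivity analyses. Repeated measurements at a timepoint are
averaged on the raw scale before normalization; the 1 h and 2 h post-drug
scores are averaged per animal for dose-response analysis (the window where
the effect of both drugs is maximal). Both reductions use the mean, the
conventional default; the pooled timepoints are an argument everywhere they
matter.

## The dose-response model

Each drug-and-assay pair is fit with a three-parameter Hill sigmoid with
the lower asymptote fixed at 0 %MPE,

$$E(d) = \frac{E_{max}}{1 + 10^{\,p\,(\log_{10}ED_{50} - \log_{10}d)}},$$

by Levenberg–Marquardt least squares on the **individual animals'** scores
(not dose-group means), so residual degrees of freedom and standard errors
reflect the per-animal replication (n = 6 per dose group). The ED50 is
parameterized as $\log_{10}ED_{50}$ internally, where the model is closest
to linear, and reported on the nmol scale with its covariance
delta-transformed to match. Defaults that matter:

* initialization: $E_{max}$ at the maximum observed effect, ED50 at the
  dose whose mean effect is nearest half of that, unit slope (overridable);
* box bounds keeping the search pharmacologically meaningful:
  $E_{max} \in (0, 120]$ %MPE, $ED_{50} \in [0.1, 1000]$ nmol,
  $p \in (0.1, 10]$;
* at least four distinct doses; flat data, non-convergence or a
  rank-deficient Jacobian raise an explicit "unidentifiable fit" error
  rather than returning defaults.

## The predicted-additive surface

With single-drug parameters $(E_A, C_A, q)$ for the drug with the lower
maximum (drug A) and $(E_B, C_B, p)$ for the higher (drug B, assigned
automatically; an Emax tie is broken by potency), a dose $a$ of drug A is
converted to the equi-effective dose of drug B,
$b_{eq}(a) = C_B / k(a)^{1/p}$ with

$$k(a) = \frac{E_B}{E_A}\Bigl(1 + \frac{C_A^{\,q}}{a^{\,q}}\Bigr) - 1,$$

and the predicted-additive effect of the pair $(a, b)$ is drug B's Hill
curve evaluated at $b + b_{eq}(a)$. Two algebraic readings of this model
circulate (the $E_B/E_A$ ratio above versus its reciprocal, and the
placement of the denominator bracket); only the form implemented here
satisfies the dose-equivalence identity — the effect of $b_{eq}(a)$ alone
equals the effect of $a$ alone, testably, to 1e-9 — and only it reduces to
drug B's sigmoid at $a = 0$. The reciprocal orientation is available as
`k_form = "reciprocal"` for comparison; it breaks both properties and can
leave the half-maximal effect unreachable on the combination ray.

Because $k(a) > E_B/E_A - 1 > 0$, the B-equivalent of even an infinite dose
of drug A saturates at $C_B/(E_B/E_A - 1)^{1/p}$: a finite amount of drug B
exhausts everything drug A can ever do. This single fact generates all of
the non-linear isobole geometry below.

The **predicted-additive ED50** on a fixed-ratio ray
$(a, b) = (f_A D, f_B D)$ is the total dose $D$ at which the surface
reaches $E_B/2$ — half the composite curve's maximum, the only definition
under which combining a drug with itself returns exactly its own ED50 (the
sham-combination test). The root is bracketed and refined to a relative
tolerance of 1e-8. For the study's 1:1-by-weight THC:CBD design, weight and
molar ratios coincide (the two phytocannabinoids are structural isomers);
the design records the basis regardless.

```{r}
thc <- hill_params(85, 14, 2.6, se = c(emax = 2, ed50 = 0.8, hill = 0.3),
                   dof = 45, drug = "THC")
cbd <- hill_params(79, 20, 1.5, se = c(emax = 2, ed50 = 0.6, hill = 0.1),
                   dof = 45, drug = "CBD")
predicted_ed50(additive_surface(cbd, thc))
```

## Delta-method uncertainty

The predicted ED50 is an implicit function of six fitted parameters. Its
standard error is propagated to first order: the gradient with respect to
$(E_A, C_A, q, E_B, C_B, p)$ is computed by central differences
(re-solving the perturbed surface; relative step 1e-5, checked to be
step-size robust to 1e-4), and combined with the block-diagonal covariance
of the two independent fits — independent because each animal contributes
to only one drug's curve. When the target level is the default $E_B/2$,
perturbing $E_B$ moves the level too; the gradient includes that term.

Two caveats the package documents rather than hides:

* the linearization is only as good as the function is locally linear. A
  Monte-Carlo check (resampling the six parameters and re-solving, with
  drug roles held fixed — the estimator the delta method linearizes)
  agrees with the delta SE to within ~1–9% for parameter sets like the
  study's;
* when the two maximal effects are **statistically indistinguishable**
  (e.g. 85 ± 2 vs 79 ± 2 %MPE), the predicted ED50 becomes strongly
  non-linear in $E_B/E_A$, and re-fitting can even swap which drug is "B".
  Across simulated replicates the sampling spread of the predicted ED50 is
  then 2–3 times its delta SE, and the synergy t-test below becomes
  anti-conservative (simulated type-I error ~0.17 at $\alpha = 0.05$ under
  the mechanical-PWT-like conditions, versus ~0.015 under the acetone-like
  conditions where the maxima are far apart). Users should read borderline
  p-values against this: the verdict is trustworthy when the single-drug
  maxima are clearly separated, and optimistic when they are not.

## Isoboles

The additivity isobole at effect level $L$ (in absolute %MPE) is
$b(a) = B_{dose}(L) - b_{eq}(a)$, floored at zero, where $B_{dose}(L)$ is
the dose of drug B alone producing $L$ — a dose, not the percent number,
which is the only dimensionally consistent reading and the one that puts
the $a = 0$ intercept at drug B's equi-effective dose (its ED50, at the
half-maximum level). Every point with $b > 0$ closes the loop through the
surface to its level within 1e-6. The default family spans 20–50 %MPE in
steps of 10.

Geometry worth knowing when reading an isobologram:

* curves at higher levels nest strictly above lower ones;
* the curve meets the drug-A axis exactly when drug A alone can produce
  the level; when the level exceeds drug A's maximum (e.g. 30–50 %MPE
  against an acetone CBD maximum of 27), it flattens to a strictly
  positive asymptote and never reaches the axis;
* when both drugs have equal maxima and unit slopes the curve collapses,
  pointwise, onto the classical straight line through the two ED50s
  (`linear_isobole()`, the standard reference overlay).

`classify_point()` formalizes the visual read: a combination ED50 below
the additivity curve at its abscissa is supra-additive.

## The synergy test

The experimentally fitted combination ED50 (total dose on the ray) is
compared with the predicted-additive ED50 by an unpaired t-test,
$t = |pred - exp| / \sqrt{se_{exp}^2 + se_{pred}^2}$, two-sided. The
degrees of freedom are not uniquely defined for derived quantities; the
package implements Welch–Satterthwaite combination of the two estimates'
residual dofs (default; the predicted side carries the sum of its two
fits' dofs) and a z approximation, and labels which was used. Significance
plus direction gives the verdict: synergistic when the experimental ED50
sits significantly below the prediction. With fit-scale dofs the published
potency-table values give p < 0.05 (mechanical PWT, potency ratio ~1.6)
and p < 0.001 (acetone, ratio ~2.2); at very small dofs (≤ ~9) the acetone
comparison would cross only the 0.01 threshold, which is why the dof
convention is surfaced in every report.

## The synthetic study generator

No raw per-animal data are published for studies of this design, so
`simulate_cci_study()` generates datasets with the statistical structure
the analysis assumes, making every stage testable end-to-end. What it
emulates: 6 animals per treatment group, one treatment arm per animal;
vehicle, two single-drug arms over a half-log ladder of 8 doses spanning
1–178 nmol, and a 1:1 fixed-ratio combination ray; healthy pre-CCI
baselines and allodynic post-CCI pre-drug baselines (PWT dropping from
~4.0 g to ~0.7 g, acetone counts rising from ~1.5 to ~8 per 2 min);
latent Hill-shaped drug effects with the published potency parameters as
truth; zero latent effect in the rotarod/bar/open-field battery and in
vehicle; scoring at 1 and 2 h. Noise is Gaussian on the %MPE scale
(SD 10 by default — chosen once so that fit standard errors land in the
magnitude range published potency tables report; no residual variance is
published for studies of this design, so this is an assumption and is
labelled as such) and
back-transformed through the inverse normalizations to raw units, clipped
to instrument bounds, with counts rounded (a Poisson mode exists for
robustness testing). `interaction_shift` scales the potency of the
combination ray: 1 is additive truth, 0.6 a synergistic truth of the size
the study reports.

What it does **not** emulate: the up-down filament testing procedure
(thresholds are emitted directly), pharmacokinetic time courses beyond the
two pooled timepoints, antagonist pharmacology, and any raw-scale
heteroscedasticity — so passing tests demonstrate the pipeline's
statistical behavior under its own assumptions, not the measurement
process of a real assay.

```{r}
records <- simulate_cci_study(cci_config(seed = 42, interaction_shift = 0.6))
run_single_drug(records) |> select(drug, assay, status, note)
```

```{r}
res <- run_combination(records, assay = "mechanical_pwt")
tidy(res)
```

## Numerical choices and degenerate inputs

* Root-finding brackets expand geometrically from twice the larger single
  ED50; an unreachable level (≥ $E_B$ on the ray, or an inconsistent
  surface) is an error, never an extrapolation.
* `hill_effect(0, ...)` is 0 by continuity, not a log-domain error;
  `inverse_hill()` refuses levels at or above $E_{max}$.
* Covariance matrices are validated (symmetric, positive semi-definite) at
  construction and again before propagation, so upstream fit failures
  surface where they occur.
* Dose-dependence screening in `run_single_drug()` (significant positive
  log-dose trend, or a dose mean ≥ 20 %MPE) decides which assays are fit
  at all, mirroring the practice of not fitting dose-response curves to
  flat side-effect measures; skipped items are reported, not dropped.
* All generator output is a deterministic function of the seed; identical
  configs produce byte-identical CSVs.

## Problem sizes used in the test suite

The packaged checks run the full pipeline at the study's own scale (6
animals × 8 doses × 4 arms): single fits take ~10 ms, a complete
combination analysis ~0.1 s. Calibration properties use 20 seeded
replicates for parameter-recovery coverage, 10^4 Monte-Carlo draws for the
delta-method check, and 200 seeded replicates per assay for type-I error —
sizes at which the binomial uncertainty of the measured rates is a few
percentage points, adequate for the pass/fail bounds they are held to.

## Known limitations

* Only Loewe-type dose-equivalence additivity is implemented — no Bliss
  independence, no response-surface interaction indices, and no confidence
  bands around isoboles.
* The delta-method SE (and hence the t-test) degrades when the two
  single-drug maxima are statistically indistinguishable; see the
  uncertainty section above.
* The three-parameter Hill model has no basal term and no model-selection
  alternatives (no biphasic or four-parameter variants).
* The %MPE normalizations assume valid, in-range baselines; degenerate
  baselines (PWT at the cut-off, zero acetone counts) are flagged as
  errors for the user to resolve, not imputed.
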