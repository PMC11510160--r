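---
title: "Methods: a minimal PBPK model of 4β-hydroxycholesterol as a hepatic CYP3A biomarker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a minimal PBPK model of 4β-hydroxycholesterol as a hepatic CYP3A biomarker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ohcpbpk)
```

## Scope and model structure

`ohcpbpk` models plasma cholesterol (parent) and 4β-hydroxycholesterol
(4β-OHC, metabolite) to quantify hepatic CYP3A activity. Each analyte gets a
single systemic compartment of volume `Vss × body weight`; the liver is not
a separate kinetic compartment. This minimal topology rests on two
assumptions: distribution to peripheral tissues has marginal impact at
steady state for both analytes (their volumes of distribution are small,
0.10 and 0.05 L/kg), and hepatic metabolism is the only elimination route.
Liver concentrations are reported through fixed liver-to-plasma partition
coefficients (Kp 3.07 and 3.87) and are also used to drive induction when a
perpetrator is simulated.

Hepatic clearance follows the well-stirred liver model on a plasma basis,

$$CL_H = \frac{Q_H\, fu_p\, CL_{int,u,H}}{Q_H + fu_p\, CL_{int,u,H}/(B\!/\!P)},$$

with the whole-liver unbound intrinsic clearance additive over pathways.
Both analytes sit deep in the low-extraction regime (extraction ratio
~5 × 10⁻⁵ for cholesterol), so `CL_H ≈ fu_p × CLint` and every translated
quantity is effectively linear in the pathway intrinsic clearances.

Cholesterol enters as a continuous intravenous infusion of 1.73 mg/kg/day.
The daily 24-h infusion of the underlying trial design is implemented with
zero gap — a constant rate — because only the steady state is of interest
and the infusion has no off-period. Metabolite formation is the parent
elimination rate times the CYP3A share of the parent's scaled intrinsic
clearance (competing pathways share extraction proportionally to their
scaled CLint), mass-converted by the molecular-weight ratio 402.35/386.65.

## Reverse translation of clearances

The in vivo elimination half-lives anchor the clearances: 46.05 days for
cholesterol and 62 h for 4β-OHC give `CLiv = 0.693 Vss W / t½`, inverted
through the well-stirred model to the total hepatic metabolic intrinsic
clearance `CLmet,H`. Fractions metabolized split this total: 27% CYP27A1
for cholesterol, 50% CYP27A1 for 4β-OHC, an initial CYP3A fraction of
2.1 × 10⁻⁵ for cholesterol attributed entirely to CYP3A4, and the remainder
assigned to a residual per-mg microsomal ("additional HLM") pathway that
stands in for CYP7A1, for which no hepatic abundance data exist. The
residual fraction is computed as `1 − (fm_CYP27A1 + fm_CYP3A)`: that is the
only mass-balanced reading and reproduces the published residual clearance
of 0.350 µL/min/mg.

In vitro/in vivo scaling uses liver weight 1737.11 g, MPPGL 39.79 mg/g, and
abundances of 137 pmol/mg (CYP3A4) and 41.93 pmol/mg (CYP27A1), with the
exact factor `liver weight × MPPGL × abundance × 60/10⁶` between
µL/min/pmol and L/h. Internal units are h, L, mg and pmol throughout.

Two body-weight conventions deserve emphasis. The half-life studies behind
the two analytes involved different subject pools, and only "average" body
weights are reported upstream. We back-derived 67.5 kg (cholesterol side)
and 63.5 kg (4β-OHC side) as the weights under which the full chain
reproduces every published elimination entry to within 2%; both defaults
are prominent arguments (`weight`, `default_physiology(body_weight =)`) and
carry no authority beyond that consistency.

The optimized CYP3A4 intrinsic clearance (4.17 × 10⁻⁷ µL/min/pmol) is
treated as the CYP3A-family total net of siblings: dividing by
`1 − (5.6% + 2.8%)` and applying the in vitro percentage contributions
yields the CYP3A5 and CYP3A7 clearances (2.55 × 10⁻⁸ and
1.27 × 10⁻⁸ µL/min/pmol). Applying the 92% CYP3A4 share *before* this
sibling scaling does not reproduce the published initial CYP3A4 value, so
the initial estimate assigns the whole 2.1 × 10⁻⁵ fraction to CYP3A4 and
the sibling split is applied only to the optimized value.

## Induction, inhibition and dynamics

CYP3A activity is a single shared relative level `E(t)` applied to CYP3A4,
CYP3A5 and CYP3A7 (perpetrator files for rifampicin-class inducers induce
the family with shared parameters; whether CYP3A7 was included upstream is
not documented — we include it, and its contribution is negligible either
way). CYP27A1 and the residual HLM pathway are never induced; consequently
the model cannot represent CYP7A1 regulation, a known limitation that also
applies to inhibitors like rifampicin's suppression of CYP7A1.

Induction: `fold = 1 + (Ind_max − 1)·C_u/(IndC50 + C_u)` with unbound liver
perpetrator concentration `C_u = fu × Kp,liver × C_plasma` in µM.
Rifampicin-like defaults Ind_max = 16, IndC50 = 0.32 µM. The fold feeds
first-order enzyme turnover `dE/dt = kdeg (fold − E)`. `kdeg` defaults to
0.0193 h⁻¹ (≈36 h hepatic CYP3A turnover half-life, the conventional
literature value) and is configurable: the upstream analysis ran induction
inside a commercial simulator and never states its turnover constant.
Competitive inhibition scales the CYP3A clearances by `1/(1 + C_u/Ki)`
instantaneously. Perpetrator kinetics are one-compartment with first-order
oral absorption (`ka`, `V`, `CL` in the config); the shipped rifampicin-like
values are implementation conveniences for exercising the machinery, not
ground truth.

CYP27A1 is represented natively as an enzyme with its own abundance; the
proxy-enzyme workaround needed in the commercial simulator is unnecessary
here.

## Numerical choices

* ODE integration uses `deSolve::lsoda` with `rtol = 1e-8`, `atol = 1e-10`
  and daily output; the system is small and smooth, and a 700-day subject
  integrates in well under a second.
* `analytic_steady_state()` provides the closed-form steady state; the ODE
  engine agrees with it to < 0.5% once runs cover ~12 parent half-lives
  (the "at least 700 days" protocol suffices for a typical subject;
  slow-clearance individuals need proportionally longer, which the tests
  apply adaptively).
* Simulations may warm-start at the analytic baseline (`init = "analytic"`),
  which removes the long approach phase in DDI protocols where only the
  perturbation matters.
* Steady-state summaries (`Css`) are means over the final 30 simulated days
  of a phase — long against the 62-h metabolite half-life, short against
  the 700-day horizon.
* The post-perturbation half-life uses log-linear regression on the
  approach to the new plateau, with the plateau estimated by Aitken Δ²
  extrapolation of the last three points (exact for a single surviving
  exponential) and the fitted range restricted to gaps above 0.1% of the
  initial departure.
* `calibrate_fm_cyp3a()` searches the CYP3A4 CLint on a log scale with
  `uniroot`; siblings stay tied to it and the HLM clearance is rebalanced
  so the parent's total `CLmet,H` is preserved, which makes the baseline
  metabolite Css strictly monotone in the search variable (bisection is
  therefore valid). Degenerate targets fail with the evaluated
  search curve attached for diagnosis.
* Unit round-trips (L/h ↔ µL/min/pmol) are exact to 10⁻¹² relative; the
  well-stirred forward/inverse pair round-trips to 10⁻⁹ relative across the
  physical input space.

## Virtual populations

Templates are thin records of means, CVs and frequencies. Sampled scalars
(body weight, liver weight, MPPGL, hepatic blood flow, abundances) are
lognormal, parameterized by arithmetic mean and CV — strictly positive and
standard for enzyme abundances. Defaults for the healthy Caucasian-like
adult template: CYP3A4 137 pmol/mg with 41% CV; CYP27A1 41.93 pmol/mg with
CV 0 (a single proteomics-derived value with no reported variability —
explorable through the sensitivity scan); a +24% female CYP3A4 abundance
shift applied to the mean before sampling; CYP3A5
extensive-metabolizer fraction 0.17 (0.48 for the Asian-like template).
Poor metabolizers receive zero CYP3A5, intermediates half the
extensive-metabolizer mean. The CYP3A5 extensive-metabolizer abundance mean
(102 pmol/mg) and the CYP3A7 adult abundance (2 pmol/mg) are documented
placeholders: neither is published in this context, CYP3A5 contributes only
a few percent of 4β-OHC formation, and the values were fixed once so that
the extensive/poor-metabolizer baseline ratio falls in the observed
1.04–1.13 range. Size-scalar CVs (weight 15%, liver weight 15%, MPPGL 30%,
QH 15%) are field-conventional choices, as the upstream population library
is proprietary.

Genotype and disease templates override the CYP3A4 abundance mean:
100.86 pmol/mg (CYP3A4\*1/\*22) and 51.27 pmol/mg (CYP3A4\*22/\*22), both
derived by the retrograde probe calculation below; 82.07 pmol/mg plus
cardiac output ×1.05 and hematocrit ×0.83 for rheumatoid arthritis.

### The retrograde probe

Genotype abundances come from clinical reductions in the clearance of a
CYP3A probe drug (midazolam-class): the probe's hepatic clearance is
reduced by 20% (heterozygous) or 50% (homozygous), the well-stirred model
is inverted, the fixed CYP3A5 contribution subtracted, and the implied
CYP3A4 abundance recovered. The actual probe parameter file is not public,
so the package ships `synthetic_cyp3a_probe()` — labelled synthetic — whose
two free properties (baseline blood extraction ratio ≈0.16 and a 13.3%
CYP3A5 share of CLint) were solved, once, so that the chain reproduces both
reference abundances exactly at the reference physiology. The probe is a
consistency device, not a midazolam model.

## Trials, DDI protocols and calibration

`run_trial_set()` mirrors the virtual-study structure (default 10 trials of
the per-study subject count; trial *i* draws its subjects with seed
`seed + i`, so two designs sharing a seed are subject-paired — this is what
makes population *ratio* endpoints, like the genotype fold-changes, nearly
noise-free at 200 subjects). Baseline Css uses the analytic engine by
default; the ODE engine is available (`method = "ode"`) and tested to agree.
`ddi_protocol()` runs paired baseline/perturbed simulations per subject and
summarizes the ratio distribution; a perpetrator may be a full PK model or
an imposed activity fold for mechanism-agnostic analyses.

Calibration defaults to the single baseline-Css target, with the induced/
baseline ratio at a chosen activity fold reported as a check
(`check_fold`), reflecting that the upstream optimization targeted a
baseline plus one rifampicin study jointly.

## What the synthetic data do and do not show

`gen_study_table()` emulates the *structure* of the literature meta-analysis
input — per-study n, mean and SD of baseline plasma 4β-OHC with
between-study scatter, within-study CV and optional sex/ethnicity shifts
(e.g. the 31% female excess). The default truth of 29.85 ng/mL matches the
pooled literature value so that the pipeline's recovery can be judged on a
realistic scale. Passing the recovery tests demonstrates that the pooling
statistics are correct and unbiased for lognormal study data; it says
nothing about the representativeness of the real 38-study literature, which
is not reconstructable from published summaries. Similarly,
`gen_observed_profiles()` applies multiplicative lognormal observation
noise to model output — adequate for testing assessment statistics, but
real bioanalytical error also has additive floors and between-visit
components the generator does not emulate.

## Known limitations

* No cholesterol homeostatic feedback and no mechanistic CYP7A1: perturbing
  cholesterol does not regulate bile-acid synthesis in the model, so
  predicted population variability of both analytes is wider than observed
  clinical variability.
* No intestinal CYP3A (its contribution to plasma 4β-OHC is reported
  negligible) and no age ontogeny; adult populations only.
* Parent Css is insensitive to CYP3A perturbation (fm_CYP3A ≈ 1.2 × 10⁻⁴),
  so the model cannot describe inducer effects on cholesterol itself —
  consistent with observation, but worth remembering when interpreting the
  parent trajectory.
* The linear turnover cascade predicts post-induction biomarker half-lives
  of a few days (bounded below by the 62-h metabolite half-life); longer
  apparent half-lives reported from full-simulator runs are not reproduced
  and are reported, not asserted, by `post_perturbation_halflife()`.
* Ethnic templates beyond the Caucasian- and Asian-like defaults require
  user-supplied parameters; only values with a published basis ship as
  defaults.
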