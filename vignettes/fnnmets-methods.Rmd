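---
title: "Methods: fuzzy neural network discovery of combinational MetS risk factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fuzzy neural network discovery of combinational MetS risk factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Metabolic syndrome (MetS) develops through interactions among routine
health-check characteristics, and single-marker screening misses
combinational risk. `fnnmets` implements a complete pipeline for finding
*pairs* of routine characteristics whose combination predicts MetS
development in longitudinal employee health-check cohorts: cohort
labeling by the Japanese (JASSO) criteria, a fuzzy neural network (FNN)
classifier with greedy forward input selection under five-fold
cross-validation, fuzzy-rule extraction, and conventional statistical
verification.

Because employee health-check records are private, the package ships a
seeded synthetic cohort generator whose defaults emulate the published
summary structure of two such cohorts. Everything downstream of the
generator is data-agnostic: a real cohort CSV with the same column
dictionary drops straight into `analysis_table()` and onward.

# Cohort labeling

A subject's examination panel is classified with the JASSO components,
all boundaries inclusive as conventionally printed:

* obesity — waist circumference ≥ 85 cm, or BMI ≥ 25 kg/m² when waist
  was not measured (synthetic cohorts carry no waist; the BMI-modified
  rule is used throughout);
* raised blood pressure — SBP ≥ 130 and/or DBP ≥ 85 mmHg;
* dyslipidemia — triglycerides ≥ 150 and/or HDL < 40 mg/dL;
* raised fasting glucose — ≥ 110 mg/dL.

MetS = obesity plus any two of the other three. Labels are assigned per
subject: `excluded` for any antihypertensive / lipid-lowering /
anti-diabetic medication, and for subjects already MetS at baseline
(a "case" must *develop* MetS; the sources leave baseline-positive
subjects unaddressed, so exclusion is this package's documented choice);
`case` for MetS in any follow-up year; `healthy_control` for subjects
who are "supercontrols" — free of all four components — at baseline and
in every follow-up year; `normal_control` otherwise.

Two conservative conventions handle partial missingness. An "and/or"
pair (SBP/DBP, TG/HDL) with one raised observed value is positive
regardless of the other; with no raised value and either member
unobserved it is *indeterminate*, not negative. A year with any
indeterminate component cannot count toward `healthy_control`, so a
healthy control is only ever declared on fully observed, fully negative
panels.

# The fuzzy neural network

Each selected input $x_j$ (standardized by its training mean and sd)
feeds two sigmoid membership functions,

$$f(x) = \frac{1}{1 + \exp(-W_g x + W_c)},$$

a non-decreasing "high" grade ($W_g > 0$) and a non-increasing "low"
grade ($W_g < 0$). For $k$ inputs, each of the $2^k$ rule units
multiplies one grade per input, $\Pi_r = \prod_j f_{j,r_j}(x_j)$, and the
output is the weighted sum $y^* = \sum_r W_{f,r} \Pi_r$. A subject is
estimated to be a case when $y^* > 0$, a healthy control when
$y^* < 0$; $y^* = 0$ is counted as incorrect for either class.

Training details are deliberately plain, since the network architecture,
not the optimizer, carries the scientific content: full-batch gradient
descent on the squared error $\sum_i (y^*_i - t_i)^2$ with targets
$t = \pm 1$, learning rate 0.05, 500 epochs (both exposed in
`fnn_config()`). The sign constraints on $W_g$ are maintained by
projection after each step. Initialization is deterministic and
symmetric: $W_c = 0$, $W_g = \pm 2$, $W_f = 0$; the configured seed only
shuffles presentation order, so training is reproducible by
construction. The low and high memberships are independent sigmoids —
their sum is not constrained to 1. No log transform is applied by
default (a monotone sigmoid absorbs monotone skew); `fnn_config()` has a
`log_inputs` toggle.

With the default learning rate the loss is empirically non-increasing on
the cohorts the package targets; the property suite checks this at
`lr = 1e-3` on fixed toy data, where it is guaranteed in practice.

# Selection and scoring

Model search follows the *parameter-increasing* (greedy forward) method
over sixteen candidate characteristics that are not themselves MetS
components: habits (smoking, alcohol), renal markers (BUN, creatinine,
uric acid), serum enzymes (γ-GTP, GOT, GPT), hematology (hemoglobin,
hematocrit, RBC, WBC), and four urinalysis flags. Stage 1 scores each
candidate alone; stage 2 pairs the stage-1 winner with each remaining
candidate. Every candidate set is re-restricted to its own complete
cases, so the analysis n shrinks as inputs accumulate, exactly as it
does in real health-check data with per-assay missingness.

Scoring uses five-fold cross-validation. Each fold's score is the
weighted accuracy

$$\text{Accuracy} = 100\left[\frac{\text{correct}_{\text{train}}}{n_{\text{train}}}\cdot\frac13 + \frac{\text{correct}_{\text{test}}}{n_{\text{test}}}\cdot\frac23\right],$$

and a candidate set's score is the *mean* of its five fold scores (the
alternative — pooling counts across folds — is not used; the source
procedure asks for an average across the CV). The yardstick is the
null-method baseline, `100·max(n_case, n_control)/n`, recomputed on each
candidate set's own complete-case subset. Multiple linear regression
(predict case iff the fitted value on ±1 targets is > 0) and multiple
logistic regression (case iff fitted probability > 0.5) are scored on
identical subsets and identical folds. Ties in selection go to the
lower input number. Perfect separation in a logistic fold falls back to
a lightly ridge-penalized fit (`glmnet`, α = 0, λ = 1e-3), flagged in
the result.

**Fold stratification.** CV folds are stratified by class by default:
subjects are shuffled within class and dealt round-robin, keeping each
fold's case fraction near the overall one (fold sizes still differ by at
most one). At the n this pipeline faces after complete-case filtering —
roughly 130–180 subjects, ~35 % cases — plain random folds occasionally
produce class-skewed folds whose accuracy noise is comparable to the
true incremental value of a second input, which destabilizes the stage-2
ranking. Stratification is the standard remedy in wrapper selection and
changes nothing in expectation; the plain random plan remains available
(`make_cv_plan(..., strata = NULL)`, `forward_select(...,
stratify = FALSE)`).

# Fuzzy-rule extraction

A trained two-input model is rendered as a 2×2 rule matrix. Each
input's low/high boundary is the raw value at which its *high*
membership crosses grade 0.5, i.e. $x^* = W_{c,\text{high}} /
W_{g,\text{high}}$ mapped back through the standardization constants.
(Where exactly such printed thresholds come from — the
high-membership midpoint, the low/high crossing, or another rule — is a
presentation convention; the high-membership midpoint is this package's
documented one, and the two coincide for symmetric memberships.) Cell
assignment is crisp: "high" iff the raw value is ≥ the threshold,
matching the ≥-phrasing such rule matrices are printed with; a fuzzy
max-membership assignment is available behind `method = "membership"`.
Each cell reports its case and control counts (always conserving the
class totals) and its raw rule weight $W_f$, unnormalized.

# Statistical verification

The selected characteristics are re-examined with standard
epidemiological machinery on the case vs healthy-control contrast:

* **Adjusted odds ratios** (`logistic_or()`): maximum-likelihood
  logistic regression with Wald 95 % CIs. The adjustment ladder is
  model 1 — unadjusted; model 2 — age, drinking, smoking; model 3 —
  model 2 + the six MetS components; model 4 — model 3 + exercise
  habit. γ-GTP enters as log₂ ("per doubling"), which makes the OR
  invariant to any positive rescaling of the assay units.
* **Correlation ratios** (`correlation_eta()`): for a binary habit the
  correlation ratio η equals in magnitude the point-biserial (Pearson)
  correlation with the 0/1 indicator; the signed value is reported, and
  the p-value is the exact t transform with n − 2 df.
* **Group comparisons** (`group_compare()`,
  `characteristics_table()`): pooled-variance Student t for continuous
  characteristics (Welch behind a flag) and Pearson chi-square *without*
  continuity correction for 2×2 tables — the combination that
  reproduces the reproducible printed p-values in published
  baseline-characteristics tables of this kind.

# The synthetic cohort generator

`cohort_spec()` fixes the study conditions; the defaults are calibrated
once, against published summary statistics, and are not tuning knobs.

* **Marginals.** Continuous characteristics are normal, truncated at
  physiologic floors; γ-GTP and triglycerides are log-normal, matching
  their large SD/mean ratios in health-check tables. Weight is derived
  from BMI and height so the two stay consistent. SBP/DBP are
  correlated at r = 0.6.
* **Habit effects.** Drinking shifts log γ-GTP by +0.38; age adds
  0.040/yr on the log scale (anchored at age 31); smoking shifts WBC by
  +1150 cells/µL. These sizes land the habit–biomarker correlation
  ratios near their published magnitudes (η ≈ 0.19 for alcohol→γ-GTP,
  ≈ 0.39 for smoking→WBC) and make the two presets' healthy-stratum
  γ-GTP means ≈ 16 IU/L (age-31 cohort) and ≈ 27 IU/L (age-43 cohort)
  — the between-study difference is purely the age effect.
* **Onset.** MetS development is one Bernoulli event per subject with
  logistic probability in standardized log γ-GTP ($z_1$), standardized
  WBC ($z_2$) and their product: logit p = −4.5 + 1.3 z₁ + 0.91 z₂ +
  0.45 z₁z₂. The marginal slopes correspond to published model-1 odds
  ratios (≈ 4.7 per γ-GTP doubling; ≈ 1.8 per 1000 WBC); the positive
  interaction encodes the synergistic high/high cell; the intercept was
  calibrated once by simulation so that an age-31 cohort of 1803 yields
  roughly 77 cases to 152 healthy controls (≈ 1:2). Onset is a
  follow-up-window event, not a per-year hazard, because the analysis
  only consumes developed-ever labels; the onset year is uniform over
  follow-up, and from it the affected subject persistently satisfies
  obesity + raised BP + dyslipidemia.
* **Follow-up dynamics.** Non-onset panels drift with age (e.g. BMI
  +0.03/yr, SBP +0.3/yr) plus exam-to-exam noise (SBP 6.5 mmHg, TG 15 %
  on the log scale, ...). Drift and noise jointly set how rarely a
  subject stays component-free for nine examinations, which is what
  makes genuine healthy controls about 8–9 % of a cohort.
* **Missingness.** MCAR per characteristic, applied to the sixteen
  candidate inputs only (γ-GTP 26 %, WBC 21 %, other labs 10–15 %);
  follow-up component panels stay complete because labeling requires
  them. The γ-GTP/WBC rates are chosen so the complete-case ladder of a
  1-input and a 2-input analysis reproduces the published pattern of
  shrinking n (roughly 156 → 124 analysis subjects per 229).
* **What is deliberately not emulated:** urinalysis flags are pure
  Bernoulli noise; no women (the emulated studies are male-only); no
  within-subject correlation beyond baseline + drift + noise; no
  informative missingness; no measurement rounding. Passing tests on
  this generator therefore demonstrate that the pipeline recovers a
  planted interaction under realistic marginals, counts and
  missingness — not that it would survive confounding structures the
  generator does not contain.

## Problem sizes used in the test and acceptance suites

The recovery experiments run 20 seeds of an n = 2000 original-preset
cohort (≈ 250 case/healthy-control subjects before per-assay
missingness) through the full 16-candidate two-stage selection; marginal
and correlation checks use n = 4000–5000 single cohorts. These sizes
hold the sampling error of the checked quantities comfortably below the
assertion tolerances while keeping the default suite fast.

# Known limitations

* The trainer is a faithful gradient implementation of the stated
  architecture, not a reproduction of any particular historical
  optimizer; published accuracy figures from private data are therefore
  qualitative references, not targets.
* Greedy forward selection up to k = 2 is the whole search space; no
  exhaustive pair search, no nested hyperparameter CV.
* The adjustment-model ladder (models 2–4) is reconstructed from the
  adjustment description in prose; footnote-level definitions in the
  source tables are not machine-readable.
* η is reported signed; two-level habits only.
* `normal_control` subjects are labeled but the verification functions
  default to the case vs healthy-control contrast.
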