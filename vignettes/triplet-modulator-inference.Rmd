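---
title: "Inferring TF-modulated RBP–splicing regulation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring TF-modulated RBP–splicing regulation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(splicemod)
library(dplyr)
```

## The scientific question

Alternative-splicing events (ASEs) are quantified per sample by PSI (percent
spliced-in), a fraction in $[0,1]$ measuring how often an exon, promoter,
terminator, donor or acceptor variant is included.  Splicing outcomes are
proximally controlled by RNA-binding proteins (RBPs), but which targets an
RBP acts on can itself depend on cellular context — in particular on the
abundance of transcription factors (TFs).  `splicemod` asks, for every
candidate combination of one TF, one RBP and one ASE in a tumor cohort:
*does the TF's expression level change the relationship between the RBP's
expression and the event's PSI?*  A combination where the answer is yes is a
**triplet**, and the TF is called a modulator of that RBP–ASE interaction.

The pipeline has six stages, each exposed as ordinary functions on tibbles:

1. **Preprocessing** (`impute_psi()`, `filter_low_expression()`,
   `harmonize_samples()`)
2. **Cancer-specific event screening** (`mi_rank()`, `isis_lasso_select()`,
   `screen_ases()`)
3. **Differential TF/RBP screening** (`wilcoxon_de()`, `select_de()`)
4. **Interaction testing** (`enumerate_triplets()`, `fit_triplet_lmm()`)
5. **Mode classification** (`annotate_modes()`, `classify_mode()`)
6. **Survival stratification and network export**
   (`summarize_survival()`, `build_network()`)

A seeded synthetic-cohort generator (`generate_cohort()`) with planted
structure underlies all statistical validation; it is first-class, tested
code, not a fixture.

## The interaction model

For a single (TF, RBP, ASE) combination the per-sample model is a linear
mixed model fitted by maximum likelihood:

$$
Y_{\mathrm{PSI}} = \beta_0 + \beta_1 X_{\mathrm{RBP}} + \beta_2
X_{\mathrm{TF}} + \beta_3\, X_{\mathrm{RBP}} X_{\mathrm{TF}} + \beta_4
X_{\mathrm{gender}} + \beta_5 X_{\mathrm{stage}} + b_{\mathrm{age}} +
b_{\mathrm{race}} + b_{\mathrm{year}} + \varepsilon
$$

with independent random intercepts $b$ over decade age bins, race
categories and diagnosis years, and i.i.d. residuals.  $\beta_3$ is the
modulation effect: if the TF does not change the RBP–PSI relationship,
$\beta_3 = 0$.  A combination is declared **significant** only when the
Wald p-values for $\beta_1$, $\beta_2$ *and* $\beta_3$ are each below 0.05
and the $\beta_3$ estimate is nonzero (an exact test on the estimate: with
continuous data it is almost surely nonzero, so the interaction p-value is
the binding clause).

Modelling choices, with reasons:

* **Fitting cohort.** Tumor samples only (configurable to `"all"`).  Stage
  and survival exist only for tumors, and the downstream risk models run on
  the tumor cohort; fitting both classes would confound the interaction
  with tumor/normal composition.
* **Covariate scales.** RBP and TF expression are $\log_2(x+1)$-transformed
  and z-scored across the fitting samples, so Wald tests are comparable
  across genes with very different dynamic ranges; PSI stays on its native
  $[0,1]$ scale.
* **Random-effect grouping.** A continuous covariate cannot index a random
  intercept, so age enters as decade bins; year of diagnosis and race as
  their categories.  Grouping factors with a single observed level are
  dropped from the model (recorded in the fit) rather than failing.
* **ML, not REML**, so likelihoods are comparable across fixed-effect
  specifications; coefficient tests are two-sided Wald tests on the
  $t_{n-p}$ reference distribution, where $p$ counts fixed-effect columns.
  When no usable grouping factor remains the model reduces to OLS, and the
  tests reduce *exactly* to the classical regression t-tests — a property
  the test suite checks against an independent normal-equations oracle at
  tolerance $10^{-6}$.
* **No multiplicity correction by default** across combinations, matching
  the raw-0.05 triple criterion; `enumerate_triplets(adjust = TRUE)` applies
  Benjamini–Hochberg per term for users who want it.
* **Failure handling.** Optimizer warnings flag the fit as non-converged
  (never significant, never silently dropped); constant PSI rows yield a
  degenerate fit with all substantive effects zero.

`enumerate_triplets()` fits every combination of the supplied feature sets
in lexicographic order.  Because only the response and three design columns
change between fits on one cohort, the random-effects structure is parsed
once and reused (lme4's modular interface); a test asserts that this fast
path reproduces the one-shot fit exactly.

## Screening stages

### Cancer-specific splicing events

Each event's PSI vector is discretized into 10 equal-width bins on
$[0,1]$ (PSI is bounded, so equal-width bins are well defined) and its
mutual information with the tumor/normal label is computed from the joint
histogram in bits.  Events are ranked by MI with ties broken by event id,
and the top 50 form the head set.

The head set then goes through an iterative selection loop:

1. *Marginal-association guard.*  The plug-in MI is, up to the factor
   $2N\ln 2$, the G-statistic of independence of the binned PSI and the
   label, so each candidate gets a G-test p-value; only candidates whose
   BH-adjusted p-value is below 0.05 remain eligible.  This guard exists
   because the head set is chosen for high MI *on the same samples*: with
   label-permuted data the top-ranked events carry real-looking spurious
   association, and cross-validated penalty choice alone (any of deviance,
   class error or AUC, at either `lambda.min` or `lambda.1se`) still admits
   a dozen spurious events.  Under permuted labels essentially nothing
   passes the guard, so the final selection is empty or near-empty.
2. *Penalized selection.*  An L1-penalized logistic classifier
   (tumor vs normal) is fitted on the working set; the penalty is chosen by
   stratified 10-fold cross-validation of the binomial deviance at the
   conservative `lambda.1se` rule (configurable to `lambda.min`).  Events
   with nonzero coefficients are kept.
3. *Conditional re-ranking.*  Remaining events are re-ranked by their MI
   with the sign of the working residual of a logistic fit on the kept set
   — association left unexplained by the current selection — and the
   working set (budget: half the head-set size) is refilled.
4. Steps 2–3 repeat until the kept set stabilizes, at most 5 passes.

The classifier AUC is reported from cross-validated (prevalidated) scores
by default; `resubstitution = TRUE` reproduces the optimistic in-sample
variant.  The fold assignment is driven by an explicit seed recorded in the
result, so selections are exactly reproducible.

### Differential TFs and RBPs

Per gene: $\log_2$ fold change of class means with pseudocount 1 (the
mean/pseudocount convention is not dictated by the data format, so it is
fixed and documented here), and a two-sided Wilcoxon rank-sum p-value
(exact for small tie-free samples, normal approximation with tie correction
otherwise), BH-adjusted across genes.  Selection requires
$|\log_2\mathrm{FC}| > 1$ *strictly* and adjusted $p < 0.05$ *strictly*; a
flag (`use_adjusted = FALSE`) switches the threshold to raw p-values for
users who prefer the laxer convention.  Genes constant across all samples
get $p = 1$ by convention.

## Modulation modes

For each significant triplet the tumor samples are split by TF expression
into the bottom and top 40% (sizes $\lfloor 0.4n \rfloor$ each, ties broken
by sample id so the split is deterministic; the middle ~20% is unused), and
the Pearson correlation between $\log_2(x+1)$ RBP expression and PSI is
computed within each stratum.  The pair $(r_{\mathrm{low}},
r_{\mathrm{high}})$ is classified:

| low     | high    | magnitude                 | mode |
|---------|---------|---------------------------|------|
| $-$     | $-$     | $|r_\mathrm{low}| < |r_\mathrm{high}|$ | SAI (strengthens attenuation) |
| $-$     | $-$     | $|r_\mathrm{low}| > |r_\mathrm{high}|$ | WAI (weakens attenuation) |
| $+$     | $+$     | $|r_\mathrm{low}| < |r_\mathrm{high}|$ | SEI (strengthens enhancement) |
| $+$     | $+$     | $|r_\mathrm{low}| > |r_\mathrm{high}|$ | WEI (weakens enhancement) |
| $+$     | $-$     |                           | IPN (inverts positive to negative) |
| $-$     | $+$     |                           | INP (inverts negative to positive) |

A zero correlation in one stratum takes the sign of the other, so a
correlation fading in or out counts as strengthening/weakening — inversion
requires an actual sign change.  Exact equality of the two correlations (a
measure-zero tie) is labelled `UNCHANGED` and excluded from the six-way
partition.  The classifier is total on $[-1,1]^2$ and swapping its
arguments maps SAI↔WAI, SEI↔WEI, IPN↔INP; both properties are tested on a
$10^4$-point grid.  Undefined correlations (constant inputs) are reported,
never silently dropped.

## Survival stratification

Each triplet becomes a risk signature: three univariate Cox
proportional-hazards fits (event PSI; $\log_2(x+1)$ TF expression;
$\log_2(x+1)$ RBP expression — the same transform as the interaction model,
so coefficients and scores live on one scale) give coefficients that weight
the per-sample risk score

$$
RS = \hat\beta_{\mathrm{ASE}}\cdot\mathrm{PSI} +
\hat\beta_{\mathrm{TF}}\cdot x_{\mathrm{TF}} +
\hat\beta_{\mathrm{RBP}}\cdot x_{\mathrm{RBP}}.
$$

Samples are split at the median score (strictly above → high risk; ties at
the median go low, deterministically) and the two groups are compared by
the log-rank test.  Cox fits use Efron tie handling; monotone-likelihood
fits are flagged and their coefficients clipped at ±10.  Each component is
additionally tested alone — both by its own median-split log-rank p and by
its Cox Wald p — so the summary can report how many survival-significant
triplets contain at least one component that is *not* individually
prognostic.  The headline "non-prognostic component" fraction uses the
median-split log-rank check (matching the triplet-level test); the Cox
variant is computed alongside and available in the per-triplet table.  All
fractions are reported as percents rounded to two decimals.

## The synthetic-cohort generator

`generate_cohort()` draws, from a single seed and in a fixed documented
order (clinical covariates, TF expression, RBP expression, PSI random
intercepts, PSI noise, survival):

* **Clinical covariates**: gender; age $\sim N(61, 11)$ clipped to 30–90;
  race with frequencies 70/15/10/5%; diagnosis year 1998–2013; stage
  I–IV (45/10/25/20%) for tumor samples.  Default cohort size is 533
  tumor / 72 normal samples, the scale of a large renal-carcinoma cohort.
* **Expression**: log-normal with per-gene $\log_2$ baselines uniform on
  $[3, 8]$ and unit $\log_2$ dispersion.  Differential expression is an
  additive shift of `de_log2fc` (default 2) $\log_2$ units in tumors with
  alternating sign over the leading `n_de_*` genes.
* **PSI**: on the logistic scale,
  $\eta = \mathrm{intercept} + \mathrm{DE\ shift}\cdot\mathbb{1}_{tumor} +
  \mathrm{covariates} + b_{\mathrm{age}} + b_{\mathrm{race}} +
  b_{\mathrm{year}} + \varepsilon$, and $\mathrm{PSI} = \mathrm{logit}^{-1}(\eta)$.
  Noise enters on the logistic scale *before* the inverse link, which keeps
  PSI in $[0,1]$ with no truncation artifacts.  Differentially spliced
  events shift by `ase_de_logit` (default 2 logit units, the magnitude
  separating tumor/normal mean PSI pairs like 0.8 vs 0.3).  Planted
  triplets add $\beta_1 z_{\mathrm{RBP}} + \beta_2 z_{\mathrm{TF}} +
  \beta_3 z_{\mathrm{RBP}} z_{\mathrm{TF}}$ to the tumor samples of their
  event, with $z$ the z-scored $\log_2(x+1)$ expression — the same
  covariate construction the fitted model uses.  An `"identity"` link
  variant (intercepts mapped through the inverse logit, effects per-unit
  PSI, output clamped) makes the linear model exactly correct for
  parameter-recovery tests.
* **Mode recipes.** Within the outer-40% TF strata the expected RBP slope
  is approximately $\beta_1 \mp 1.14\,\beta_3$ (±1.14 being the mean of a
  standard normal truncated to its outer 40% tails), so `mode_recipe()`
  realizes each of the six modes by sign/magnitude patterns such as
  $\beta_1 = 0.9, \beta_3 = 0.5$ (SEI) or $\beta_1 = 0, \beta_3 = 0.8$
  (INP).  At $n = 2000$ these classify into the intended mode in ≥95% of
  seeds (tested).
* **Survival**: exponential proportional hazards on tumor samples with
  baseline hazard $\log 2 / 1500$ per day (median ~4 years), log-hazard
  equal to the configured linear combination of the first planted triplet's
  components (zero when nothing is planted), and uniform administrative
  censoring between 5 and 10 years.  Normal samples carry `NA` survival.
* `generate_null_cohort()` consumes the identical random stream but omits
  every planted triplet effect, so full and null cohorts differ only in the
  PSI rows of planted events (and, downstream of risk, the tumor survival
  columns) — a clean type-I-error harness.

What the generator does **not** emulate: TCGA-like marginal distributions,
library-size or batch effects, correlated event structure within genes, or
informative censoring.  Passing tests therefore demonstrate the pipeline's
statistical behavior under its own assumptions — calibration, recovery,
classification fidelity — not performance on any particular real cohort.

## Validation conditions and problem sizes

The statistical acceptance checks run at these sizes, chosen to make
Monte-Carlo error small relative to the tested bands while keeping the
default suite to a few minutes:

* interaction type-I error: 10 null cohorts of 300 tumor samples, 500
  combinations each; the rejection rate of the interaction clause must lie
  in $[0.03, 0.07]$;
* planted recovery: 3 triplets ($\beta_3 = 0.8$, noise 0.5) among 200
  combinations at $n = 400$, all three flagged in ≥95% of 20 seeds;
* screening: 5 separating events among 200 noise events at 300
  samples/class, all five ranked into the MI top-50 and selected in ≥90%
  of 20 seeds; label-permuted nulls select ≤2 events in ≥90% of seeds;
* survival: Cox slope recovered within ±0.1 at $n = 1000$; log-rank power
  ≥95% at hazard ratio 3 with $n = 200$; null rejection within
  $[0.02, 0.08]$ over 400 simulations.

`scripts/acceptance.R` re-runs a compact version of the full pipeline from
scratch at a caller-supplied seed and writes every headline quantity as
JSON.

## Known limitations

* The linear model on native PSI is an approximation near the boundaries
  of $[0,1]$; strongly saturated events attenuate the estimated effects
  (the logistic generator makes this visible: recovered coefficients are
  shrunk relative to logit-scale truth, though detection is unaffected at
  the tested sizes).
* The iterative screening step is a reconstruction of the MI-based
  sure-independence-screening family (the guard, re-ranking rule, budget
  and stopping rule are this package's documented choices), not a
  transcription of any specific published variant.
* Per-combination p-values are marginal; with hundreds of thousands of
  combinations the raw-0.05 triple criterion controls neither FWER nor
  FDR.  The BH option exists but is off by default to match the stated
  criterion.
* Univariate Cox coefficients feeding the risk score ignore correlation
  between the three components; the score is a signature, not a fitted
  multivariable model.
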