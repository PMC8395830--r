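# splicemod

Inference of **TF–RBP–splicing-event modulator triplets** from paired
exon-inclusion (PSI) and gene-expression profiles of a tumor/normal cohort.

Alternative-splicing events (ASEs) are proximally regulated by RNA-binding
proteins (RBPs), but an RBP acts on only a context-dependent subset of its
targets — and that context is often set by transcription factors (TFs).
`splicemod` finds combinations (one TF, one RBP, one ASE) in which the TF's
expression level changes how the RBP's expression relates to the event's
PSI, classifies *how* it changes (strengthening, weakening, or inverting a
positive or negative RBP–ASE correlation), and asks whether the triplet's
combined signal stratifies patient survival.

## The model at the core

For each candidate combination, on tumor samples, a linear mixed model is
fitted by maximum likelihood:

```
Y_PSI = β0 + β1·X_RBP + β2·X_TF + β3·X_RBP·X_TF + β4·X_gender + β5·X_stage
        + b_age + b_race + b_year + ε
```

with random intercepts over decade age bins, race and diagnosis year, and
expression covariates on the z-scored log2(x+1) scale.  `β3` is the
modulation effect.  A combination is a **significant triplet** when the
Wald p-values of the RBP, TF and interaction terms are all below 0.05 and
the `β3` estimate is nonzero.  Each significant triplet is then labelled
with one of six modulation modes (SAI, WAI, SEI, WEI, IPN, INP) by
comparing the Pearson correlation of RBP expression and PSI in the bottom
vs top 40% of TF expression, and scored for prognosis via a risk score
weighted by univariate Cox coefficients, a median split and the log-rank
test.

Upstream, cancer-specific events are screened by mutual information with
the tumor/normal label followed by an iterative LASSO refinement
(stratified 10-fold cross-validation, with a G-test marginal-association
guard), and differential TFs/RBPs by |log2FC| > 1 with a BH-adjusted
Wilcoxon rank-sum test.  Everything is driven from plain tab-delimited
tables; a seeded synthetic-cohort generator with planted effects,
modulator triplets and proportional-hazards survival makes the whole
pipeline testable offline.  See the methods vignette
(`vignettes/triplet-modulator-inference.Rmd`) for models, assumptions and
design choices.

## Worked example

```r
library(splicemod)
library(dplyr)

cfg <- cohort_config(
  n_tumor = 300, n_normal = 150, n_tf = 20, n_rbp = 15, n_ase = 60,
  n_de_tf = 6, n_de_rbp = 5, n_de_ase = 4,
  planted_triplets = list(planted_triplet_for_mode("SEI", 1, 1, 1)),
  seed = 2024
)
cohort <- generate_cohort(cfg)

# 1. screen cancer-specific splicing events
screen <- screen_ases(cohort$psi, cohort$clinical, seed = 1)
screen
#> ASE screen: 10 event(s) selected from 50 candidates (2 pass(es))
#> AUC (cross-validated): 1.000

# 2. differential TFs and RBPs
tfs  <- select_de(wilcoxon_de(cohort$tf_expr,  cohort$clinical$class))
rbps <- select_de(wilcoxon_de(cohort$rbp_expr, cohort$clinical$class))

# 3. interaction models + 4. modulation modes
triplets <- enumerate_triplets(cohort$psi, cohort$tf_expr, cohort$rbp_expr,
                               cohort$clinical,
                               tfs = tfs, rbps = rbps,
                               ases = screen$selected) |>
  annotate_modes(cohort$psi, cohort$tf_expr, cohort$rbp_expr, cohort$clinical)
filter(triplets, significant) |>
  select(tf, rbp, event_id, beta3, p_interaction, pcc_low, pcc_high, mode)
#> # A tibble: 1 × 8
#>   tf    rbp    event_id         beta3 p_interaction pcc_low pcc_high mode
#>   <chr> <chr>  <chr>            <dbl>         <dbl>   <dbl>    <dbl> <chr>
#> 1 TF001 RBP001 ASG001_10001_ES 0.0724      3.26e-27   0.545    0.881 SEI

# 5. survival stratification of the significant triplets
summarize_survival(filter(triplets, significant),
                   cohort$psi, cohort$tf_expr, cohort$rbp_expr,
                   cohort$clinical)
#> Triplet survival stratification: 1/1 significant (100.00%);
#>   0/1 with a non-prognostic component (0.00%)

# 6. tripartite network
net <- build_network(triplets)
c(igraph::vcount(net), igraph::ecount(net))
#> [1] 3 3
```

Out of 300 tested combinations, exactly the planted triplet
(TF001, RBP001, ASG001_10001_ES) is flagged: its interaction coefficient
is positive and the RBP–PSI correlation strengthens from 0.55 in the
low-TF stratum to 0.88 in the high-TF stratum, hence the "strengthens
enhancement" (SEI) label — the mode it was planted with.  Its risk score
separates survival because the generator ties the tumor hazard to the
planted components.

Real cohorts enter through `read_psi()` (SpliceSeq-style or simplified
tab-delimited dialects), `read_expression()`, `read_clinical()`,
`read_gene_list()`/`read_ppi()`, with `impute_psi()` (class-mean
imputation), `filter_low_expression()` (strict >50% not-expressed removal)
and `harmonize_samples()` for preprocessing.

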