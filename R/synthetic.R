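mode_labels <- c("SAI", "WAI", "SEI", "WEI", "IPN", "INP")

#' Specify a planted modulator triplet
#'
#' Describes one (TF, RBP, ASE) combination to plant in a synthetic cohort.
#' The generating model for the event's tumor-sample PSI mirrors the fitted
#' interaction model: on the logistic scale the linear predictor is
#' `beta1 * z_rbp + beta2 * z_tf + beta3 * z_rbp * z_tf` where `z_*` are
#' z-scored log2 expression values, plus covariate effects, random
#' intercepts and noise.  `beta3` is the modulation (interaction) effect and
#' must be nonzero.
#'
#' @param tf_index,rbp_index,ase_index 1-based feature indices into the
#'   generated TF, RBP and ASE panels.
#' @param beta1,beta2,beta3 generating fixed effects for the RBP, the TF and
#'   their interaction (logit-PSI units per standard deviation).
#' @param intended_mode optional expected modulation mode, one of
#'   `r paste(mode_labels, collapse = ", ")`; see [mode_recipe()] for
#'   coefficient patterns that realize each mode.
#' @return An object of class `triplet_spec`.
#' @export
triplet_spec <- function(tf_index, rbp_index, ase_index,
                         beta1 = 0.8, beta2 = 0.5, beta3 = 0.8,
                         intended_mode = NULL) {
  stopifnot(
    length(tf_index) == 1L, length(rbp_index) == 1L, length(ase_index) == 1L,
    tf_index >= 1, rbp_index >= 1, ase_index >= 1
  )
  if (!is.null(intended_mode)) {
    intended_mode <- match.arg(intended_mode, mode_labels)
  }
  if (beta3 == 0) rlang::abort("planted triplets must have `beta3` != 0")
  structure(
    list(
      tf_index = as.integer(tf_index), rbp_index = as.integer(rbp_index),
      ase_index = as.integer(ase_index),
      beta1 = beta1, beta2 = beta2, beta3 = beta3,
      intended_mode = intended_mode %||% NA_character_
    ),
    class = "triplet_spec"
  )
}

#' Coefficient recipes for the six modulation modes
#'
#' Returns generating coefficients whose large-sample stratified
#' correlations fall in the target mode.  Within the bottom/top 40% TF
#' strata the expected RBP slope is approximately `beta1 -/+ 1.14 * beta3`
#' (the mean of a standard normal truncated to its outer 40% tails is about
#' ±1.14), so sign and magnitude of `beta1` and `beta3` pick the mode:
#' e.g. `beta1 = 0.9, beta3 = 0.5` gives a positive correlation that
#' strengthens from the low- to the high-TF group (SEI).
#'
#' @param mode one of `r paste(mode_labels, collapse = ", ")`.
#' @return A list with elements `beta1`, `beta2`, `beta3`.
#' @export
mode_recipe <- function(mode) {
  mode <- match.arg(mode, mode_labels)
  switch(mode,
    SEI = list(beta1 = 0.9, beta2 = 0.5, beta3 = 0.5),
    WEI = list(beta1 = 0.9, beta2 = 0.5, beta3 = -0.5),
    SAI = list(beta1 = -0.9, beta2 = 0.5, beta3 = -0.5),
    WAI = list(beta1 = -0.9, beta2 = 0.5, beta3 = 0.5),
    INP = list(beta1 = 0, beta2 = 0.5, beta3 = 0.8),
    IPN = list(beta1 = 0, beta2 = 0.5, beta3 = -0.8)
  )
}

#' @rdname mode_recipe
#' @inheritParams triplet_spec
#' @export
planted_triplet_for_mode <- function(mode, tf_index, rbp_index, ase_index) {
  r <- mode_recipe(mode)
  triplet_spec(tf_index, rbp_index, ase_index,
               beta1 = r$beta1, beta2 = r$beta2, beta3 = r$beta3,
               intended_mode = mode)
}

#' Configure a synthetic tumor/normal cohort
#'
#' Defines the generating conditions for [generate_cohort()].  Defaults
#' emulate a large renal-carcinoma-style cohort (533 tumor / 72 normal
#' samples) at desk-scale feature counts: log-normal expression with a
#' subset of differentially expressed TFs and RBPs (additive log2-scale
#' shift `de_log2fc`), logit-scale PSI with differentially spliced events
#' (logit shift `ase_de_logit`), optional planted modulator triplets, random
#' intercepts over decade age groups, race and diagnosis year, and
#' exponential proportional-hazards survival whose log-hazard is a linear
#' combination of the first planted triplet's components.
#'
#' @param n_tumor,n_normal sample counts.
#' @param n_tf,n_rbp,n_ase feature counts.
#' @param n_de_tf,n_de_rbp,n_de_ase planted differentially
#'   expressed/spliced feature counts (the leading features of each panel,
#'   with alternating direction).
#' @param de_log2fc expression effect size, log2 units.
#' @param ase_de_logit splicing effect size, logit-PSI units.
#' @param planted_triplets list of [triplet_spec()] objects.
#' @param noise_sd residual standard deviation on the logit-PSI scale.
#' @param random_effect_sds named length-3 vector of random-intercept
#'   standard deviations for `age_group`, `race`, `year` (logit-PSI units).
#' @param gender_effect,stage_effect fixed covariate effects on logit PSI
#'   (male indicator; stage number 1--4, 0 for normal samples).
#' @param link `"logistic"` squashes the linear predictor through
#'   `plogis()`; `"identity"` uses it directly (clamped to \[0, 1\]), which
#'   makes the linear fitted model exactly correct and is used for
#'   parameter-recovery checks.
#' @param baseline_hazard exponential baseline hazard (per day).
#' @param risk_betas named length-3 vector of log-hazard weights for the
#'   first planted triplet's PSI, TF and RBP components.
#' @param censor_time upper bound (days) of the uniform censoring window.
#' @param seed integer seed; the full cohort is a deterministic function of
#'   the configuration.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_tumor = 533, n_normal = 72,
                          n_tf = 60, n_rbp = 40, n_ase = 50,
                          n_de_tf = 20, n_de_rbp = 15, n_de_ase = 10,
                          de_log2fc = 2, ase_de_logit = 2,
                          planted_triplets = list(),
                          noise_sd = 0.5,
                          random_effect_sds = c(age_group = 0.1, race = 0.1,
                                                year = 0.1),
                          gender_effect = 0.1, stage_effect = 0.1,
                          link = c("logistic", "identity"),
                          baseline_hazard = log(2) / 1500,
                          risk_betas = c(ase = 0.5, tf = 0.5, rbp = 0.5),
                          censor_time = 3650,
                          seed = 1L) {
  link <- match.arg(link)
  counts <- c(n_tumor = n_tumor, n_normal = n_normal, n_tf = n_tf,
              n_rbp = n_rbp, n_ase = n_ase)
  if (any(counts < 1)) rlang::abort("all sample/feature counts must be >= 1")
  if (n_de_tf > n_tf || n_de_rbp > n_rbp || n_de_ase > n_ase) {
    rlang::abort("planted-DE counts cannot exceed feature counts")
  }
  if (noise_sd < 0 || any(random_effect_sds < 0)) {
    rlang::abort("`noise_sd` and `random_effect_sds` must be non-negative")
  }
  stopifnot(length(random_effect_sds) == 3L, length(risk_betas) == 3L,
            baseline_hazard > 0, censor_time > 0)
  for (sp in planted_triplets) {
    if (!inherits(sp, "triplet_spec")) {
      rlang::abort("`planted_triplets` must be a list of triplet_spec objects")
    }
    if (sp$tf_index > n_tf || sp$rbp_index > n_rbp || sp$ase_index > n_ase) {
      rlang::abort(sprintf(
        "triplet_spec indices (%d, %d, %d) exceed the configured panel sizes",
        sp$tf_index, sp$rbp_index, sp$ase_index
      ))
    }
  }
  structure(
    list(
      n_tumor = as.integer(n_tumor), n_normal = as.integer(n_normal),
      n_tf = as.integer(n_tf), n_rbp = as.integer(n_rbp),
      n_ase = as.integer(n_ase),
      n_de_tf = as.integer(n_de_tf), n_de_rbp = as.integer(n_de_rbp),
      n_de_ase = as.integer(n_de_ase),
      de_log2fc = de_log2fc, ase_de_logit = ase_de_logit,
      planted_triplets = planted_triplets,
      noise_sd = noise_sd,
      random_effect_sds = setNames(as.numeric(random_effect_sds),
                                   c("age_group", "race", "year")),
      gender_effect = gender_effect, stage_effect = stage_effect,
      link = link,
      baseline_hazard = baseline_hazard,
      risk_betas = setNames(as.numeric(risk_betas), c("ase", "tf", "rbp")),
      censor_time = censor_time,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Generate a synthetic cohort
#'
#' Draws a complete cohort from a [cohort_config()]: TF and RBP expression
#' tables, a PSI table, a clinical table and a `synthetic_truth` record of
#' everything that was planted.  `generate_null_cohort()` draws the same
#' random numbers in the same order but omits every planted triplet effect,
#' so the two cohorts are identical except in the PSI rows of planted
#' events (a type-I-error harness for the interaction test).
#'
#' Random draws follow a fixed documented order (clinical covariates, TF
#' expression, RBP expression, PSI random intercepts, PSI noise, survival),
#' so the output is a pure function of the configuration.
#'
#' @param config a [cohort_config()].
#' @return A list of class `splice_cohort` with elements `tf_expr`,
#'   `rbp_expr`, `psi`, `clinical`, `truth` and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  generate_cohort_impl(config, include_planted = TRUE)
}

#' @rdname generate_cohort
#' @export
generate_null_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  generate_cohort_impl(config, include_planted = FALSE)
}

generate_cohort_impl <- function(cfg, include_planted) {
  set.seed(cfg$seed)
  n_t <- cfg$n_tumor
  n_n <- cfg$n_normal
  n <- n_t + n_n
  sample_id <- c(sprintf("T%04d", seq_len(n_t)), sprintf("N%04d", seq_len(n_n)))
  is_tumor <- c(rep(TRUE, n_t), rep(FALSE, n_n))

  ## clinical covariates
  gender <- sample(c("female", "male"), n, replace = TRUE)
  age <- pmin(pmax(round(rnorm(n, 61, 11)), 30), 90)
  race <- sample(c("white", "black", "asian", "other"), n, replace = TRUE,
                 prob = c(0.70, 0.15, 0.10, 0.05))
  year <- sample(1998:2013, n, replace = TRUE)
  stage_num <- ifelse(is_tumor,
                      sample(1:4, n, replace = TRUE,
                             prob = c(0.45, 0.10, 0.25, 0.20)),
                      NA_integer_)
  stage <- c("I", "II", "III", "IV")[stage_num]
  age_group <- paste0("age", age %/% 10, "0s")

  ## expression panels: log-normal, DE = additive log2 shift in tumors
  gen_expr <- function(n_genes, n_de, prefix) {
    genes <- sprintf("%s%03d", prefix, seq_len(n_genes))
    mu <- runif(n_genes, 3, 8)
    lx <- matrix(rnorm(n_genes * n, sd = 1), n_genes, n) + mu
    de_idx <- seq_len(n_de)
    de_sign <- rep_len(c(1, -1), n_de)
    if (n_de > 0) {
      lx[de_idx, is_tumor] <- lx[de_idx, is_tumor] +
        de_sign * cfg$de_log2fc
    }
    m <- 2^lx
    dimnames(m) <- list(genes, sample_id)
    list(m = m, de = tibble::tibble(gene = genes[de_idx],
                                    direction = de_sign))
  }
  tf <- gen_expr(cfg$n_tf, cfg$n_de_tf, "TF")
  rbp <- gen_expr(cfg$n_rbp, cfg$n_de_rbp, "RBP")

  ## splicing events
  ase_ids <- format_ase_id(sprintf("ASG%03d", seq_len(cfg$n_ase)),
                           10000L + seq_len(cfg$n_ase),
                           rep_len(ase_types, cfg$n_ase))
  intercept <- runif(cfg$n_ase, -1.5, 1.5)
  de_shift <- numeric(cfg$n_ase)
  if (cfg$n_de_ase > 0) {
    de_shift[seq_len(cfg$n_de_ase)] <-
      rep_len(c(1, -1), cfg$n_de_ase) * cfg$ase_de_logit
  }

  ## random intercepts over the three grouping factors, independent per event
  re_sum <- matrix(0, cfg$n_ase, n)
  groups <- list(age_group = age_group, race = race, year = as.character(year))
  for (g in names(groups)) {
    lev <- unique(groups[[g]])
    eff <- matrix(rnorm(cfg$n_ase * length(lev),
                        sd = cfg$random_effect_sds[[g]]),
                  cfg$n_ase, length(lev), dimnames = list(NULL, lev))
    re_sum <- re_sum + eff[, groups[[g]], drop = FALSE]
  }

  noise <- matrix(rnorm(cfg$n_ase * n, sd = cfg$noise_sd), cfg$n_ase, n)

  covar <- cfg$gender_effect * (gender == "male") +
    cfg$stage_effect * dplyr::coalesce(stage_num, 0L)
  # identity link works on the probability scale directly, so the baseline
  # is mapped through plogis and the effects are per-unit PSI
  base_level <- if (cfg$link == "identity") plogis(intercept) else intercept
  eta <- base_level + outer(de_shift, as.numeric(is_tumor)) + re_sum + noise +
    matrix(covar, cfg$n_ase, n, byrow = TRUE)

  ## planted triplet effects (tumor samples; z-scores over tumor samples)
  tumor_z <- function(m, i) zscore(log2p1(m[i, is_tumor]))
  planted <- if (include_planted) cfg$planted_triplets else list()
  for (sp in planted) {
    zt <- tumor_z(tf$m, sp$tf_index)
    zr <- tumor_z(rbp$m, sp$rbp_index)
    eta[sp$ase_index, is_tumor] <- eta[sp$ase_index, is_tumor] +
      sp$beta1 * zr + sp$beta2 * zt + sp$beta3 * zr * zt
  }

  psi <- if (cfg$link == "logistic") plogis(eta) else pmin(pmax(eta, 0), 1)
  dimnames(psi) <- list(ase_ids, sample_id)

  ## survival: exponential PH, log-hazard from the first planted triplet
  latent_risk <- rep(0, n_t)
  if (length(planted)) {
    sp <- planted[[1]]
    latent_risk <- cfg$risk_betas[["ase"]] * psi[sp$ase_index, is_tumor] +
      cfg$risk_betas[["tf"]] * tumor_z(tf$m, sp$tf_index) +
      cfg$risk_betas[["rbp"]] * tumor_z(rbp$m, sp$rbp_index)
  }
  u <- runif(n_t)
  ev_time <- -log(u) / (cfg$baseline_hazard * exp(latent_risk - mean(latent_risk)))
  cens <- runif(n_t, cfg$censor_time / 2, cfg$censor_time)
  os_time <- rep(NA_real_, n)
  os_event <- rep(NA_integer_, n)
  os_time[is_tumor] <- pmin(ev_time, cens)
  os_event[is_tumor] <- as.integer(ev_time <= cens)

  clinical <- tibble::tibble(
    sample_id = sample_id, class = ifelse(is_tumor, "tumor", "normal"),
    gender = gender, stage = stage, age = age, race = race, year = year,
    os_time = round(os_time, 1), os_event = os_event
  )

  planted_tbl <- purrr::map_dfr(cfg$planted_triplets, function(sp) {
    tibble::tibble(
      tf = rownames(tf$m)[sp$tf_index], rbp = rownames(rbp$m)[sp$rbp_index],
      event_id = ase_ids[sp$ase_index],
      tf_index = sp$tf_index, rbp_index = sp$rbp_index,
      ase_index = sp$ase_index,
      beta1 = sp$beta1, beta2 = sp$beta2, beta3 = sp$beta3,
      intended_mode = sp$intended_mode
    )
  })

  truth <- structure(
    list(
      planted = planted_tbl,
      planted_active = include_planted && length(cfg$planted_triplets) > 0,
      de_tf = tf$de, de_rbp = rbp$de,
      de_ase = tibble::tibble(event_id = ase_ids[seq_len(cfg$n_de_ase)],
                              logit_shift = de_shift[seq_len(cfg$n_de_ase)]),
      ase_params = tibble::tibble(event_id = ase_ids, intercept = base_level,
                                  de_logit_shift = de_shift),
      risk = tibble::tibble(sample_id = sample_id[is_tumor],
                            latent_risk = as.numeric(latent_risk))
    ),
    class = "synthetic_truth"
  )

  structure(
    list(
      tf_expr = matrix_to_tbl(tf$m, "gene"),
      rbp_expr = matrix_to_tbl(rbp$m, "gene"),
      psi = matrix_to_tbl(psi, "event_id"),
      clinical = clinical,
      truth = truth,
      config = cfg
    ),
    class = "splice_cohort"
  )
}

#' Write a synthetic cohort to tab-delimited files
#'
#' Emits the same dialects the readers accept (`psi.tsv`, `tf_expr.tsv`,
#' `rbp_expr.tsv`, `clinical.tsv`) plus `truth_planted.tsv` documenting the
#' planted structure.
#'
#' @param cohort a `splice_cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "splice_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("psi.tsv", "tf_expr.tsv", "rbp_expr.tsv",
                            "clinical.tsv", "truth_planted.tsv"))
  readr::write_tsv(cohort$psi, paths[1], progress = FALSE)
  readr::write_tsv(cohort$tf_expr, paths[2], progress = FALSE)
  readr::write_tsv(cohort$rbp_expr, paths[3], progress = FALSE)
  readr::write_tsv(cohort$clinical, paths[4], progress = FALSE)
  readr::write_tsv(cohort$truth$planted, paths[5], progress = FALSE)
  invisible(paths)
}

#' Simulate single-covariate proportional-hazards survival data
#'
#' Exponential event times with log-hazard `coef * feature` for a standard
#' normal feature, with uniform censoring on `(0, censor_time)`.  Used to
#' validate Cox-coefficient recovery and log-rank power.
#'
#' @param n sample count.
#' @param coef true log-hazard slope per unit of the feature.
#' @param baseline_hazard exponential baseline hazard.
#' @param censor_time upper censoring bound.
#' @param seed optional integer seed.
#' @return A tibble with columns `feature`, `os_time`, `os_event`.
#' @export
simulate_ph <- function(n, coef = 0.7, baseline_hazard = 0.002,
                        censor_time = 2000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- rnorm(n)
  ev <- rexp(n, baseline_hazard * exp(coef * x))
  cens <- runif(n, 0, censor_time)
  tibble::tibble(
    feature = x,
    os_time = pmin(ev, cens),
    os_event = as.integer(ev <= cens)
  )
}
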