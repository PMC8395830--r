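#' Assemble the per-sample model frame for one triplet
#'
#' Joins one splicing event's PSI row with one RBP and one TF expression row
#' and the clinical covariates, restricted to the fitting cohort.  RBP and
#' TF expression are log2(x+1)-transformed and z-scored across the fitting
#' samples (stabilizes Wald tests across expression scales); PSI stays on
#' its native \[0, 1\] scale.  Age is discretized into decade bins and year
#' of diagnosis is kept as a factor so both can index random intercepts.
#' Samples missing any model covariate are dropped with a message.
#'
#' @param psi_row,rbp_row,tf_row numeric vectors named by sample id.
#' @param clinical clinical tibble.
#' @param cohort `"tumor"` (default; modulator inference runs on the tumor
#'   cohort, where stage and survival exist) or `"all"`.
#' @return A tibble with columns `sample_id`, `psi`, `rbp`, `tf`, `gender`,
#'   `stage`, `age_group`, `race`, `year`.
#' @export
assemble_triplet_data <- function(psi_row, rbp_row, tf_row, clinical,
                                  cohort = c("tumor", "all")) {
  cohort <- match.arg(cohort)
  keep <- if (cohort == "tumor") clinical$class == "tumor" else
    rep(TRUE, nrow(clinical))
  clin <- clinical[keep, ]
  ids <- Reduce(intersect, list(clin$sample_id, names(psi_row),
                                names(rbp_row), names(tf_row)))
  if (!length(ids)) rlang::abort("no shared samples across inputs")
  clin <- clin[match(ids, clin$sample_id), ]
  df <- tibble::tibble(
    sample_id = ids,
    psi = as.numeric(psi_row[ids]),
    rbp = zscore(log2p1(as.numeric(rbp_row[ids]))),
    tf = zscore(log2p1(as.numeric(tf_row[ids]))),
    gender = factor(clin$gender),
    stage = factor(clin$stage),
    age_group = factor(paste0("age", clin$age %/% 10, "0s")),
    race = factor(clin$race),
    year = factor(clin$year)
  )
  complete <- stats::complete.cases(df)
  if (any(!complete)) {
    rlang::inform(sprintf(
      "assemble_triplet_data: dropped %d sample(s) with missing covariates",
      sum(!complete)
    ))
  }
  df[complete, ]
}

fixed_terms_for <- function(df) {
  extras <- c("gender", "stage")
  extras[vapply(extras, function(v) nlevels(droplevels(df[[v]])) >= 2L,
                logical(1))]
}

# core fitter shared by fit_triplet_lmm() and enumerate_triplets();
# assumes a complete-case model frame
fit_lmm_core <- function(df, random_effects, min_n = 30) {
  n <- nrow(df)
  if (n < min_n) {
    rlang::abort(sprintf("need at least %d complete samples (have %d)",
                         min_n, n))
  }
  terms_main <- c("(Intercept)", "rbp", "tf", "rbp:tf")
  empty_coefs <- tibble::tibble(
    term = terms_main,
    estimate = c(NA, 0, 0, 0),
    std_error = NA_real_, statistic = NA_real_, p_value = NA_real_
  )
  if (sd(df$psi) == 0) {
    return(new_triplet_lmm(empty_coefs, re_variances = numeric(0),
                           sigma = 0, converged = TRUE, degenerate = TRUE,
                           n = n, dropped_re = character(0),
                           formula = "psi ~ constant"))
  }
  fixed <- c("rbp * tf", fixed_terms_for(df))
  re_use <- random_effects[vapply(random_effects, function(v) {
    nlevels(droplevels(df[[v]])) >= 2L
  }, logical(1))]
  dropped_re <- setdiff(random_effects, re_use)

  if (!length(re_use)) {
    form <- stats::as.formula(paste("psi ~", paste(fixed, collapse = " + ")))
    fit <- stats::lm(form, data = df)
    sm <- summary(fit)$coefficients
    coefs <- tibble::tibble(
      term = rownames(sm), estimate = unname(sm[, 1]),
      std_error = unname(sm[, 2]), statistic = unname(sm[, 3]),
      p_value = unname(sm[, 4])
    )
    return(new_triplet_lmm(coefs, re_variances = setNames(numeric(0), NULL),
                           sigma = summary(fit)$sigma, converged = TRUE,
                           degenerate = FALSE, n = n, dropped_re = dropped_re,
                           formula = deparse(form)))
  }

  form <- stats::as.formula(paste(
    "psi ~", paste(fixed, collapse = " + "), "+",
    paste(sprintf("(1 | %s)", re_use), collapse = " + ")
  ))
  converged <- TRUE
  fit <- withCallingHandlers(
    tryCatch(
      lme4::lmer(form, data = df, REML = FALSE,
                 control = lme4::lmerControl(calc.derivs = FALSE)),
      error = function(e) e
    ),
    warning = function(w) {
      converged <<- FALSE
      invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage")
  )
  if (inherits(fit, "error")) {
    return(new_triplet_lmm(empty_coefs, re_variances = numeric(0),
                           sigma = NA_real_, converged = FALSE,
                           degenerate = FALSE, n = n, dropped_re = dropped_re,
                           formula = deparse(form)))
  }
  extract_mermod(fit, converged = converged, n = n, dropped_re = dropped_re,
                 formula = paste(deparse(form), collapse = " "))
}

# Wald summaries from a fitted merMod: two-sided t with n - p df
extract_mermod <- function(fit, converged, n, dropped_re, formula) {
  beta <- lme4::fixef(fit)
  se <- sqrt(Matrix::diag(stats::vcov(fit)))
  tval <- beta / se
  dfree <- n - length(beta)
  pval <- 2 * pt(-abs(tval), df = dfree)
  vc <- lme4::VarCorr(fit)
  re_var <- vapply(vc, function(v) as.numeric(v[1, 1]), numeric(1))
  coefs <- tibble::tibble(
    term = names(beta), estimate = as.numeric(beta), std_error = as.numeric(se),
    statistic = as.numeric(tval), p_value = as.numeric(pval)
  )
  new_triplet_lmm(coefs, re_variances = re_var,
                  sigma = stats::sigma(fit), converged = converged,
                  degenerate = FALSE, n = n, dropped_re = dropped_re,
                  formula = formula)
}

# Fast fitter for repeated fits on one cohort: the clinical design and
# random-effects structure are parsed once (lme4 modular interface); each
# call swaps in a new response and the three substantive design columns.
# Produces the same ML fit as fit_lmm_core() on the same data.
make_lmm_engine <- function(base_df, random_effects, min_n = 30) {
  n <- nrow(base_df)
  if (n < min_n) {
    rlang::abort(sprintf("need at least %d complete samples (have %d)",
                         min_n, n))
  }
  # deterministic non-constant placeholders (no RNG use): only the design
  # *structure* matters here, values are swapped per call
  template <- base_df
  template$psi <- seq_len(n) / n
  template$rbp <- seq_len(n) / n - 0.5
  template$tf <- ((seq_len(n) * 7L) %% n) / n - 0.5
  re_use <- random_effects[vapply(random_effects, function(v) {
    nlevels(droplevels(template[[v]])) >= 2L
  }, logical(1))]

  if (!length(re_use)) {
    return(function(y, rbp, tf) {
      df <- template
      df$psi <- y; df$rbp <- rbp; df$tf <- tf
      fit_lmm_core(df, random_effects, min_n = min_n)
    })
  }

  dropped_re <- setdiff(random_effects, re_use)
  fixed <- c("rbp * tf", fixed_terms_for(template))
  form <- stats::as.formula(paste(
    "psi ~", paste(fixed, collapse = " + "), "+",
    paste(sprintf("(1 | %s)", re_use), collapse = " + ")
  ))
  ctrl <- lme4::lmerControl(calc.derivs = FALSE)
  lf <- suppressMessages(
    lme4::lFormula(form, data = template, REML = FALSE, control = ctrl)
  )
  form_chr <- paste(deparse(form), collapse = " ")
  terms_main <- c("(Intercept)", "rbp", "tf", "rbp:tf")
  empty_coefs <- tibble::tibble(
    term = terms_main, estimate = c(NA, 0, 0, 0),
    std_error = NA_real_, statistic = NA_real_, p_value = NA_real_
  )

  function(y, rbp, tf) {
    if (sd(y) == 0) {
      return(new_triplet_lmm(empty_coefs, re_variances = numeric(0),
                             sigma = 0, converged = TRUE, degenerate = TRUE,
                             n = n, dropped_re = character(0),
                             formula = "psi ~ constant"))
    }
    lf$fr[["psi"]] <- y
    lf$X[, "rbp"] <- rbp
    lf$X[, "tf"] <- tf
    lf$X[, "rbp:tf"] <- rbp * tf
    converged <- TRUE
    fit <- withCallingHandlers(
      tryCatch({
        devfun <- do.call(lme4::mkLmerDevfun, lf)
        opt <- lme4::optimizeLmer(devfun, optimizer = "nloptwrap")
        lme4::mkMerMod(environment(devfun), opt, lf$reTrms, fr = lf$fr)
      }, error = function(e) e),
      warning = function(w) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      },
      message = function(m) invokeRestart("muffleMessage")
    )
    if (inherits(fit, "error")) {
      return(new_triplet_lmm(empty_coefs, re_variances = numeric(0),
                             sigma = NA_real_, converged = FALSE,
                             degenerate = FALSE, n = n,
                             dropped_re = dropped_re, formula = form_chr))
    }
    extract_mermod(fit, converged = converged, n = n, dropped_re = dropped_re,
                   formula = form_chr)
  }
}

new_triplet_lmm <- function(coefficients, re_variances, sigma, converged,
                            degenerate, n, dropped_re, formula) {
  structure(
    list(coefficients = coefficients, re_variances = re_variances,
         sigma = sigma, converged = converged, degenerate = degenerate,
         n = n, dropped_re = dropped_re, formula = formula),
    class = "triplet_lmm"
  )
}

#' Fit the triplet interaction model to one (TF, RBP, ASE) combination
#'
#' Fits, by maximum likelihood, the linear mixed model
#' `psi ~ rbp * tf + gender + stage + (1 | age_group) + (1 | race) +
#' (1 | year)` on the assembled model frame (see
#' [assemble_triplet_data()]).  Wald two-sided p-values use the t
#' distribution with `n - p` degrees of freedom, where `p` is the number of
#' fixed-effect columns.  Grouping factors with a single level are dropped
#' from the random effects (recorded in the fit); when no usable grouping
#' factor remains the model reduces to ordinary least squares with
#' classical t tests, and in that limit the two routes agree exactly.  A
#' constant PSI row yields a degenerate fit (all substantive effects 0,
#' never significant); optimizer warnings mark the fit as non-converged
#' rather than dropping it.
#'
#' @param data model frame from [assemble_triplet_data()] (columns `psi`,
#'   `rbp`, `tf`, `gender`, `stage`, `age_group`, `race`, `year`).
#' @param random_effects character vector of grouping factors to model as
#'   random intercepts; use `character(0)` for a pure fixed-effects (OLS)
#'   fit.
#' @param min_n minimum complete-sample count.
#' @return An object of class `triplet_lmm` with a broom-style
#'   `coefficients` tibble, random-intercept variances, residual sigma and
#'   convergence flags.  See [tidy.triplet_lmm()].
#' @export
fit_triplet_lmm <- function(data,
                            random_effects = c("age_group", "race", "year"),
                            min_n = 30) {
  needed <- c("psi", "rbp", "tf", "gender", "stage", random_effects)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    rlang::abort(paste0("`data` is missing columns: ",
                        paste(missing_cols, collapse = ", ")))
  }
  fit_lmm_core(data[stats::complete.cases(data[, needed]), ],
               random_effects, min_n = min_n)
}

lmm_term <- function(fit, term, what = "p_value") {
  co <- fit$coefficients
  i <- match(term, co$term)
  if (is.na(i)) NA_real_ else co[[what]][i]
}

#' Triple-significance decision for a fitted triplet model
#'
#' A combination is significant when the RBP, TF and RBP-by-TF interaction
#' p-values are all strictly below `alpha` *and* the interaction estimate
#' is nonzero (an exact test on the estimate; with continuous data this is
#' almost surely true, so the interaction p-value is the binding clause).
#' Non-converged or degenerate fits are never significant.
#'
#' @param fit a `triplet_lmm`.
#' @param alpha significance level (default 0.05).
#' @return Logical scalar.
#' @export
triplet_significant <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "triplet_lmm"))
  if (!fit$converged || fit$degenerate) return(FALSE)
  p <- vapply(c("rbp", "tf", "rbp:tf"), lmm_term, numeric(1), fit = fit)
  b3 <- lmm_term(fit, "rbp:tf", "estimate")
  !anyNA(p) && all(p < alpha) && !is.na(b3) && b3 != 0
}

#' @export
print.triplet_lmm <- function(x, ...) {
  cat("Triplet interaction model (", if (x$converged) "converged" else
    "NOT converged", if (x$degenerate) ", degenerate" else "", "), n = ",
    x$n, "\n", sep = "")
  print(x$coefficients)
  if (length(x$re_variances)) {
    cat("Random-intercept variances:\n")
    print(x$re_variances)
  }
  invisible(x)
}

#' Tidy triplet-model fits
#'
#' `tidy()` returns the fixed-effect coefficient table; `glance()` a
#' one-row fit summary including random-intercept variances.
#'
#' @param x a `triplet_lmm`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.triplet_lmm <- function(x, ...) x$coefficients

#' @rdname tidy.triplet_lmm
#' @exportS3Method generics::glance
glance.triplet_lmm <- function(x, ...) {
  out <- tibble::tibble(
    n = x$n, sigma = x$sigma, converged = x$converged,
    degenerate = x$degenerate,
    dropped_random_effects = paste(x$dropped_re, collapse = ",")
  )
  for (nm in names(x$re_variances)) {
    out[[paste0("var_", nm)]] <- x$re_variances[[nm]]
  }
  out
}

#' Fit the interaction model over a grid of combinations
#'
#' Enumerates every (TF, RBP, ASE) combination from the supplied feature
#' sets in deterministic lexicographic order, fits the interaction model on
#' the shared fitting cohort and applies the triple-significance decision.
#' Combinations where the TF and RBP are the same gene symbol are skipped
#' (reported via a message).  Clinical covariates and expression z-scores
#' are prepared once, so large grids stay affordable.
#'
#' @param psi,tf_expr,rbp_expr wide tables (first column = feature id).
#' @param clinical clinical tibble.
#' @param tfs,rbps,ases feature subsets to cross; default all rows.
#' @param cohort fitting cohort, `"tumor"` (default) or `"all"`.
#' @param random_effects grouping factors for random intercepts.
#' @param alpha per-term significance level.
#' @param adjust apply Benjamini-Hochberg adjustment to each term's
#'   p-values across combinations before the significance decision
#'   (off by default, matching the raw-0.05 criterion).
#' @param min_n minimum complete-sample count per fit.
#' @return A tibble with one row per combination: `tf`, `rbp`, `event_id`,
#'   the four substantive estimates, the three substantive p-values,
#'   `converged`, `degenerate`, `significant`.
#' @export
enumerate_triplets <- function(psi, tf_expr, rbp_expr, clinical,
                               tfs = NULL, rbps = NULL, ases = NULL,
                               cohort = c("tumor", "all"),
                               random_effects = c("age_group", "race", "year"),
                               alpha = 0.05, adjust = FALSE, min_n = 30) {
  cohort <- match.arg(cohort)
  tf_m <- feature_matrix(tf_expr)
  rbp_m <- feature_matrix(rbp_expr)
  psi_m <- feature_matrix(psi)
  tfs <- sort(tfs %||% rownames(tf_m))
  rbps <- sort(rbps %||% rownames(rbp_m))
  ases <- sort(ases %||% rownames(psi_m))
  check_subset <- function(x, pool, what) {
    bad <- setdiff(x, pool)
    if (length(bad)) {
      rlang::abort(paste0("unknown ", what, ": ", paste(bad, collapse = ", ")))
    }
  }
  check_subset(tfs, rownames(tf_m), "TFs")
  check_subset(rbps, rownames(rbp_m), "RBPs")
  check_subset(ases, rownames(psi_m), "events")

  keep <- if (cohort == "tumor") clinical$class == "tumor" else
    rep(TRUE, nrow(clinical))
  clin <- clinical[keep, ]
  ids <- Reduce(intersect, list(clin$sample_id, colnames(psi_m),
                                colnames(tf_m), colnames(rbp_m)))
  clin <- clin[match(ids, clin$sample_id), ]
  base_df <- tibble::tibble(
    gender = factor(clin$gender),
    stage = factor(clin$stage),
    age_group = factor(paste0("age", clin$age %/% 10, "0s")),
    race = factor(clin$race),
    year = factor(clin$year)
  )
  complete <- stats::complete.cases(base_df)
  if (any(!complete)) {
    rlang::inform(sprintf(
      "enumerate_triplets: dropped %d sample(s) with missing covariates",
      sum(!complete)
    ))
  }
  base_df <- base_df[complete, ]
  ids <- ids[complete]

  zrows <- function(m, feats) {
    sub <- log2p1(m[feats, ids, drop = FALSE])
    t(apply(sub, 1L, zscore))
  }
  tf_z <- zrows(tf_m, tfs)
  rbp_z <- zrows(rbp_m, rbps)
  psi_sub <- psi_m[ases, ids, drop = FALSE]

  grid <- tidyr::expand_grid(tf = tfs, rbp = rbps, event_id = ases)
  same <- grid$tf == grid$rbp
  if (any(same)) {
    rlang::inform(sprintf(
      "enumerate_triplets: skipped %d combination(s) where TF and RBP share a symbol",
      sum(same)
    ))
    grid <- grid[!same, ]
  }

  engine <- make_lmm_engine(base_df, random_effects, min_n = min_n)
  fits <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    fits[[i]] <- engine(psi_sub[grid$event_id[i], ],
                        rbp_z[grid$rbp[i], ],
                        tf_z[grid$tf[i], ])
  }

  out <- dplyr::bind_cols(grid, purrr::map_dfr(fits, function(f) {
    tibble::tibble(
      beta0 = lmm_term(f, "(Intercept)", "estimate"),
      beta1 = lmm_term(f, "rbp", "estimate"),
      beta2 = lmm_term(f, "tf", "estimate"),
      beta3 = lmm_term(f, "rbp:tf", "estimate"),
      p_rbp = lmm_term(f, "rbp"),
      p_tf = lmm_term(f, "tf"),
      p_interaction = lmm_term(f, "rbp:tf"),
      converged = f$converged,
      degenerate = f$degenerate
    )
  }))
  if (adjust) {
    out <- dplyr::mutate(out, dplyr::across(
      c("p_rbp", "p_tf", "p_interaction"),
      ~ stats::p.adjust(.x, method = "BH")
    ))
  }
  out$significant <- !is.na(out$p_rbp) & !is.na(out$p_tf) &
    !is.na(out$p_interaction) &
    out$p_rbp < alpha & out$p_tf < alpha & out$p_interaction < alpha &
    !is.na(out$beta3) & out$beta3 != 0 & out$converged & !out$degenerate
  out
}
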