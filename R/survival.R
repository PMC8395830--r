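#' Univariate Cox regression coefficient
#'
#' Fits a single-covariate Cox proportional-hazards model by partial
#' likelihood (Efron tie handling) and returns the log-hazard coefficient
#' per unit of the feature.  Monotone-likelihood fits (perfect separation)
#' are flagged and the coefficient is clipped to ±10 log-hazard units.
#'
#' @param feature numeric covariate, one value per subject.
#' @param time non-negative follow-up times.
#' @param event 0/1 event indicators (>= 2 events required).
#' @param clip absolute clip bound for runaway coefficients.
#' @return An object of class `uni_cox`: list with `coef`, `se`,
#'   `p_value`, `n`, `n_event`, `flagged`.
#' @export
univariate_cox <- function(feature, time, event, clip = 10) {
  stopifnot(length(feature) == length(time), length(time) == length(event))
  ok <- stats::complete.cases(feature, time, event)
  feature <- feature[ok]; time <- time[ok]; event <- event[ok]
  if (sum(event) < 2) rlang::abort("need at least 2 events to fit a Cox model")
  if (diff(range(feature)) == 0) {
    rlang::abort("feature is constant; Cox coefficient undefined")
  }
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(time, event) ~ feature, ties = "efron")
  )
  sm <- summary(fit)$coefficients
  co <- unname(sm[1, "coef"])
  flagged <- !is.finite(co) || abs(co) > clip ||
    !is.finite(sm[1, "se(coef)"]) || sm[1, "se(coef)"] > clip
  if (flagged) co <- sign(co) * min(abs(co), clip)
  structure(
    list(coef = co, se = unname(sm[1, "se(coef)"]),
         p_value = unname(sm[1, "Pr(>|z|)"]),
         n = length(feature), n_event = sum(event), flagged = flagged),
    class = "uni_cox"
  )
}

#' @export
print.uni_cox <- function(x, ...) {
  cat(sprintf("Univariate Cox: coef = %.4f (se %.4f, p = %.3g), %d/%d events%s\n",
              x$coef, x$se, x$p_value, x$n_event, x$n,
              if (x$flagged) " [flagged: monotone likelihood]" else ""))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.uni_cox <- function(x, ...) {
  tibble::tibble(term = "feature", estimate = x$coef, std_error = x$se,
                 p_value = x$p_value, flagged = x$flagged)
}

#' Triplet risk score
#'
#' `RS = coef_ase * psi + coef_tf * expr_tf + coef_rbp * expr_rbp`, the
#' linear combination of a triplet's PSI and two expression values weighted
#' by their univariate Cox coefficients.  Vectorized over samples; the two
#' gene terms commute.
#'
#' @param psi PSI values.
#' @param expr_tf,expr_rbp expression values on the scale used for the Cox
#'   fits.
#' @param coef_ase,coef_tf,coef_rbp univariate Cox coefficients.
#' @return Numeric risk scores.
#' @export
risk_score <- function(psi, expr_tf, expr_rbp, coef_ase, coef_tf, coef_rbp) {
  stopifnot(is.finite(coef_ase), is.finite(coef_tf), is.finite(coef_rbp))
  coef_ase * psi + coef_tf * expr_tf + coef_rbp * expr_rbp
}

#' Median split of risk scores
#'
#' High-risk = scores strictly above the median; low-risk = the rest (ties
#' at the median go to the low group, deterministically).
#'
#' @param scores numeric vector named by sample id, length >= 4.
#' @return A list with character vectors `high` and `low`.
#' @export
stratify_median <- function(scores) {
  if (is.null(names(scores))) rlang::abort("`scores` must be named by sample id")
  if (length(scores) < 4L) rlang::abort("need at least 4 samples")
  if (diff(range(scores)) == 0) {
    rlang::abort("all risk scores identical; stratification impossible")
  }
  med <- median(scores)
  list(high = names(scores)[scores > med], low = names(scores)[scores <= med])
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square statistic (1 degree of freedom) comparing
#' survival between two groups.
#'
#' @param group two-level group label per subject.
#' @param time follow-up times.
#' @param event 0/1 event indicators (>= 1 event overall).
#' @return A list with `statistic` and `p_value`.
#' @export
logrank_test <- function(group, time, event) {
  stopifnot(length(group) == length(time), length(time) == length(event))
  group <- as.factor(as.character(group))
  if (nlevels(group) != 2L || any(table(group) == 0)) {
    rlang::abort("`group` must contain two non-empty groups")
  }
  if (sum(event) < 1) rlang::abort("need at least one event overall")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  stat <- unname(sd$chisq)
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Kaplan-Meier coordinates for two risk groups
#'
#' Convenience export of the step-function coordinates (time, number at
#' risk, survival) per group, suitable for external plotting.
#'
#' @inheritParams logrank_test
#' @return A tibble with columns `group`, `time`, `n_risk`, `n_event`,
#'   `survival`.
#' @export
km_coordinates <- function(group, time, event) {
  fit <- survival::survfit(survival::Surv(time, event) ~ group,
                           data = data.frame(group = group))
  strata <- rep(names(fit$strata), fit$strata)
  tibble::tibble(
    group = sub("^group=", "", strata),
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    survival = fit$surv
  )
}

#' Survival stratification across a set of triplets
#'
#' For each triplet, on tumor samples with survival data: fits three
#' univariate Cox models (event PSI; log2(x+1) TF expression; log2(x+1)
#' RBP expression), combines them into per-sample risk scores
#' ([risk_score()]), splits at the median and runs the log-rank test.  Each
#' component is also tested on its own (both by its median-split log-rank p
#' and by its univariate Cox Wald p) so that triplets whose combined score
#' stratifies survival even though at least one component does not can be
#' counted — the "network beats components" fraction.  All reported
#' fractions use two-decimal percent rounding.
#'
#' @param triplets triplet tibble (typically the significant, annotated
#'   set); must contain `tf`, `rbp`, `event_id`.
#' @param psi,tf_expr,rbp_expr wide feature tables.
#' @param clinical clinical tibble with `os_time`/`os_event`.
#' @param alpha log-rank significance level.
#' @param component_check which per-component p-value feeds the headline
#'   "component not individually prognostic" flag: median-split log-rank
#'   (default) or univariate Cox Wald.
#' @return An object of class `survival_summary`: `per_triplet` tibble
#'   (Cox coefficients, log-rank statistic/p, per-component p-values,
#'   `failed` flag) and a one-row `summary` tibble with counts, fractions
#'   and percent labels.
#' @export
summarize_survival <- function(triplets, psi, tf_expr, rbp_expr, clinical,
                               alpha = 0.05,
                               component_check = c("logrank", "cox")) {
  component_check <- match.arg(component_check)
  if (nrow(triplets) == 0L) {
    rlang::abort("no triplets supplied; an empty survival summary is meaningless")
  }
  stopifnot(all(c("tf", "rbp", "event_id") %in% names(triplets)))
  psi_m <- feature_matrix(psi)
  tf_m <- feature_matrix(tf_expr)
  rbp_m <- feature_matrix(rbp_expr)
  clin <- clinical[clinical$class == "tumor" & !is.na(clinical$os_time) &
                     !is.na(clinical$os_event), ]
  ids <- Reduce(intersect, list(clin$sample_id, colnames(psi_m),
                                colnames(tf_m), colnames(rbp_m)))
  if (length(ids) < 10L) rlang::abort("too few tumor samples with survival data")
  clin <- clin[match(ids, clin$sample_id), ]
  time <- clin$os_time
  event <- clin$os_event

  component_p <- function(values) {
    strata <- stratify_median(setNames(values, ids))
    grp <- ifelse(ids %in% strata$high, "high", "low")
    lr <- logrank_test(grp, time, event)$p_value
    cox <- univariate_cox(values, time, event)
    c(logrank = lr, cox = cox$p_value)
  }

  rows <- purrr::pmap_dfr(
    triplets[, c("tf", "rbp", "event_id")],
    function(tf, rbp, event_id) {
      res <- tryCatch({
        psi_v <- psi_m[event_id, ids]
        tf_v <- log2p1(tf_m[tf, ids])
        rbp_v <- log2p1(rbp_m[rbp, ids])
        cx_ase <- univariate_cox(psi_v, time, event)
        cx_tf <- univariate_cox(tf_v, time, event)
        cx_rbp <- univariate_cox(rbp_v, time, event)
        rs <- risk_score(psi_v, tf_v, rbp_v,
                         cx_ase$coef, cx_tf$coef, cx_rbp$coef)
        strata <- stratify_median(setNames(rs, ids))
        grp <- ifelse(ids %in% strata$high, "high", "low")
        lr <- logrank_test(grp, time, event)
        comp <- rbind(ase = component_p(psi_v), tf = component_p(tf_v),
                      rbp = component_p(rbp_v))
        tibble::tibble(
          coef_ase = cx_ase$coef, coef_tf = cx_tf$coef, coef_rbp = cx_rbp$coef,
          logrank_stat = lr$statistic, logrank_p = lr$p_value,
          p_comp_ase = comp["ase", component_check],
          p_comp_tf = comp["tf", component_check],
          p_comp_rbp = comp["rbp", component_check],
          failed = FALSE
        )
      }, error = function(e) {
        tibble::tibble(
          coef_ase = NA_real_, coef_tf = NA_real_, coef_rbp = NA_real_,
          logrank_stat = NA_real_, logrank_p = NA_real_,
          p_comp_ase = NA_real_, p_comp_tf = NA_real_, p_comp_rbp = NA_real_,
          failed = TRUE
        )
      })
      dplyr::bind_cols(tibble::tibble(tf = tf, rbp = rbp,
                                      event_id = event_id), res)
    }
  )

  ok <- !rows$failed
  sig <- ok & rows$logrank_p < alpha
  weak_comp <- sig & (rows$p_comp_ase >= alpha | rows$p_comp_tf >= alpha |
                        rows$p_comp_rbp >= alpha)
  frac_sig <- format_percent(sum(sig), sum(ok))
  frac_weak <- if (sum(sig) > 0) format_percent(sum(weak_comp), sum(sig)) else
    list(count = 0L, total = 0L, percent = NA_real_, label = NA_character_)
  structure(
    list(
      per_triplet = rows,
      summary = tibble::tibble(
        n_triplets = nrow(rows),
        n_failed = sum(rows$failed),
        n_tested = sum(ok),
        n_significant = sum(sig),
        frac_significant = frac_sig$percent,
        frac_significant_label = frac_sig$label,
        n_weak_component = sum(weak_comp),
        frac_weak_component = frac_weak$percent,
        frac_weak_component_label = frac_weak$label,
        component_check = component_check,
        alpha = alpha
      )
    ),
    class = "survival_summary"
  )
}

#' @export
print.survival_summary <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Triplet survival stratification: %d/%d significant (%s); %d/%d with a non-prognostic component (%s)\n",
    s$n_significant, s$n_tested, s$frac_significant_label,
    s$n_weak_component, s$n_significant,
    s$frac_weak_component_label %||% "NA"
  ))
  invisible(x)
}

#' Tidy survival summaries
#'
#' `tidy()` returns the per-triplet table; `glance()` the one-row summary.
#'
#' @param x a `survival_summary`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.survival_summary <- function(x, ...) x$per_triplet

#' @rdname tidy.survival_summary
#' @exportS3Method generics::glance
glance.survival_summary <- function(x, ...) x$summary
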