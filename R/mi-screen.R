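#' Mutual information between a PSI vector and sample classes
#'
#' Plug-in estimate (log base 2, bits) from the joint histogram of the
#' binned PSI values and the binary class labels.  PSI is discretized into
#' `n_bins` equal-width bins on \[0, 1\]; if values fall outside \[0, 1\]
#' (e.g. residual association screening), equal-width bins over the
#' observed range are used instead.
#'
#' @param x numeric vector (PSI fractions).
#' @param labels vector with exactly two distinct values (tumor/normal).
#' @param n_bins number of bins, >= 2.
#' @return Non-negative mutual information in bits.
#' @examples
#' mutual_information(c(0.1, 0.1, 0.9, 0.9), c(0, 0, 1, 1), n_bins = 2)
#' @export
mutual_information <- function(x, labels, n_bins = 10) {
  mi_table(x, labels, n_bins)$mi
}

# joint-histogram MI plus the associated G-test of independence
# (G = 2 N ln(2) MI_bits ~ chi-square with (occupied bins - 1) df)
mi_table <- function(x, labels, n_bins = 10) {
  if (length(x) != length(labels)) {
    rlang::abort("`x` and `labels` must have equal length")
  }
  if (n_bins < 2) rlang::abort("`n_bins` must be >= 2")
  if (length(unique(labels)) != 2L) {
    rlang::abort("`labels` must take exactly two distinct values")
  }
  if (anyNA(x)) rlang::abort("`x` must not contain missing values")
  if (all(x >= 0 & x <= 1)) {
    breaks <- seq(0, 1, length.out = n_bins + 1)
  } else if (diff(range(x)) == 0) {
    return(list(mi = 0, p_value = 1)) # constant out-of-range vector
  } else {
    breaks <- seq(min(x), max(x), length.out = n_bins + 1)
  }
  bx <- cut(x, breaks = breaks, include.lowest = TRUE)
  tab <- table(bx, labels)
  n <- sum(tab)
  p <- tab / n
  px <- rowSums(p)
  py <- colSums(p)
  nz <- p > 0
  mi <- sum(p[nz] * log2(p[nz] / outer(px, py)[nz]))
  occupied <- sum(px > 0)
  dfree <- max(1L, occupied - 1L)
  list(mi = mi, p_value = pchisq(2 * n * log(2) * mi, df = dfree,
                                 lower.tail = FALSE))
}

#' Rank splicing events by mutual information with the class label
#'
#' Computes [mutual_information()] for every event and ranks events by
#' decreasing MI, breaking ties by event-id lexicographic order so the
#' ranking is deterministic.  The top `k` events (default 50) are flagged
#' for the iterative selection stage.  A per-event G-test of independence
#' (the likelihood-ratio counterpart of the plug-in MI) with BH adjustment
#' across all events is reported alongside.
#'
#' @param psi imputed PSI tibble (`event_id` + sample columns).
#' @param labels class label per sample column (two distinct values).
#' @param k size of the head set to flag; if fewer events are available,
#'   all are flagged with a warning.
#' @param n_bins passed to [mutual_information()].
#' @return A tibble with columns `event_id`, `mi`, `p_value`, `p_adjusted`,
#'   `rank`, `top_k`, sorted by rank.
#' @export
mi_rank <- function(psi, labels, k = 50, n_bins = 10) {
  m <- feature_matrix(psi)
  if (length(labels) != ncol(m)) {
    rlang::abort("`labels` must have one entry per PSI sample column")
  }
  res <- apply(m, 1L, mi_table, labels = labels, n_bins = n_bins)
  mi <- unname(vapply(res, `[[`, numeric(1), "mi"))
  pv <- unname(vapply(res, `[[`, numeric(1), "p_value"))
  ord <- order(-mi, rownames(m), method = "radix")
  out <- tibble::tibble(
    event_id = rownames(m)[ord],
    mi = mi[ord],
    p_value = pv[ord],
    p_adjusted = stats::p.adjust(pv, method = "BH")[ord],
    rank = seq_along(ord)
  )
  if (nrow(out) < k) {
    rlang::warn(sprintf("only %d events available; k = %d requested",
                        nrow(out), k))
    k <- nrow(out)
  }
  out$top_k <- out$rank <= k
  attr(out, "k") <- k
  out
}

#' Iterative sure-independence screening with LASSO refinement
#'
#' Starting from the MI-ranked head set, iterates a screening/selection
#' loop: fit an L1-penalized logistic classifier of tumor-vs-normal on the
#' current working set with the penalty chosen by stratified `folds`-fold
#' cross-validation (binomial deviance); keep events with nonzero
#' coefficients; re-rank the unselected events by their mutual information
#' with the sign of the working residual of a logistic fit on the kept set
#' (conditional association); refill the working set and repeat until the
#' kept set stabilizes or `max_iter` passes.
#'
#' Because the head set is itself chosen for high MI on the same samples, a
#' marginal-association guard is applied first: only events whose MI
#' G-test survives BH adjustment at `guard_alpha` across the supplied
#' candidates are eligible for selection.  Under label-permuted null data
#' essentially nothing passes the guard, so the selected set is empty or
#' near-empty instead of inheriting the screening bias.
#'
#' The classifier AUC is reported from the cross-validated (prevalidated)
#' linear predictors by default, or by resubstitution when
#' `resubstitution = TRUE`.
#'
#' @param psi_top PSI tibble restricted to the MI head set (see
#'   [mi_rank()]).
#' @param labels class label per sample column.
#' @param folds number of CV folds (default 10); both classes must contain
#'   at least `folds` samples.
#' @param seed integer seed driving the fold assignment; identical inputs
#'   and seed reproduce the selection exactly.
#' @param lambda_rule `"1se"` (most conservative penalty within one
#'   standard error of the CV optimum, default) or `"min"`.
#' @param max_iter iteration cap for the re-screening loop.
#' @param n_bins bins for the MI computations.
#' @param guard_alpha BH-adjusted significance level of the
#'   marginal-association guard; set to 1 to disable it.
#' @param resubstitution report the AUC on resubstituted fitted values
#'   instead of cross-validated scores.
#' @return An object of class `screen_result`: selected event set, AUC,
#'   ROC points, per-sample fold ids and iteration history.  See
#'   [tidy.screen_result()].
#' @export
isis_lasso_select <- function(psi_top, labels, folds = 10, seed = 1L,
                              lambda_rule = c("1se", "min"), max_iter = 5,
                              n_bins = 10, guard_alpha = 0.05,
                              resubstitution = FALSE) {
  lambda_rule <- match.arg(lambda_rule)
  m <- feature_matrix(psi_top)
  x <- t(m)
  if (length(labels) != nrow(x)) {
    rlang::abort("`labels` must have one entry per PSI sample column")
  }
  lev <- sort(unique(as.character(labels)))
  if (length(lev) != 2L) rlang::abort("`labels` must be binary")
  positive <- if ("tumor" %in% lev) "tumor" else lev[2]
  y <- as.integer(as.character(labels) == positive)
  class_sizes <- table(y)
  if (min(class_sizes) < folds) {
    rlang::abort(sprintf(
      "stratified %d-fold CV needs >= %d samples per class (smallest class has %d)",
      folds, folds, min(class_sizes)
    ))
  }
  set.seed(seed)
  foldid <- integer(length(y))
  for (cl in c(0L, 1L)) {
    idx <- which(y == cl)
    foldid[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }

  ## marginal-association guard
  marg <- apply(x, 2L, mi_table, labels = y, n_bins = n_bins)
  marg_mi <- vapply(marg, `[[`, numeric(1), "mi")
  marg_padj <- stats::p.adjust(vapply(marg, `[[`, numeric(1), "p_value"),
                               method = "BH")
  eligible <- colnames(x)[marg_padj < guard_alpha]
  eligible <- eligible[order(-marg_mi[eligible], eligible, method = "radix")]

  empty_result <- function(n_iter, history) {
    structure(
      list(selected = character(0), candidates = colnames(x),
           eligible = eligible, auc = 0.5, auc_type = "cross-validated",
           roc = tibble::tibble(fpr = c(0, 1), tpr = c(0, 1)),
           folds = tibble::tibble(sample_id = rownames(x), fold = foldid,
                                  label = y, score = 0),
           lambda = NA_real_, lambda_rule = lambda_rule,
           n_iter = n_iter, history = history, seed = seed),
      class = "screen_result"
    )
  }
  if (length(eligible) == 0L) return(empty_result(0L, list()))
  if (length(eligible) == 1L) {
    res <- empty_result(1L, list(eligible))
    res$selected <- eligible
    g <- suppressWarnings(stats::glm.fit(cbind(1, x[, eligible]), y,
                                         family = stats::binomial()))
    res$auc_type <- "resubstitution"
    scores <- g$fitted.values
    roc <- pROC::roc(y, scores, quiet = TRUE, direction = "<")
    res$auc <- as.numeric(pROC::auc(roc))
    res$roc <- tibble::tibble(fpr = rev(1 - roc$specificities),
                              tpr = rev(roc$sensitivities))
    res$folds$score <- scores
    return(res)
  }

  budget <- max(2L, ceiling(ncol(x) / 2)) # working-set size per pass
  candidates <- head(eligible, budget)
  selected <- character(0)
  history <- list()
  cvfit <- NULL
  lam <- NULL
  for (it in seq_len(max_iter)) {
    pool <- union(selected, candidates)
    if (length(pool) < 2L) {
      pool <- union(pool, head(setdiff(eligible, pool), 2L - length(pool)))
    }
    cvfit <- suppressWarnings(
      glmnet::cv.glmnet(x[, pool, drop = FALSE], y, family = "binomial",
                        foldid = foldid, keep = TRUE,
                        type.measure = "deviance")
    )
    lam <- if (lambda_rule == "min") cvfit$lambda.min else cvfit$lambda.1se
    co <- as.matrix(coef(cvfit, s = lam))[-1L, 1L]
    new_selected <- names(co)[co != 0]
    history[[it]] <- new_selected
    stable <- setequal(new_selected, selected)
    selected <- new_selected
    if (stable) break
    remaining <- setdiff(eligible, selected)
    if (!length(remaining)) break
    if (length(selected)) {
      g <- suppressWarnings(
        stats::glm.fit(cbind(1, x[, selected, drop = FALSE]), y,
                       family = stats::binomial())
      )
      resid_sign <- factor(y - g$fitted.values > 0)
      if (nlevels(droplevels(resid_sign)) < 2L) break # fully explained
      cond_mi <- apply(x[, remaining, drop = FALSE], 2L,
                       mutual_information, labels = resid_sign,
                       n_bins = n_bins)
      remaining <- remaining[order(-cond_mi, remaining, method = "radix")]
    }
    candidates <- head(remaining, max(1L, budget - length(selected)))
  }

  scores <- if (resubstitution) {
    as.numeric(predict(cvfit, x[, rownames(coef(cvfit, s = lam))[-1L],
                                drop = FALSE], s = lam))
  } else {
    cvfit$fit.preval[, which.min(abs(cvfit$lambda - lam))]
  }
  roc <- if (length(unique(scores)) > 1L) {
    pROC::roc(y, scores, quiet = TRUE, direction = "<")
  } else {
    NULL
  }
  auc <- if (is.null(roc)) 0.5 else as.numeric(pROC::auc(roc))
  roc_points <- if (is.null(roc)) {
    tibble::tibble(fpr = c(0, 1), tpr = c(0, 1))
  } else {
    tibble::tibble(fpr = rev(1 - roc$specificities),
                   tpr = rev(roc$sensitivities))
  }

  structure(
    list(
      selected = sort(selected),
      candidates = colnames(x),
      eligible = eligible,
      auc = auc,
      auc_type = if (resubstitution) "resubstitution" else "cross-validated",
      roc = roc_points,
      folds = tibble::tibble(sample_id = rownames(x), fold = foldid,
                             label = y, score = scores),
      lambda = lam, lambda_rule = lambda_rule,
      n_iter = length(history), history = history,
      seed = seed
    ),
    class = "screen_result"
  )
}

#' Screen cancer-specific splicing events
#'
#' End-to-end screening stage: MI ranking of all events ([mi_rank()])
#' followed by iterative LASSO selection on the head set
#' ([isis_lasso_select()]).  Also reports per-event class means in the
#' style of a selected-event summary table.
#'
#' @param psi imputed PSI tibble.
#' @param clinical clinical tibble covering the PSI samples.
#' @param k MI head-set size.
#' @param ... passed on to [isis_lasso_select()].
#' @return A `screen_result` whose `table` element summarizes the selected
#'   events (event id, tumor/normal means, MI value).
#' @export
screen_ases <- function(psi, clinical, k = 50, ...) {
  samples <- sample_columns(psi)
  labels <- clinical$class[match(samples, clinical$sample_id)]
  if (anyNA(labels)) rlang::abort("every PSI sample needs a clinical class")
  ranking <- mi_rank(psi, labels, k = k)
  top_ids <- ranking$event_id[ranking$top_k]
  res <- isis_lasso_select(psi[match(top_ids, psi$event_id), ], labels, ...)
  m <- feature_matrix(psi)
  sel <- res$selected
  res$table <- tibble::tibble(
    event_id = sel,
    mean_tumor = rowMeans(m[sel, labels == "tumor", drop = FALSE]),
    mean_normal = rowMeans(m[sel, labels != "tumor", drop = FALSE]),
    mi = ranking$mi[match(sel, ranking$event_id)]
  ) |> dplyr::arrange(dplyr::desc(.data$mi))
  res$ranking <- ranking
  res
}

#' @export
print.screen_result <- function(x, ...) {
  cat("ASE screen: ", length(x$selected), " event(s) selected from ",
      length(x$candidates), " candidates (", x$n_iter, " pass(es))\n",
      "AUC (", x$auc_type, "): ", sprintf("%.3f", x$auc), "\n", sep = "")
  invisible(x)
}

#' Tidy and summarize screening results
#'
#' `tidy()` returns one row per candidate event with its guard and
#' selection flags; `glance()` returns a one-row model summary.
#'
#' @param x a `screen_result`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.screen_result <- function(x, ...) {
  tibble::tibble(
    event_id = x$candidates,
    eligible = x$candidates %in% x$eligible,
    selected = x$candidates %in% x$selected
  )
}

#' @rdname tidy.screen_result
#' @exportS3Method generics::glance
glance.screen_result <- function(x, ...) {
  tibble::tibble(
    n_candidates = length(x$candidates),
    n_eligible = length(x$eligible),
    n_selected = length(x$selected),
    auc = x$auc,
    auc_type = x$auc_type,
    lambda = x$lambda,
    n_iter = x$n_iter
  )
}
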