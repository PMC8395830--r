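#' Split samples into bottom/top 40% TF-expression strata
#'
#' Orders samples by TF expression with ties broken by sample-id
#' lexicographic order (stable and deterministic), then takes the
#' `floor(0.4 * n)` smallest as the low group and the `floor(0.4 * n)`
#' largest as the high group; the middle ~20% is unused.
#'
#' @param tf_row numeric vector of TF expression named by sample id.
#' @return A list with character vectors `low` and `high` of sample ids.
#' @export
split_by_tf <- function(tf_row) {
  if (is.null(names(tf_row)) || any(!nzchar(names(tf_row)))) {
    rlang::abort("`tf_row` must be named by sample id")
  }
  n <- length(tf_row)
  if (n < 10L) rlang::abort("need at least 10 samples to stratify")
  if (diff(range(tf_row)) == 0) {
    rlang::abort("TF expression is constant; stratification is meaningless")
  }
  ord <- order(tf_row, names(tf_row), method = "radix")
  g <- floor(0.4 * n)
  list(low = names(tf_row)[ord[seq_len(g)]],
       high = names(tf_row)[ord[seq(n - g + 1L, n)]])
}

#' Pearson correlation with defined-input checks
#'
#' Standard product-moment correlation; errors (rather than returning
#' `NA`) when either vector is constant or shorter than 3, so degenerate
#' triplets are surfaced instead of silently mislabelled.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return Correlation in \[-1, 1\].
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) rlang::abort("`x` and `y` must match in length")
  if (length(x) < 3L) rlang::abort("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) rlang::abort("inputs must not contain NA")
  if (sd(x) == 0 || sd(y) == 0) {
    rlang::abort("correlation undefined for a constant vector")
  }
  cor(x, y, method = "pearson")
}

#' Classify the TF modulation mode from stratified correlations
#'
#' Compares the RBP-vs-PSI Pearson correlation in the low-TF group
#' (`pcc_low`) with the high-TF group (`pcc_high`):
#'
#' * sign inversion low-to-high: negative to positive = `INP`, positive to
#'   negative = `IPN`;
#' * same sign, both negative: `SAI` when the correlation strengthens
#'   (`|pcc_low| < |pcc_high|`), `WAI` when it weakens;
#' * same sign, both positive: `SEI` when it strengthens, `WEI` when it
#'   weakens;
#' * exact equality: `UNCHANGED` (a measure-zero tie, excluded from the
#'   six-way partition).
#'
#' A zero correlation in one group takes the sign of the other group, so
#' fading in/out of a correlation counts as strengthening/weakening, not
#' inversion.  The function is total and deterministic on \[-1, 1\]^2, and
#' swapping the arguments maps SAI<->WAI, SEI<->WEI and IPN<->INP.
#'
#' @param pcc_low,pcc_high numeric vectors of correlations in \[-1, 1\].
#' @return Character vector of mode labels.
#' @examples
#' classify_mode(-0.28, 0.14) # INP
#' classify_mode(0.23, 0.51)  # SEI
#' @export
classify_mode <- function(pcc_low, pcc_high) {
  stopifnot(length(pcc_low) == length(pcc_high))
  if (any(abs(c(pcc_low, pcc_high)) > 1, na.rm = TRUE)) {
    rlang::abort("correlations must lie in [-1, 1]")
  }
  purrr::map2_chr(pcc_low, pcc_high, function(lo, hi) {
    if (is.na(lo) || is.na(hi)) return(NA_character_)
    if (lo == hi) return("UNCHANGED")
    sl <- sign(lo)
    sh <- sign(hi)
    if (sl == 0) sl <- sh
    if (sh == 0) sh <- sl
    if (sl < 0 && sh > 0) return("INP")
    if (sl > 0 && sh < 0) return("IPN")
    if (sl < 0) {
      if (abs(lo) < abs(hi)) "SAI" else "WAI"
    } else {
      if (abs(lo) < abs(hi)) "SEI" else "WEI"
    }
  })
}

#' Annotate significant triplets with modulation modes
#'
#' For every significant triplet, stratifies the fitting cohort by the
#' bottom/top 40% of TF expression ([split_by_tf()]), computes the Pearson
#' correlation between log2(x+1) RBP expression and PSI within each
#' stratum and classifies the mode ([classify_mode()]).  Triplets whose
#' correlations are undefined (constant inputs) keep `NA` mode labels and
#' are reported via a message, never silently dropped.
#'
#' @param triplets result tibble from [enumerate_triplets()].
#' @param psi,tf_expr,rbp_expr wide feature tables.
#' @param clinical clinical tibble.
#' @param cohort stratification cohort, matching the fitting cohort.
#' @return `triplets` with added columns `pcc_low`, `pcc_high`, `mode`.
#' @export
annotate_modes <- function(triplets, psi, tf_expr, rbp_expr, clinical,
                           cohort = c("tumor", "all")) {
  cohort <- match.arg(cohort)
  stopifnot(all(c("tf", "rbp", "event_id", "significant") %in% names(triplets)))
  psi_m <- feature_matrix(psi)
  tf_m <- feature_matrix(tf_expr)
  rbp_m <- feature_matrix(rbp_expr)
  keep <- if (cohort == "tumor") clinical$class == "tumor" else
    rep(TRUE, nrow(clinical))
  ids <- Reduce(intersect, list(clinical$sample_id[keep], colnames(psi_m),
                                colnames(tf_m), colnames(rbp_m)))

  out <- dplyr::mutate(triplets, pcc_low = NA_real_, pcc_high = NA_real_,
                       mode = NA_character_)
  n_failed <- 0L
  for (i in which(out$significant)) {
    res <- tryCatch({
      strata <- split_by_tf(tf_m[out$tf[i], ids])
      rbp_l2 <- log2p1(rbp_m[out$rbp[i], ids])
      psi_v <- psi_m[out$event_id[i], ids]
      lo <- pearson_cor(rbp_l2[strata$low], psi_v[strata$low])
      hi <- pearson_cor(rbp_l2[strata$high], psi_v[strata$high])
      c(lo, hi)
    }, error = function(e) NULL)
    if (is.null(res)) {
      n_failed <- n_failed + 1L
      next
    }
    out$pcc_low[i] <- res[1]
    out$pcc_high[i] <- res[2]
    out$mode[i] <- classify_mode(res[1], res[2])
  }
  if (n_failed > 0L) {
    rlang::inform(sprintf(
      "annotate_modes: %d significant triplet(s) had undefined correlations (mode = NA)",
      n_failed
    ))
  }
  out
}

#' Count triplets per modulation mode
#'
#' Tabulates the six mode labels among annotated significant triplets.
#' The six counts partition the successfully annotated significant set;
#' `UNCHANGED` (exact correlation ties) and annotation failures are
#' reported in the attributes `n_unchanged` and `n_failed`.
#'
#' @param triplets annotated tibble from [annotate_modes()].
#' @return A tibble with columns `mode` and `n`, one row per mode label.
#' @export
mode_counts <- function(triplets) {
  stopifnot(all(c("mode", "significant") %in% names(triplets)))
  sig <- triplets[triplets$significant, ]
  counts <- table(factor(sig$mode, levels = mode_labels))
  out <- tibble::tibble(mode = mode_labels, n = as.integer(counts))
  attr(out, "n_unchanged") <- sum(sig$mode == "UNCHANGED", na.rm = TRUE)
  attr(out, "n_failed") <- sum(is.na(sig$mode))
  out
}
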