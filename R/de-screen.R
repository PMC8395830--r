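#' Log2 fold change between classes
#'
#' `log2((mean_tumor + pseudocount) / (mean_normal + pseudocount))` over raw
#' expression values.  The pseudocount (default 1) guards against zero class
#' means; the result is antisymmetric under swapping the class labels.
#'
#' @param values non-negative expression vector.
#' @param labels class label per value; `"tumor"` defines the numerator
#'   class when present, otherwise the second sorted level.
#' @param pseudocount positive stabilizer added to both class means.
#' @return Scalar log2 fold change.
#' @export
log2_fold_change <- function(values, labels, pseudocount = 1) {
  stopifnot(length(values) == length(labels), pseudocount > 0)
  lev <- sort(unique(as.character(labels)))
  if (length(lev) != 2L) rlang::abort("`labels` must take two distinct values")
  positive <- if ("tumor" %in% lev) "tumor" else lev[2]
  tum <- values[labels == positive]
  nor <- values[labels != positive]
  if (!length(tum) || !length(nor)) rlang::abort("both classes must be non-empty")
  log2((mean(tum) + pseudocount) / (mean(nor) + pseudocount))
}

#' Differential-expression screen by rank-sum test and fold change
#'
#' For every gene, computes the log2 fold change between tumor and normal
#' samples and a two-sided Wilcoxon rank-sum p-value (exact for small
#' tie-free samples, normal approximation with tie correction otherwise),
#' then applies Benjamini-Hochberg adjustment across all tested genes.
#' Genes constant across all samples get `p = 1` by convention (reported
#' via a message).
#'
#' @param expr expression tibble (`gene` + sample columns).
#' @param labels class label per sample column.
#' @param pseudocount passed to [log2_fold_change()].
#' @param lfc_cutoff,alpha selection thresholds: a gene is selected when
#'   `|log2FC|` exceeds `lfc_cutoff` strictly and its (adjusted) p-value is
#'   below `alpha` strictly.
#' @param use_adjusted use BH-adjusted p-values for selection (default);
#'   set `FALSE` to select on raw p-values.
#' @return A tibble with columns `gene`, `log2fc`, `p_value`, `p_adjusted`,
#'   `selected`.
#' @export
wilcoxon_de <- function(expr, labels, pseudocount = 1,
                        lfc_cutoff = 1, alpha = 0.05, use_adjusted = TRUE) {
  m <- feature_matrix(expr)
  if (length(labels) != ncol(m)) {
    rlang::abort("`labels` must have one entry per expression sample column")
  }
  lev <- sort(unique(as.character(labels)))
  if (length(lev) != 2L) rlang::abort("`labels` must take two distinct values")
  positive <- if ("tumor" %in% lev) "tumor" else lev[2]
  tum <- labels == positive
  if (sum(tum) < 2L || sum(!tum) < 2L) {
    rlang::abort("both classes need at least 2 samples")
  }
  lfc <- unname(apply(m, 1L, log2_fold_change, labels = labels,
                      pseudocount = pseudocount))
  n_constant <- 0L
  p <- unname(apply(m, 1L, function(v) {
    if (diff(range(v)) == 0) {
      n_constant <<- n_constant + 1L
      return(1)
    }
    suppressWarnings(
      stats::wilcox.test(v[tum], v[!tum], exact = NULL)$p.value
    )
  }))
  if (n_constant > 0L) {
    rlang::inform(sprintf(
      "wilcoxon_de: %d constant gene(s) assigned p = 1", n_constant
    ))
  }
  p_adj <- stats::p.adjust(p, method = "BH")
  p_sel <- if (use_adjusted) p_adj else p
  tibble::tibble(
    gene = rownames(m),
    log2fc = lfc,
    p_value = p,
    p_adjusted = p_adj,
    selected = abs(lfc) > lfc_cutoff & p_sel < alpha
  )
}

#' Extract the selected gene set from a differential screen
#'
#' @param de result tibble from [wilcoxon_de()].
#' @return Character vector of selected gene symbols.
#' @export
select_de <- function(de) {
  stopifnot(all(c("gene", "selected") %in% names(de)))
  de$gene[de$selected]
}
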