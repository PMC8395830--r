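# shared internal helpers

# wide feature table (first column = feature id, remaining columns = samples)
# -> numeric matrix with feature rownames
feature_matrix <- function(tbl, id_col = 1L) {
  stopifnot(is.data.frame(tbl), ncol(tbl) >= 2L)
  ids <- as.character(tbl[[id_col]])
  if (anyDuplicated(ids)) {
    rlang::abort(paste0(
      "duplicate feature ids: ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  m <- as.matrix(tbl[, -id_col, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

matrix_to_tbl <- function(m, id_name = "feature") {
  tibble::as_tibble(m, rownames = id_name)
}

sample_columns <- function(tbl) names(tbl)[-1L]

log2p1 <- function(x) log2(x + 1)

zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    rlang::abort("cannot z-score a constant vector")
  }
  (x - mean(x)) / s
}

# percent with the two-decimal rounding convention used in all reported
# fractions, e.g. 5580/6519 -> 85.60 -> "85.60%"
format_percent <- function(count, total) {
  stopifnot(length(count) == 1L, length(total) == 1L, total > 0, count >= 0)
  pct <- round(100 * count / total, 2)
  list(
    count = as.integer(count),
    total = as.integer(total),
    percent = pct,
    label = sprintf("%.2f%%", pct)
  )
}

`%||%` <- rlang::`%||%`
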