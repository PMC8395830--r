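#' Read a PSI matrix
#'
#' Reads a tab-delimited table of percent-spliced-in (PSI) values, events in
#' rows and samples in columns.  Two dialects are accepted:
#'
#' * **annotated**: SpliceSeq-style columns `symbol`, `as_id`, `splice_type`
#'   (case-insensitive; optional `exons`, `from_exon`, `to_exon` are dropped),
#'   followed by one column per sample.  The event id is assembled as
#'   `SYMBOL_NUMBER_TYPE`.
#' * **simplified**: first column holds full event ids (any header name),
#'   remaining columns are samples.
#'
#' @param path file path.
#' @return A tibble with column `event_id` followed by one numeric column per
#'   sample; values in \[0, 1\] or `NA`.
#' @export
read_psi <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  nm <- tolower(names(tbl))
  anno <- c("symbol", "as_id", "splice_type")
  if (all(anno %in% nm)) {
    event_id <- format_ase_id(
      as.character(tbl[[which(nm == "symbol")]]),
      as.integer(tbl[[which(nm == "as_id")]]),
      as.character(tbl[[which(nm == "splice_type")]])
    )
    drop <- nm %in% c(anno, "exons", "from_exon", "to_exon", "gene")
    tbl <- tbl[, !drop, drop = FALSE]
    tbl <- dplyr::bind_cols(tibble::tibble(event_id = event_id), tbl)
  } else {
    names(tbl)[1] <- "event_id"
    tbl$event_id <- as.character(tbl$event_id)
  }
  parse_ase_id(tbl$event_id) # validates; errors name the offending token
  vals <- as.matrix(tbl[, -1, drop = FALSE])
  if (!is.numeric(vals)) rlang::abort("PSI sample columns must be numeric")
  if (any(vals < 0 | vals > 1, na.rm = TRUE)) {
    rlang::abort("PSI values must lie in [0, 1]")
  }
  tbl
}

#' Read a gene-expression matrix
#'
#' Tab-delimited, genes in rows (first column = gene symbol), samples in
#' columns.  Values must be non-negative; duplicate gene rows are an error.
#'
#' @param path file path.
#' @return A tibble with column `gene` followed by sample columns.
#' @export
read_expression <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(tbl)[1] <- "gene"
  tbl$gene <- as.character(tbl$gene)
  if (anyDuplicated(tbl$gene)) {
    rlang::abort(paste0("duplicate gene rows: ",
                        paste(unique(tbl$gene[duplicated(tbl$gene)]),
                              collapse = ", ")))
  }
  vals <- as.matrix(tbl[, -1, drop = FALSE])
  if (!is.numeric(vals) || any(vals < 0, na.rm = TRUE)) {
    rlang::abort("expression values must be non-negative numbers")
  }
  tbl
}

clinical_columns <- c(
  "sample_id", "class", "gender", "stage", "age", "race", "year",
  "os_time", "os_event"
)

#' Read a clinical table
#'
#' Tab-delimited per-sample covariates with a fixed header contract
#' (case-insensitive): `sample_id`, `class` (`tumor`/`normal`), `gender`,
#' `stage`, `age` (years), `race`, `year` (of diagnosis), `os_time` (days),
#' `os_event` (0/1).  Survival fields may be `NA` (e.g. normal samples).
#'
#' @param path file path.
#' @return A validated tibble with the nine columns above.
#' @export
read_clinical <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(tbl) <- tolower(names(tbl))
  missing_cols <- setdiff(clinical_columns, names(tbl))
  if (length(missing_cols)) {
    rlang::abort(paste0("clinical table is missing columns: ",
                        paste(missing_cols, collapse = ", ")))
  }
  tbl <- tbl[, clinical_columns]
  validate_clinical(tbl)
  tbl
}

validate_clinical <- function(clinical) {
  if (anyDuplicated(clinical$sample_id)) {
    rlang::abort("clinical sample ids must be unique")
  }
  if (!all(clinical$class %in% c("tumor", "normal"))) {
    rlang::abort("clinical `class` must be 'tumor' or 'normal'")
  }
  if (!all(clinical$os_event %in% c(0L, 1L, NA))) {
    rlang::abort("clinical `os_event` must be 0/1 (or NA)")
  }
  if (any(clinical$os_time < 0, na.rm = TRUE)) {
    rlang::abort("clinical `os_time` must be non-negative")
  }
  invisible(clinical)
}

#' Read a gene list or a PPI edge list
#'
#' `read_gene_list()` expects one symbol per line; `read_ppi()` expects two
#' tab-separated symbols per line (an undirected edge).
#'
#' @param path file path.
#' @return `read_gene_list()`: a character vector of unique symbols.
#'   `read_ppi()`: a tibble with columns `a` and `b`.
#' @export
read_gene_list <- function(path) {
  x <- readr::read_lines(path, progress = FALSE)
  x <- trimws(x)
  unique(x[nzchar(x)])
}

#' @rdname read_gene_list
#' @export
read_ppi <- function(path) {
  tbl <- readr::read_tsv(path, col_names = c("a", "b"),
                         show_col_types = FALSE, progress = FALSE)
  if (ncol(tbl) != 2L) rlang::abort("PPI edge list must have two columns")
  tbl
}

#' Impute missing PSI values by class mean
#'
#' Each missing PSI cell is replaced by the mean of the non-missing values of
#' that event *within the sample's class* (tumor mean for tumor samples,
#' normal mean for normal samples).  Non-missing cells are unchanged, so
#' class-wise event means are preserved exactly and the operation is
#' idempotent.
#'
#' @param psi PSI tibble (`event_id` + sample columns), possibly with `NA`s.
#' @param clinical clinical tibble with `sample_id` and `class` covering
#'   every PSI sample column.
#' @return The PSI tibble with no missing values.
#' @export
impute_psi <- function(psi, clinical) {
  m <- feature_matrix(psi)
  samples <- colnames(m)
  cls <- clinical$class[match(samples, clinical$sample_id)]
  if (anyNA(cls)) {
    rlang::abort(paste0("samples without a class label: ",
                        paste(samples[is.na(cls)], collapse = ", ")))
  }
  if (!anyNA(m)) return(psi)
  for (cl in unique(cls)) {
    idx <- which(cls == cl)
    sub <- m[, idx, drop = FALSE]
    na_count <- rowSums(is.na(sub))
    all_missing <- na_count == length(idx)
    if (any(all_missing)) {
      rlang::abort(paste0(
        "events entirely missing in the ", cl, " class: ",
        paste(rownames(m)[all_missing], collapse = ", ")
      ))
    }
    if (any(na_count > 0)) {
      means <- rowMeans(sub, na.rm = TRUE)
      nas <- which(is.na(sub), arr.ind = TRUE)
      sub[nas] <- means[nas[, 1]]
      m[, idx] <- sub
    }
  }
  out <- matrix_to_tbl(m, "event_id")
  names(out) <- names(psi)
  out
}

#' Remove genes expressed in too few samples
#'
#' A gene counts as expressed in a sample when its value is strictly
#' positive; zeros and missing values both count as not expressed.  Genes
#' whose not-expressed fraction exceeds 50% strictly are removed; a gene
#' not expressed in exactly half of the samples is kept.
#'
#' @param expr expression tibble (`gene` + sample columns).
#' @return The filtered expression tibble.
#' @export
filter_low_expression <- function(expr) {
  if (nrow(expr) == 0L) return(expr)
  m <- feature_matrix(expr)
  expressed <- rowMeans(m > 0 & !is.na(m))
  expr[expressed >= 0.5, , drop = FALSE]
}

#' Restrict all tables to their common samples
#'
#' Takes the intersection of the clinical sample ids and the sample columns
#' of every supplied wide table (PSI or expression), drops everything else,
#' and reports how many samples each table lost.
#'
#' @param clinical clinical tibble.
#' @param ... named wide tables (first column = feature id).
#' @return A list with the harmonized `clinical` plus one element per
#'   supplied table, all restricted to the common samples in a common order.
#' @export
harmonize_samples <- function(clinical, ...) {
  tables <- list(...)
  if (!length(tables) || is.null(names(tables)) || any(!nzchar(names(tables)))) {
    rlang::abort("supply named wide tables in `...`")
  }
  common <- clinical$sample_id
  for (tbl in tables) common <- intersect(common, sample_columns(tbl))
  if (!length(common)) rlang::abort("no samples are shared by all tables")
  dropped_clin <- setdiff(clinical$sample_id, common)
  if (length(dropped_clin)) {
    rlang::inform(sprintf("harmonize_samples: dropped %d clinical sample(s)",
                          length(dropped_clin)))
  }
  out <- purrr::imap(tables, function(tbl, nm) {
    lost <- length(sample_columns(tbl)) - length(common)
    if (lost > 0) {
      rlang::inform(sprintf("harmonize_samples: dropped %d sample(s) from %s",
                            lost, nm))
    }
    tbl[, c(names(tbl)[1], common), drop = FALSE]
  })
  c(list(clinical = clinical[match(common, clinical$sample_id), ]), out)
}
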