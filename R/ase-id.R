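#' Splicing-event types
#'
#' The seven splice-type codes used in event identifiers: exon skip (ES),
#' mutually exclusive exons (ME), retained intron (RI), alternate promoter
#' (AP), alternate terminator (AT), alternate donor site (AD) and alternate
#' acceptor site (AA).
#'
#' @export
ase_types <- c("ES", "ME", "RI", "AP", "AT", "AD", "AA")

#' Parse splicing-event identifiers
#'
#' Event identifiers take the form `SYMBOL_NUMBER_TYPE`, e.g.
#' `RACGAP1_21625_AT`: the host gene symbol, a numeric event id, and one of
#' the seven splice-type codes in [ase_types].  Gene symbols may themselves
#' contain underscores; the last two underscore-separated tokens must be a
#' positive integer and a valid splice-type code.
#'
#' @param id character vector of event identifiers.
#'
#' @return A tibble with one row per identifier and columns `event_id`,
#'   `symbol`, `event_number` (integer) and `splice_type`.
#'
#' @examples
#' parse_ase_id(c("RACGAP1_21625_AT", "PCNA_58648_AP"))
#' @export
parse_ase_id <- function(id) {
  if (!is.character(id) || length(id) == 0L || anyNA(id) || any(!nzchar(id))) {
    rlang::abort("`id` must be a character vector of non-empty strings")
  }
  parts <- strsplit(id, "_", fixed = TRUE)
  out <- purrr::map2(parts, id, function(p, full) {
    if (length(p) < 3L) {
      rlang::abort(sprintf(
        "malformed event id %s: expected SYMBOL_NUMBER_TYPE", dQuote(full)
      ))
    }
    type <- p[length(p)]
    num <- p[length(p) - 1L]
    if (!type %in% ase_types) {
      rlang::abort(sprintf(
        "unknown splice type %s in event id %s", dQuote(type), dQuote(full)
      ))
    }
    if (!grepl("^[0-9]+$", num) || as.numeric(num) < 1) {
      rlang::abort(sprintf(
        "invalid event number %s in event id %s", dQuote(num), dQuote(full)
      ))
    }
    tibble::tibble(
      event_id = full,
      symbol = paste(p[seq_len(length(p) - 2L)], collapse = "_"),
      event_number = as.integer(num),
      splice_type = type
    )
  })
  dplyr::bind_rows(out)
}

#' Format splicing-event identifiers
#'
#' Inverse of [parse_ase_id()]: builds `SYMBOL_NUMBER_TYPE` strings.
#'
#' @param symbol gene symbol(s).
#' @param event_number positive integer event id(s).
#' @param splice_type splice-type code(s), one of [ase_types].
#'
#' @return Character vector of event identifiers.
#' @export
format_ase_id <- function(symbol, event_number, splice_type) {
  stopifnot(is.character(symbol), all(nzchar(symbol)))
  if (any(!splice_type %in% ase_types)) {
    bad <- unique(splice_type[!splice_type %in% ase_types])
    rlang::abort(sprintf("unknown splice type(s): %s",
                         paste(dQuote(bad), collapse = ", ")))
  }
  if (any(event_number < 1) || any(event_number != round(event_number))) {
    rlang::abort("`event_number` must be positive integers")
  }
  paste(symbol, as.integer(event_number), splice_type, sep = "_")
}
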