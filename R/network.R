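#' Build the tripartite triplet network
#'
#' Each triplet contributes three undirected edges — TF–RBP, TF–ASE and
#' RBP–ASE — deduplicated across triplets.  Nodes carry a `partition`
#' attribute (`tf`, `rbp` or `ase`); ASE nodes keep their full event id as
#' the node name and record the host gene symbol in `host_gene` (used for
#' gene-level PPI matching).  A symbol appearing in more than one partition
#' (e.g. a gene listed as both TF and RBP) is kept as a single node with
#' the partitions joined by `;` and reported via a message.
#'
#' @param triplets triplet tibble with columns `tf`, `rbp`, `event_id`;
#'   when a `significant` column is present only significant rows are used.
#' @return An [igraph::igraph] with vertex attributes `partition` and
#'   `host_gene` and edge attribute `edge_class` in
#'   `{"tf-rbp", "tf-ase", "rbp-ase"}`.
#' @export
build_network <- function(triplets) {
  stopifnot(all(c("tf", "rbp", "event_id") %in% names(triplets)))
  if ("significant" %in% names(triplets)) {
    triplets <- triplets[triplets$significant, ]
  }
  edges <- dplyr::bind_rows(
    tibble::tibble(from = triplets$tf, to = triplets$rbp,
                   edge_class = "tf-rbp"),
    tibble::tibble(from = triplets$tf, to = triplets$event_id,
                   edge_class = "tf-ase"),
    tibble::tibble(from = triplets$rbp, to = triplets$event_id,
                   edge_class = "rbp-ase")
  )
  # canonical order so (A,B) and (B,A) deduplicate as one undirected edge
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]
  edges$from[swap] <- edges$to[swap]
  edges$to[swap] <- tmp
  edges <- dplyr::distinct(edges)

  nodes <- dplyr::bind_rows(
    tibble::tibble(name = unique(triplets$tf), partition = "tf"),
    tibble::tibble(name = unique(triplets$rbp), partition = "rbp"),
    tibble::tibble(name = unique(triplets$event_id), partition = "ase")
  )
  collided <- nodes$name[duplicated(nodes$name)]
  if (length(collided)) {
    rlang::inform(paste0(
      "build_network: symbol(s) present in multiple partitions: ",
      paste(unique(collided), collapse = ", ")
    ))
    nodes <- nodes |>
      dplyr::group_by(.data$name) |>
      dplyr::summarise(partition = paste(sort(unique(.data$partition)),
                                         collapse = ";"),
                       .groups = "drop")
  }
  nodes$host_gene <- nodes$name
  is_ase <- grepl("ase", nodes$partition, fixed = TRUE)
  if (any(is_ase)) {
    nodes$host_gene[is_ase] <- parse_ase_id(nodes$name[is_ase])$symbol
  }
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}

ppi_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Overlap of network edges with a reference PPI edge list
#'
#' Matches the network's edges against an undirected protein-protein
#' interaction list by gene symbol (ASE endpoints are mapped to their host
#' gene), ignoring pair order, and reports the overlap per edge class.
#'
#' @param network tripartite network from [build_network()].
#' @param ppi_edges tibble with two symbol columns (e.g. from
#'   [read_ppi()]).
#' @return A tibble with columns `edge_class`, `n_edges`, `n_overlap`.
#' @export
ppi_overlap <- function(network, ppi_edges) {
  stopifnot(igraph::is_igraph(network), ncol(ppi_edges) >= 2L)
  ref <- unique(ppi_key(as.character(ppi_edges[[1]]),
                        as.character(ppi_edges[[2]])))
  el <- igraph::as_data_frame(network, what = "edges")
  host <- setNames(igraph::V(network)$host_gene, igraph::V(network)$name)
  hit <- ppi_key(host[el$from], host[el$to]) %in% ref
  tibble::tibble(edge_class = c("tf-rbp", "tf-ase", "rbp-ase")) |>
    dplyr::left_join(
      dplyr::summarise(dplyr::group_by(
        tibble::tibble(edge_class = el$edge_class, hit = hit),
        .data$edge_class
      ), n_edges = dplyr::n(), n_overlap = sum(.data$hit), .groups = "drop"),
      by = "edge_class"
    ) |>
    dplyr::mutate(dplyr::across(c("n_edges", "n_overlap"),
                                ~ dplyr::coalesce(.x, 0L)))
}

#' Overlap of a gene set with a reference list
#'
#' Counts `|genes ∩ reference|` and formats the fraction of the gene set as
#' a two-decimal percent (e.g. 122 of 477 prints as `"25.58%"`).
#'
#' @param genes non-empty character vector (duplicates ignored).
#' @param reference character vector of reference symbols.
#' @return A list with `count`, `total`, `percent` and `label`.
#' @export
overlap_fraction <- function(genes, reference) {
  genes <- unique(genes)
  if (!length(genes)) rlang::abort("`genes` must be non-empty")
  format_percent(length(intersect(genes, reference)), length(genes))
}

#' Export the triplet network
#'
#' Writes the network as any of: a SIF file (`edges.sif`), GraphML
#' (`network.graphml`), and tab-delimited edge/node tables (`edges.tsv`,
#' `nodes.tsv`).
#'
#' @param network network from [build_network()].
#' @param dir output directory (created if needed).
#' @param formats subset of `c("sif", "graphml", "tsv")`.
#' @return Invisibly, the paths written.
#' @export
export_network <- function(network, dir, formats = c("sif", "graphml", "tsv")) {
  stopifnot(igraph::is_igraph(network))
  formats <- match.arg(formats, several.ok = TRUE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  el <- igraph::as_data_frame(network, what = "edges")
  paths <- character(0)
  if ("sif" %in% formats) {
    p <- file.path(dir, "edges.sif")
    readr::write_tsv(tibble::tibble(source = el$from,
                                    interaction = el$edge_class,
                                    target = el$to),
                     p, col_names = FALSE, progress = FALSE)
    paths <- c(paths, p)
  }
  if ("graphml" %in% formats) {
    p <- file.path(dir, "network.graphml")
    igraph::write_graph(network, p, format = "graphml")
    paths <- c(paths, p)
  }
  if ("tsv" %in% formats) {
    pe <- file.path(dir, "edges.tsv")
    pn <- file.path(dir, "nodes.tsv")
    readr::write_tsv(el, pe, progress = FALSE)
    nodes <- igraph::as_data_frame(network, what = "vertices")
    nodes$degree <- igraph::degree(network)[nodes$name]
    readr::write_tsv(tibble::as_tibble(nodes), pn, progress = FALSE)
    paths <- c(paths, pe, pn)
  }
  invisible(paths)
}
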