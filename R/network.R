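#' Read a protein-protein interaction edge list
#'
#' Reads an undirected PPI network from either a plain two-column
#' tab-separated edge list or a BioGRID TAB-delimited export. Gene symbols
#' are taken verbatim (no case folding, no alias resolution); self-loops and
#' duplicate rows survive until [preprocess_network()].
#'
#' @param path Path to the edge-list file.
#' @param format `"tsv2col"` (first two tab-separated columns, `#` comment
#'   lines ignored, optional header) or `"biogrid_tab"` (header naming the
#'   two interactor-symbol columns).
#' @param symbol_cols For `biogrid_tab`: the two header names holding the
#'   official gene symbols of the interactors.
#' @return A tibble with columns `from` and `to`, one row per parsed edge.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("A\tB", "B\tC", "A\tB"), f)
#' read_ppi_edges(f)
#' @export
read_ppi_edges <- function(path,
                           format = c("tsv2col", "biogrid_tab"),
                           symbol_cols = c("Official Symbol Interactor A",
                                           "Official Symbol Interactor B")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("cannot read network file '%s': no such file", path))
  }
  if (format == "tsv2col") {
    raw <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE)
    if (nrow(raw) == 0 || ncol(raw) == 0) {
      abort(sprintf("empty input: no edges parsed from '%s'", path))
    }
    if (ncol(raw) < 2) {
      abort("format error: tsv2col input needs at least 2 tab-separated columns")
    }
    # tolerate a header row such as "from\tto"
    if (nrow(raw) > 0 && tolower(raw[[1]][1]) %in% c("from", "source", "genea", "gene_a") &&
        tolower(raw[[2]][1]) %in% c("to", "target", "geneb", "gene_b")) {
      raw <- raw[-1, ]
    }
    edges <- tibble(from = raw[[1]], to = raw[[2]])
  } else {
    raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
    missing_cols <- setdiff(symbol_cols, names(raw))
    if (length(missing_cols) > 0) {
      abort(sprintf("format error: missing BioGRID column(s): %s",
                    paste(missing_cols, collapse = ", ")))
    }
    edges <- tibble(from = raw[[symbol_cols[1]]], to = raw[[symbol_cols[2]]])
  }
  edges <- filter(edges, !is.na(.data$from), !is.na(.data$to),
                  .data$from != "", .data$to != "")
  if (nrow(edges) == 0) {
    abort(sprintf("empty input: no edges parsed from '%s'", path))
  }
  edges
}

#' Build a PPI network object from an edge table
#'
#' Constructs the undirected interaction network used throughout the
#' pipeline. The raw constructor keeps self-loops and duplicate edges;
#' call [preprocess_network()] to clean it.
#'
#' @param edges A data frame whose first two columns are gene identifiers
#'   of interacting pairs.
#' @return A `ppi_network` object (an undirected igraph with class
#'   `ppi_network` prepended).
#' @export
ppi_network <- function(edges) {
  stopifnot(is.data.frame(edges), ncol(edges) >= 2)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges[[1]]), to = as.character(edges[[2]]),
               stringsAsFactors = FALSE),
    directed = FALSE
  )
  class(g) <- unique(c("ppi_network", class(g)))
  g
}

as_ppi_network <- function(x) {
  if (inherits(x, "igraph")) {
    class(x) <- unique(c("ppi_network", class(x)))
    return(x)
  }
  if (is.data.frame(x)) return(ppi_network(x))
  abort("expected a ppi_network, igraph, or edge data frame")
}

#' Clean a PPI network
#'
#' Applies the standard reference-network preprocessing: self-interactions
#' are removed, duplicate edges collapsed, and proteins left without any
#' interaction partner dropped, in that order.
#'
#' @param net A `ppi_network` (or igraph / edge data frame).
#' @param quiet Suppress the removal-count message.
#' @return A cleaned `ppi_network`: simple (no loops or multi-edges) with
#'   every node of degree >= 1. Idempotent on already-clean networks.
#' @export
preprocess_network <- function(net, quiet = FALSE) {
  g <- as_ppi_network(net)
  n0 <- igraph::vcount(g)
  e0 <- igraph::ecount(g)
  g <- igraph::simplify(g, remove.loops = TRUE, remove.multiple = TRUE)
  isolated <- which(igraph::degree(g) == 0)
  g <- igraph::delete_vertices(g, isolated)
  if (igraph::vcount(g) == 0) {
    abort("empty network after removing self-interactions and isolated proteins")
  }
  if (!quiet) {
    inform(sprintf(
      "preprocess_network: removed %d self-loop/duplicate edge(s), %d isolated node(s); %d nodes, %d edges remain",
      e0 - igraph::ecount(g), length(isolated),
      igraph::vcount(g), igraph::ecount(g)))
  }
  class(g) <- unique(c("ppi_network", class(g)))
  g
}

#' Distinct node degrees of a network
#'
#' The degree classes of the reference network index the empirical null
#' model: one null distribution is built per seed degree class.
#'
#' @param net A preprocessed `ppi_network`.
#' @return Strictly increasing integer vector of distinct node degrees.
#' @export
degree_classes <- function(net) {
  g <- as_ppi_network(net)
  sort(unique(as.integer(igraph::degree(g))))
}

#' Unweighted shortest-path length between two genes
#'
#' @param net A `ppi_network`.
#' @param u,v Gene identifiers present in the network.
#' @return A positive integer, or `Inf` when `u` and `v` lie in different
#'   connected components.
#' @export
path_length <- function(net, u, v) {
  g <- as_ppi_network(net)
  nodes <- igraph::V(g)$name
  missing_nodes <- setdiff(c(u, v), nodes)
  if (length(missing_nodes) > 0) {
    abort(sprintf("node(s) not in network: %s",
                  paste(missing_nodes, collapse = ", ")))
  }
  as.vector(igraph::distances(g, v = u, to = v))
}

#' Order-independent fingerprint of a network's edge set
#'
#' Used to check that a serialized null model was built on the same
#' reference network it is applied to.
#'
#' @param net A `ppi_network`.
#' @return A character hash of the sorted undirected edge list.
#' @export
network_hash <- function(net) {
  g <- as_ppi_network(net)
  el <- igraph::as_edgelist(g)
  key <- sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "\t"))
  rlang::hash(key)
}

#' Write a network as a two-column TSV edge list
#' @param net A `ppi_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  g <- as_ppi_network(net)
  el <- igraph::as_edgelist(g)
  readr::write_tsv(tibble(from = el[, 1], to = el[, 2]), path)
  invisible(path)
}

#' Write a network in GraphML format
#' @inheritParams write_edge_list
#' @export
write_graphml <- function(net, path) {
  g <- as_ppi_network(net)
  class(g) <- "igraph"
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @method tidy ppi_network
#' @export
tidy.ppi_network <- function(x, ...) {
  el <- igraph::as_edgelist(x)
  tibble(from = el[, 1], to = el[, 2])
}

#' @method glance ppi_network
#' @export
glance.ppi_network <- function(x, ...) {
  tibble(
    n_nodes = igraph::vcount(x),
    n_edges = igraph::ecount(x),
    n_degree_classes = length(degree_classes(x)),
    n_components = igraph::count_components(x)
  )
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %d nodes, %d edges, %d components\n",
              igraph::vcount(x), igraph::ecount(x),
              igraph::count_components(x)))
  invisible(x)
}
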