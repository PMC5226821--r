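#' Pool significant seed-candidate interactions across replicate sets
#'
#' Collapses kept assessments from all replicate sets into a universal
#' pool of undirected candidate edges. Only pairs whose BOTH endpoints
#' are differentially methylated genes in at least one replicate set
#' (not necessarily the same one) enter the pool; an edge observed in
#' both orientations within one replicate set counts once for that set.
#'
#' @param assessments Tibble of assessments (rows from
#'   [assess_candidates()] over all seeds and replicate sets).
#' @param dmmg_union Character vector: the union of DmMG genes over all
#'   replicate sets.
#' @return A tibble, one row per undirected pair: `from`, `to` (sorted
#'   within pair), `recurrence` (number of distinct replicate sets),
#'   `rs_ids` (comma-joined), `min_L`, `min_p`.
#' @export
pool_edges <- function(assessments, dmmg_union) {
  kept <- filter(assessments, .data$kept)
  if (nrow(kept) == 0) {
    return(tibble(from = character(), to = character(),
                  recurrence = integer(), rs_ids = character(),
                  min_L = double(), min_p = double()))
  }
  kept |>
    filter(.data$seed %in% dmmg_union, .data$candidate %in% dmmg_union) |>
    mutate(from = pmin(.data$seed, .data$candidate),
           to = pmax(.data$seed, .data$candidate)) |>
    group_by(.data$from, .data$to) |>
    summarise(
      recurrence = dplyr::n_distinct(.data$rs_id),
      rs_ids = paste(sort(unique(.data$rs_id)), collapse = ","),
      min_L = min(.data$L),
      min_p = min(.data$p),
      .groups = "drop"
    ) |>
    arrange(.data$from, .data$to)
}

#' Weighted consensus score of pooled edges
#'
#' For each replicate set in which an edge occurs, the edge weight is
#' `w = (-log10(x) - log10(y)) / 2` where x and y are the gene-level
#' methylation FDRs of the two endpoints in that replicate set; the
#' consensus score `s` is the sum of w over the occurring sets. An
#' endpoint that is not a DmMG in a given set contributes its best FDR
#' across all sets (logged); FDRs of exactly 0 are floored.
#'
#' @param pool Tibble from [pool_edges()].
#' @param genesets Tibble of per-replicate-set gene calls
#'   ([sites_to_genes()] rows bound together), with `rs_id`, `gene`,
#'   `best_fdr`.
#' @param fdr_floor Lower bound applied to FDRs before taking logs
#'   (default 1e-300).
#' @return `pool` with an added `score` column.
#' @export
weighted_consensus_score <- function(pool, genesets, fdr_floor = 1e-300) {
  if (nrow(pool) == 0) return(mutate(pool, score = double()))
  if (any(genesets$best_fdr < fdr_floor)) {
    warn(sprintf("FDR value(s) below %g floored before log transform", fdr_floor))
  }
  per_rs <- genesets |>
    mutate(fdr = pmax(.data$best_fdr, fdr_floor)) |>
    select("rs_id", "gene", "fdr")
  best_overall <- per_rs |>
    group_by(.data$gene) |>
    summarise(fdr_best = min(.data$fdr), .groups = "drop")
  n_filled <- 0L
  lookup <- function(gene, rs) {
    hit <- per_rs$fdr[per_rs$gene == gene & per_rs$rs_id == rs]
    if (length(hit) > 0) return(hit[1])
    n_filled <<- n_filled + 1L
    best_overall$fdr_best[best_overall$gene == gene]
  }
  score <- purrr::map2_dbl(
    seq_len(nrow(pool)), strsplit(pool$rs_ids, ","),
    function(i, rs_vec) {
      sum(vapply(rs_vec, function(rs) {
        x <- lookup(pool$from[i], rs)
        y <- lookup(pool$to[i], rs)
        (-log10(x) - log10(y)) / 2
      }, double(1)))
    }
  )
  if (n_filled > 0) {
    inform(sprintf(
      "weighted_consensus_score: %d endpoint FDR(s) gap-filled with the gene's best FDR across replicate sets",
      n_filled))
  }
  mutate(pool, score = score)
}

#' Build the consensus methylation-driven network
#'
#' Retains pooled edges that recur in at least `min_recurrence` replicate
#' sets (default: every set, the published rule). The genes incident to a
#' retained edge are the predicted m6A-driven genes (mDrGenes); each is
#' annotated with its hyper/hypo label (majority vote over the replicate
#' sets calling it, ties resolved by the direction of its globally
#' best-FDR call) and the number of sets in which it is a DmMG.
#'
#' @param pool Tibble from [pool_edges()] (a `score` column, if present,
#'   is carried through).
#' @param genesets Per-replicate-set gene calls used for node annotation.
#' @param n_rs Number of replicate sets in the study (default: number of
#'   distinct `rs_id` in `genesets`).
#' @param min_recurrence Minimum number of sets an edge must recur in;
#'   default `n_rs` ("consistently occur in every replicate set").
#' @return A `consensus_network`: list with tibbles `edges` and `nodes`
#'   plus `n_rs` and `min_recurrence`.
#' @export
build_consensus <- function(pool, genesets, n_rs = NULL,
                            min_recurrence = NULL) {
  n_rs <- n_rs %||% dplyr::n_distinct(genesets$rs_id)
  min_recurrence <- min_recurrence %||% n_rs
  stopifnot(is_count(n_rs), is_count(min_recurrence))
  edges <- filter(pool, .data$recurrence >= min_recurrence)
  if (nrow(edges) == 0) {
    warn("empty consensus network: no edge meets the recurrence rule")
    nodes <- tibble(gene = character(), label = character(),
                    n_rs_dmmg = integer())
  } else {
    genes <- sort(unique(c(edges$from, edges$to)))
    nodes <- purrr::map_dfr(genes, function(gn) {
      calls <- filter(genesets, .data$gene == gn)
      if (nrow(calls) == 0) {
        return(tibble(gene = gn, label = NA_character_, n_rs_dmmg = 0L))
      }
      n_hyper <- sum(calls$label == "hyper")
      n_hypo <- sum(calls$label == "hypo")
      label <- if (n_hyper != n_hypo) {
        if (n_hyper > n_hypo) "hyper" else "hypo"
      } else {
        best <- calls |>
          arrange(.data$best_fdr, -abs(.data$best_log2fc))
        best$label[1]
      }
      tibble(gene = gn, label = label,
             n_rs_dmmg = dplyr::n_distinct(calls$rs_id))
    })
  }
  structure(
    list(edges = edges, nodes = nodes, n_rs = as.integer(n_rs),
         min_recurrence = as.integer(min_recurrence)),
    class = "consensus_network"
  )
}

#' Genes of a consensus network
#' @param cn A `consensus_network`.
#' @return Character vector of predicted m6A-driven genes.
#' @export
mdr_genes <- function(cn) {
  stopifnot(inherits(cn, "consensus_network"))
  cn$nodes$gene
}

#' Write a consensus network to disk
#'
#' @param cn A `consensus_network`.
#' @param path Output path. For `tsv`, two files are written:
#'   `<path>_edges.tsv` and `<path>_nodes.tsv`; for `graphml` and `sif`,
#'   `path` is used as-is.
#' @param format One of `"tsv"`, `"graphml"`, `"sif"`.
#' @return The path(s) written, invisibly.
#' @export
write_consensus <- function(cn, path, format = c("tsv", "graphml", "sif")) {
  stopifnot(inherits(cn, "consensus_network"))
  format <- match.arg(format)
  if (format == "tsv") {
    paths <- paste0(path, c("_edges.tsv", "_nodes.tsv"))
    readr::write_tsv(cn$edges, paths[1])
    readr::write_tsv(cn$nodes, paths[2])
    return(invisible(paths))
  }
  g <- igraph::graph_from_data_frame(cn$edges, directed = FALSE,
                                     vertices = cn$nodes)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    lines <- sprintf("%s\tpp\t%s", cn$edges$from, cn$edges$to)
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read back a TSV-serialized consensus network
#' @param path The prefix given to [write_consensus()] with
#'   `format = "tsv"`.
#' @return A `consensus_network`.
#' @export
read_consensus <- function(path) {
  edges <- readr::read_tsv(paste0(path, "_edges.tsv"),
                           col_types = readr::cols(), progress = FALSE)
  nodes <- readr::read_tsv(paste0(path, "_nodes.tsv"),
                           col_types = readr::cols(), progress = FALSE)
  if ("recurrence" %in% names(edges)) {
    edges$recurrence <- as.integer(edges$recurrence)
  }
  if ("n_rs_dmmg" %in% names(nodes)) {
    nodes$n_rs_dmmg <- as.integer(nodes$n_rs_dmmg)
  }
  structure(
    list(edges = as_tibble(edges), nodes = as_tibble(nodes),
         n_rs = if (nrow(edges)) max(edges$recurrence) else NA_integer_,
         min_recurrence = if (nrow(edges)) min(edges$recurrence) else NA_integer_),
    class = "consensus_network"
  )
}

#' @method tidy consensus_network
#' @export
tidy.consensus_network <- function(x, ...) x$edges

#' @method glance consensus_network
#' @export
glance.consensus_network <- function(x, ...) {
  tibble(
    n_mdr_genes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_hyper = sum(x$nodes$label == "hyper", na.rm = TRUE),
    n_hypo = sum(x$nodes$label == "hypo", na.rm = TRUE),
    n_rs = x$n_rs,
    min_recurrence = x$min_recurrence
  )
}

#' @export
print.consensus_network <- function(x, ...) {
  cat(sprintf(
    "<consensus_network> %d mDrGenes, %d edges (recurrence >= %s of %s replicate sets)\n",
    nrow(x$nodes), nrow(x$edges), x$min_recurrence, x$n_rs))
  invisible(x)
}
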