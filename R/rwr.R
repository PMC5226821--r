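#' Column-stochastic transition matrix of a network
#'
#' Builds the sparse column-normalized adjacency matrix used by the random
#' walk: entry (i, j) is 1/degree(j) when i and j interact, else 0. Nodes
#' are ordered lexicographically so the matrix is deterministic for a
#' given network.
#'
#' @param net A preprocessed `ppi_network` (no degree-0 nodes).
#' @return A `dgCMatrix` with row/column names in lexicographic node order;
#'   every column sums to 1.
#' @export
transition_matrix <- function(net) {
  g <- as_ppi_network(net)
  nodes <- sort(igraph::V(g)$name, method = "radix")
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)[nodes, nodes]
  deg <- Matrix::colSums(A)
  if (any(deg == 0)) {
    abort("internal invariant violation: degree-0 node in preprocessed network")
  }
  M <- A %*% Matrix::Diagonal(x = 1 / deg)
  dimnames(M) <- list(nodes, nodes)
  methods::as(M, "CsparseMatrix")
}

#' Random walk with restart
#'
#' Iterates p_{t+1} = (1 - restart) * M p_t + restart * p_0 from a uniform
#' distribution over the seed genes (p_0 = 1/k on each of the k seeds)
#' until the L1 difference between successive vectors falls below `tol`.
#' The stationary probability of each gene measures its network closeness
#' to the seeds; mass never leaves the seeds' connected component(s).
#'
#' @param M Transition matrix from [transition_matrix()], or a
#'   `ppi_network` (converted internally).
#' @param seeds Non-empty character vector of seed genes.
#' @param restart Restart probability at each step, in (0, 1]; default 0.5.
#' @param tol L1 convergence threshold; default 1e-6.
#' @param max_iter Iteration cap; non-convergence warns but is not fatal.
#' @return A tibble (`node`, `probability`) in the matrix node order, with
#'   attributes `seeds`, `iterations`, `converged`.
#' @examples
#' net <- preprocess_network(ppi_network(data.frame(from = c("A", "B"),
#'                                                  to   = c("B", "C"))),
#'                           quiet = TRUE)
#' rwr <- random_walk_restart(net, "A")
#' rwr$probability  # (7/12, 1/3, 1/12)
#' @export
random_walk_restart <- function(M, seeds, restart = 0.5, tol = 1e-6,
                                max_iter = 10000L) {
  if (inherits(M, "igraph")) M <- transition_matrix(M)
  assert_scalar_prob(restart, "restart", lo = 0, hi = 1, lo_open = TRUE)
  stopifnot(tol > 0, is_count(max_iter))
  nodes <- rownames(M)
  seeds <- unique(as.character(seeds))
  if (length(seeds) == 0) abort("at least one seed gene is required")
  missing_seeds <- setdiff(seeds, nodes)
  if (length(missing_seeds) > 0) {
    abort(sprintf("seed gene(s) not in network: %s",
                  paste(missing_seeds, collapse = ", ")))
  }
  p0 <- numeric(length(nodes))
  names(p0) <- nodes
  p0[seeds] <- 1 / length(seeds)
  p <- p0
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    p_new <- as.numeric((1 - restart) * (M %*% p)) + restart * p0
    delta <- sum(abs(p_new - p))
    p <- p_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(sprintf("random walk did not converge in %d iterations", max_iter))
  }
  out <- tibble(node = nodes, probability = as.numeric(p))
  attr(out, "seeds") <- seeds
  attr(out, "iterations") <- iter
  attr(out, "converged") <- converged
  out
}

#' Top-ranked non-seed candidates of a random walk
#'
#' Ranks non-seed genes by stationary probability (descending), breaking
#' ties lexicographically by gene identifier, and returns the top `k`.
#' Genes with zero probability (outside the seeds' component) are never
#' candidates, so fewer than `k` rows may be returned.
#'
#' @param p Result of [random_walk_restart()].
#' @param k Number of candidates to keep (default 10).
#' @return A tibble (`node`, `probability`, `rank`).
#' @export
top_candidates <- function(p, k = 10L) {
  stopifnot(is_count(k))
  seeds <- attr(p, "seeds") %||% character()
  cand <- p |>
    filter(!(.data$node %in% seeds), .data$probability > 0) |>
    arrange(desc(.data$probability), .data$node) |>
    head(k)
  mutate(cand, rank = row_number())
}

#' Write per-seed random-walk probabilities as TSV
#' @param p Result of [random_walk_restart()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rwr_probabilities <- function(p, path) {
  out <- p |>
    arrange(desc(.data$probability), .data$node) |>
    mutate(rank = row_number())
  readr::write_tsv(out, path)
  invisible(path)
}
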