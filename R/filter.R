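#' The candidate keep rule
#'
#' A candidate is significant when its empirical p-value beats `alpha`
#' (strict inequality) or it directly interacts with its seed (`L == 1`).
#' Unreachable candidates (`L = Inf`) can only be kept on the p branch.
#'
#' @param p Empirical p-value(s).
#' @param L Shortest-path length(s) to the seed (`Inf` = unreachable).
#' @param alpha Significance level (default 0.05).
#' @return Logical vector of keep verdicts.
#' @export
keep_rule <- function(p, L, alpha = 0.05) {
  p < alpha | L == 1
}

#' Assess random-walk candidates for topological and biological significance
#'
#' For each candidate of a seed gene, computes the degree-conditioned
#' empirical p-value (topological significance) and the shortest-path
#' length L to the seed (biological significance), and applies the keep
#' rule: a candidate is retained iff `p < alpha` or `L == 1` (a direct
#' interaction). The p-value comparison is strict: a candidate at exactly
#' `alpha` with L > 1 is dropped.
#'
#' @param candidates Tibble from [top_candidates()] (`node`,
#'   `probability`, `rank`).
#' @param net The reference `ppi_network`.
#' @param seed The seed gene (a network node).
#' @param model A fitted `null_pvalue_model` for this network.
#' @param alpha Significance level (default 0.05).
#' @param rs_id Optional replicate-set label attached to the result.
#' @return A tibble, one row per candidate in input order: `rs_id`,
#'   `seed`, `candidate`, `rank`, `probability`, `p`, `L`, `kept`.
#' @export
assess_candidates <- function(candidates, net, seed, model, alpha = 0.05,
                              rs_id = NA_character_) {
  g <- as_ppi_network(net)
  assert_scalar_prob(alpha, "alpha", lo = 0, hi = 1)
  nodes <- igraph::V(g)$name
  if (!(seed %in% nodes)) {
    abort(sprintf("seed gene '%s' is not in the network", seed))
  }
  unknown <- setdiff(candidates$node, nodes)
  if (length(unknown) > 0) {
    warn(sprintf("skipping %d candidate(s) not in the network: %s",
                 length(unknown), paste(unknown, collapse = ", ")))
    candidates <- filter(candidates, .data$node %in% nodes)
  }
  if (nrow(candidates) == 0) {
    return(tibble(rs_id = character(), seed = character(),
                  candidate = character(), rank = integer(),
                  probability = double(), p = double(), L = double(),
                  kept = logical()))
  }
  deg <- igraph::degree(g)
  p <- empirical_pvalue(model, as.integer(deg[seed]),
                        as.integer(deg[candidates$node]))
  L <- as.vector(igraph::distances(g, v = seed, to = candidates$node))
  tibble(
    rs_id = rs_id,
    seed = seed,
    candidate = candidates$node,
    rank = candidates$rank,
    probability = candidates$probability,
    p = p,
    L = L,
    kept = keep_rule(p, L, alpha)
  )
}

#' Write a per-replicate-set candidate assessment table
#' @param assessments Tibble from [assess_candidates()] (possibly several
#'   seeds bound together).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_assessments <- function(assessments, path) {
  readr::write_tsv(assessments, path)
  invisible(path)
}
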