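#' Degree-preserving network randomization
#'
#' Rewires the network by repeated double-edge switches (the standard
#' switching algorithm): two edges (a,b), (c,d) are replaced by (a,c),
#' (b,d) unless that would create a self-loop or duplicate edge. Every
#' node keeps its exact degree and the network stays simple.
#'
#' @param net A preprocessed `ppi_network` with at least 2 edges.
#' @param switches_per_edge Attempted switches per edge (total attempts =
#'   this times the edge count); default 10.
#' @param seed Optional integer seed making the rewiring deterministic.
#' @return A rewired `ppi_network` with the same nodes and degree map.
#' @export
randomize_network <- function(net, switches_per_edge = 10L, seed = NULL) {
  g <- as_ppi_network(net)
  if (igraph::ecount(g) < 2) {
    abort("randomization error: network must have at least 2 edges")
  }
  stopifnot(is_count(switches_per_edge))
  niter <- as.integer(switches_per_edge) * igraph::ecount(g)
  r <- with_seed_or_ambient(seed, {
    igraph::rewire(g, with = igraph::keeping_degseq(loops = FALSE,
                                                    niter = niter))
  })
  class(r) <- unique(c("ppi_network", class(r)))
  r
}

#' Null occurrence table from random networks
#'
#' Builds the degree-conditioned empirical null. For each of `n_networks`
#' degree-preserving random copies of the reference network and each seed
#' degree class, one uniformly drawn node of that degree seeds a random
#' walk with restart; the degrees of its top-`k` candidates are pooled
#' into the class's occurrence multiset S_j. The occurrence frequency of
#' candidate degree d_i under seed class j is
#' `freq_ij = (# occurrences of degree-d_i genes in S_j) / (# degree-d_i
#' genes in the reference network)` and the empirical p-value is
#' `p_ij = freq_ij / n_networks`.
#'
#' @param net A preprocessed `ppi_network`.
#' @param n_networks Number of random networks (default 100).
#' @param k Top-k candidates per walk (default 10).
#' @param switches_per_edge Passed to [randomize_network()].
#' @param restart,tol,max_iter Random-walk parameters, see
#'   [random_walk_restart()].
#' @param seed Integer seed; sub-streams are derived per (network, class)
#'   so the table is fully deterministic.
#' @return A tibble over the full seed-degree x candidate-degree grid:
#'   `seed_degree`, `candidate_degree`, `n_random` (occurrences in S_j),
#'   `n_ppi` (genes of that degree in the reference network), `freq`, `p`.
#'   Raw values are not clipped; clipping to [0, 1] happens at fit time.
#' @export
null_occurrence_table <- function(net, n_networks = 100L, k = 10L,
                                  switches_per_edge = 10L,
                                  restart = 0.5, tol = 1e-6,
                                  max_iter = 10000L, seed = 1L) {
  g <- as_ppi_network(net)
  stopifnot(is_count(n_networks), is_count(k))
  deg <- igraph::degree(g)
  classes <- sort(unique(as.integer(deg)))
  n_ppi <- vapply(classes, function(d) sum(deg == d), integer(1))
  names(n_ppi) <- classes
  nodes_by_degree <- split(names(deg), deg)

  counts <- matrix(0L, nrow = length(classes), ncol = length(classes),
                   dimnames = list(seed = classes, candidate = classes))
  for (r in seq_len(n_networks)) {
    g_r <- randomize_network(g, switches_per_edge = switches_per_edge,
                             seed = derive_seed(seed, r, 0L))
    M_r <- transition_matrix(g_r)
    for (j in seq_along(classes)) {
      pool <- nodes_by_degree[[as.character(classes[j])]]
      seed_node <- with_seed_or_ambient(
        derive_seed(seed, r, j),
        pool[sample.int(length(pool), 1L)]
      )
      p <- random_walk_restart(M_r, seed_node, restart = restart,
                               tol = tol, max_iter = max_iter)
      cand <- top_candidates(p, k = k)
      cand_deg <- as.integer(deg[cand$node])
      tab <- table(factor(cand_deg, levels = classes))
      counts[j, ] <- counts[j, ] + as.integer(tab)
    }
  }

  grid <- expand.grid(seed_degree = classes, candidate_degree = classes,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- as_tibble(grid[order(grid$seed_degree, grid$candidate_degree), ])
  grid$n_random <- as.integer(counts[cbind(
    match(grid$seed_degree, classes), match(grid$candidate_degree, classes))])
  grid$n_ppi <- n_ppi[as.character(grid$candidate_degree)]
  grid$freq <- grid$n_random / grid$n_ppi
  grid$p <- grid$freq / n_networks
  attr(grid, "n_networks") <- as.integer(n_networks)
  attr(grid, "k") <- as.integer(k)
  attr(grid, "switches_per_edge") <- as.integer(switches_per_edge)
  attr(grid, "rng_seed") <- as.integer(seed)
  attr(grid, "network_hash") <- network_hash(g)
  grid
}

fit_one_class <- function(d, p_raw, span) {
  p_clip <- pmin(pmax(p_raw, 0), 1)
  n_obs <- sum(p_raw > 0)
  used_fallback <- FALSE
  fitted <- if (n_obs >= 3 && length(d) >= 4) {
    f <- tryCatch(
      loess(p ~ x, data = data.frame(x = log10(d), p = p_clip),
            span = span, degree = 1, family = "gaussian",
            control = stats::loess.control(surface = "direct")),
      error = function(e) NULL
    )
    if (is.null(f)) {
      used_fallback <- TRUE
      p_clip
    } else {
      predict(f, newdata = data.frame(x = log10(d)))
    }
  } else {
    used_fallback <- TRUE
    p_clip
  }
  # isotonic projection: the null probability of being prioritized grows
  # with candidate degree, so wiggles at sparse degrees are projected out
  fitted <- isoreg(seq_along(d), fitted)$yf
  fitted <- pmin(pmax(fitted, 0), 1)
  list(p_fit = fitted, fallback = used_fallback)
}

#' Fit the empirical p-value surface
#'
#' For each seed degree class j, fits a smooth function f_j of candidate
#' degree to the raw empirical p-values by local regression on the
#' log-degree scale, projects it to be non-decreasing (isotonic
#' regression) and clips it to [0, 1]. Classes with fewer than 3 degrees
#' of non-zero occurrence fall back to a step interpolation of the raw
#' (clipped) p-values. Queries outside the observed degree range return
#' the boundary fitted value.
#'
#' @param table Output of [null_occurrence_table()].
#' @param span Nearest-neighbour fraction of the local regression
#'   (default 0.7).
#' @return A `null_pvalue_model` object.
#' @export
fit_null_model <- function(table, span = 0.7) {
  stopifnot(all(c("seed_degree", "candidate_degree", "p") %in% names(table)))
  classes <- sort(unique(table$seed_degree))
  fallback_classes <- integer()
  fitted <- purrr::map_dfr(classes, function(sd) {
    sub <- table |>
      filter(.data$seed_degree == sd) |>
      arrange(.data$candidate_degree)
    res <- fit_one_class(sub$candidate_degree, sub$p, span)
    if (res$fallback) fallback_classes <<- c(fallback_classes, sd)
    tibble(seed_degree = sd, candidate_degree = sub$candidate_degree,
           p = res$p_fit)
  })
  if (length(fallback_classes) > 0) {
    inform(sprintf(
      "fit_null_model: step-function fallback for %d seed class(es) with sparse occurrences",
      length(fallback_classes)))
  }
  structure(
    list(
      fitted = fitted,
      raw = table,
      classes = classes,
      fallback_classes = fallback_classes,
      span = span,
      k = attr(table, "k"),
      n_networks = attr(table, "n_networks"),
      switches_per_edge = attr(table, "switches_per_edge"),
      rng_seed = attr(table, "rng_seed"),
      network_hash = attr(table, "network_hash")
    ),
    class = "null_pvalue_model"
  )
}

#' Empirical p-value of a candidate given the seed's degree class
#'
#' Evaluates the fitted surface: the probability that a gene of degree
#' `candidate_degree` would be prioritized by chance from a seed of
#' degree `seed_degree`. Only two degree lookups and one interpolation —
#' no random walks are run at query time.
#'
#' @param model A `null_pvalue_model`.
#' @param seed_degree Degree of the seed gene (a degree class of the
#'   reference network; the nearest class is used, with a warning, if
#'   absent).
#' @param candidate_degree Degree(s) of the candidate gene(s).
#' @return Numeric vector of p-values in [0, 1].
#' @export
empirical_pvalue <- function(model, seed_degree, candidate_degree) {
  stopifnot(inherits(model, "null_pvalue_model"),
            length(seed_degree) == 1L)
  if (!(seed_degree %in% model$classes)) {
    nearest <- model$classes[which.min(abs(model$classes - seed_degree))]
    warn(sprintf("seed degree %d is not a degree class; using nearest class %d",
                 as.integer(seed_degree), as.integer(nearest)))
    seed_degree <- nearest
  }
  grid <- model$fitted |>
    filter(.data$seed_degree == !!seed_degree) |>
    arrange(.data$candidate_degree)
  if (nrow(grid) == 1L) {
    return(rep(grid$p, length(candidate_degree)))
  }
  approx(grid$candidate_degree, grid$p, xout = candidate_degree,
         method = "linear", rule = 2)$y
}

#' Serialize a fitted null model to a flat versioned file
#'
#' The model is written as a commented-header TSV so it can be built once
#' per reference network and reused across studies; the stored network
#' hash lets the pipeline refuse a model built on a different network.
#'
#' @param model A `null_pvalue_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_null_model <- function(model, path) {
  stopifnot(inherits(model, "null_pvalue_model"))
  hdr <- c(
    "# mdrnet null_pvalue_model v1",
    sprintf("# k: %d", model$k),
    sprintf("# n_networks: %d", model$n_networks),
    sprintf("# switches_per_edge: %d", model$switches_per_edge),
    sprintf("# rng_seed: %d", model$rng_seed),
    sprintf("# span: %g", model$span),
    sprintf("# network_hash: %s", model$network_hash)
  )
  writeLines(hdr, path)
  suppressWarnings(
    readr::write_tsv(model$fitted, path, append = TRUE, col_names = TRUE)
  )
  invisible(path)
}

#' Read a serialized null model
#' @param path File written by [write_null_model()].
#' @return A `null_pvalue_model` (without the raw occurrence table).
#' @export
read_null_model <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  if (length(hdr) == 0 || !grepl("mdrnet null_pvalue_model", hdr[1])) {
    abort(sprintf("'%s' is not an mdrnet null model file", path))
  }
  get_field <- function(key) {
    ln <- hdr[grepl(paste0("^# ", key, ":"), hdr)]
    if (length(ln) == 0) return(NA_character_)
    trimws(sub(paste0("^# ", key, ":"), "", ln[1]))
  }
  fitted <- readr::read_tsv(I(lines[!startsWith(lines, "#")]),
                            col_types = "iid", progress = FALSE)
  structure(
    list(
      fitted = fitted,
      raw = NULL,
      classes = sort(unique(fitted$seed_degree)),
      fallback_classes = integer(),
      span = as.numeric(get_field("span")),
      k = as.integer(get_field("k")),
      n_networks = as.integer(get_field("n_networks")),
      switches_per_edge = as.integer(get_field("switches_per_edge")),
      rng_seed = as.integer(get_field("rng_seed")),
      network_hash = get_field("network_hash")
    ),
    class = "null_pvalue_model"
  )
}

#' @method tidy null_pvalue_model
#' @export
tidy.null_pvalue_model <- function(x, ...) x$fitted

#' @method glance null_pvalue_model
#' @export
glance.null_pvalue_model <- function(x, ...) {
  tibble(
    n_classes = length(x$classes),
    n_networks = x$n_networks,
    k = x$k,
    switches_per_edge = x$switches_per_edge,
    span = x$span,
    n_fallback_classes = length(x$fallback_classes),
    network_hash = x$network_hash
  )
}

#' @export
print.null_pvalue_model <- function(x, ...) {
  cat(sprintf(
    "<null_pvalue_model> %d seed degree classes, %s random networks, top-%s\n",
    length(x$classes), x$n_networks %||% "?", x$k %||% "?"))
  invisible(x)
}
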