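#' Generate a toy protein interaction network
#'
#' Produces a small simple network with the degree heterogeneity of real
#' PPI data (scale-free by default) for testing and simulation. The
#' result always passes [preprocess_network()] unchanged.
#'
#' @param n_nodes Number of nodes (>= 10).
#' @param model `"barabasi_albert"` (preferential attachment, heavy-tailed
#'   degrees), `"erdos_renyi"`, or `"configuration"` (given degree
#'   sequence).
#' @param params Model parameters: `m` (edges per new node, default 2)
#'   for Barabasi-Albert; `p` (edge probability, default 0.05) for
#'   Erdos-Renyi; `degrees` (integer vector) for the configuration model.
#' @param seed Integer seed; the same seed always yields the same network.
#' @return A preprocessed `ppi_network` with nodes named `g0001`, ...
#' @export
generate_toy_ppi <- function(n_nodes, model = c("barabasi_albert",
                                                "erdos_renyi",
                                                "configuration"),
                             params = list(), seed = 1L) {
  model <- match.arg(model)
  stopifnot(is_count(n_nodes), n_nodes >= 10)
  g <- with_seed_or_ambient(seed, {
    switch(model,
      barabasi_albert = igraph::sample_pa(
        n_nodes, m = params$m %||% 2, directed = FALSE),
      erdos_renyi = igraph::sample_gnp(
        n_nodes, p = params$p %||% 0.05),
      configuration = igraph::sample_degseq(
        params$degrees %||% abort("configuration model needs params$degrees"),
        method = "fast.heur.simple")
    )
  })
  igraph::V(g)$name <- sprintf("g%04d", seq_len(igraph::vcount(g)))
  g <- igraph::simplify(g)
  g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  if (igraph::vcount(g) == 0) {
    abort("generation error: network parameters produced no connected nodes")
  }
  class(g) <- unique(c("ppi_network", class(g)))
  g
}

#' Generate a planted methylation study with known ground truth
#'
#' Emulates a replicate-set MeRIP-seq differential methylation study over
#' a reference network: a module of mutually well-interacting genes is
#' planted (a high-degree hub, its strongest neighbours, plus extra
#' within-module edges so the module is dense, mirroring the premise that
#' functionally related methylation-driven genes interact closely), and
#' per replicate set each module gene is emitted as 1-3 differential
#' sites with probability `1 - dropout` while each background gene is
#' spuriously called with probability `background_rate`. Planted sites
#' get FDRs log-uniform in [1e-10, 1e-3]; background sites sit just
#' under the 0.05 call threshold (log-uniform in [1e-3, 0.049]).
#'
#' @param net A preprocessed `ppi_network` (e.g. from
#'   [generate_toy_ppi()]).
#' @param module_size Number of planted module genes (default 12).
#' @param n_rs Number of replicate sets (default 4).
#' @param dropout Per-replicate-set probability a module gene is
#'   unobserved (default 0.3).
#' @param background_rate Per-replicate-set probability a background gene
#'   is spuriously called (default 0.02).
#' @param module_density Probability an extra edge is planted between a
#'   pair of module genes (default 0.5).
#' @param direction `"hyper"` (all planted log2 fold changes positive,
#'   the methylase-knockdown situation) or `"mixed"`.
#' @param seed Integer seed; deterministic output per seed.
#' @return A `planted_study`: list with `network` (the input network plus
#'   planted module edges), `module_genes`, `sites` (tibble of all sites
#'   with `rs_id`), `genesets` (per-RS gene calls at cutoff 0.05), and
#'   the generation parameters.
#' @export
generate_planted_study <- function(net, module_size = 12L, n_rs = 4L,
                                   dropout = 0.3, background_rate = 0.02,
                                   module_density = 0.5,
                                   direction = c("hyper", "mixed"),
                                   seed = 1L) {
  direction <- match.arg(direction)
  g <- as_ppi_network(net)
  stopifnot(is_count(module_size), is_count(n_rs))
  assert_scalar_prob(dropout, "dropout")
  assert_scalar_prob(background_rate, "background_rate")
  if (module_size > igraph::vcount(g)) {
    abort("generation error: module_size exceeds network size")
  }

  res <- with_seed_or_ambient(seed, {
    deg <- igraph::degree(g)
    hub <- names(deg)[which.max(deg)]
    nb <- igraph::neighbors(g, hub)$name
    nb <- nb[order(-deg[nb], nb)]
    module <- c(hub, nb)
    if (length(module) < module_size) {
      # widen to the 2-hop neighbourhood when the hub is too small
      two_hop <- unique(unlist(lapply(module, function(v)
        igraph::neighbors(g, v)$name)))
      extra <- setdiff(two_hop, module)
      module <- c(module, extra[order(-deg[extra], extra)])
    }
    if (length(module) < module_size) {
      abort("generation error: no sufficiently connected neighbourhood for the module")
    }
    module <- module[seq_len(module_size)]

    # plant within-module edges so module genes interact densely
    pairs <- utils::combn(sort(module), 2)
    have <- igraph::get_edge_ids(g, as.vector(pairs)) > 0
    add <- !have & runif(ncol(pairs)) < module_density
    if (any(add)) {
      g <- igraph::add_edges(g, as.vector(pairs[, add, drop = FALSE]))
    }

    background <- setdiff(igraph::V(g)$name, module)
    sites <- purrr::map_dfr(seq_len(n_rs), function(rs) {
      rs_id <- sprintf("RS%d", rs)
      obs_module <- module[runif(length(module)) >= dropout]
      mod_sites <- purrr::map_dfr(obs_module, function(gn) {
        k <- sample.int(3L, 1L)
        sgn <- if (direction == "hyper") rep(1, k) else sample(c(-1, 1), k, replace = TRUE)
        start <- sort(sample.int(100000L, k))
        tibble(
          rs_id = rs_id, gene = gn, chrom = "chr1",
          start = start, end = start + 100L, strand = "+",
          log2fc = sgn * runif(k, 0.5, 3),
          fdr = 10^runif(k, -10, -3)
        )
      })
      obs_bg <- background[runif(length(background)) < background_rate]
      bg_sites <- purrr::map_dfr(obs_bg, function(gn) {
        start <- sample.int(100000L, 1L)
        tibble(
          rs_id = rs_id, gene = gn, chrom = "chr1",
          start = start, end = start + 100L, strand = "+",
          log2fc = (if (direction == "hyper") 1 else sample(c(-1, 1), 1)) *
            runif(1, 0.5, 3),
          fdr = 10^runif(1, log10(1e-3), log10(0.049))
        )
      })
      bind_rows(mod_sites, bg_sites)
    })
    list(g = g, module = module, sites = sites)
  })

  class(res$g) <- unique(c("ppi_network", class(res$g)))
  genesets <- purrr::map_dfr(
    split(res$sites, res$sites$rs_id),
    function(s) sites_to_genes(s, s$rs_id[1], fdr_cutoff = 0.05)
  )
  structure(
    list(
      network = res$g,
      module_genes = res$module,
      sites = res$sites,
      genesets = genesets,
      n_rs = as.integer(n_rs),
      dropout = dropout,
      background_rate = background_rate,
      module_density = module_density,
      direction = direction,
      seed = seed
    ),
    class = "planted_study"
  )
}

#' Write a planted study to disk in the pipeline's input dialects
#'
#' Emits the TSV edge list [read_ppi_edges()] reads and one per-replicate
#' site table in the dialect [read_dmm_sites()] reads, guaranteeing a
#' generator-to-parser round trip.
#'
#' @param study A `planted_study`.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "planted_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  net_path <- file.path(dir, "network.tsv")
  write_edge_list(study$network, net_path)
  rs_ids <- sort(unique(study$sites$rs_id))
  site_paths <- vapply(rs_ids, function(rs) {
    p <- file.path(dir, paste0("sites_", rs, ".tsv"))
    study$sites |>
      filter(.data$rs_id == rs) |>
      select(gene = "gene", chr = "chrom", chromStart = "start",
             chromEnd = "end", strand = "strand", log2.fc = "log2fc",
             fdr = "fdr") |>
      readr::write_tsv(p)
    p
  }, character(1))
  invisible(list(network = net_path, sites = site_paths))
}

#' @export
print.planted_study <- function(x, ...) {
  cat(sprintf(
    "<planted_study> %d-gene module in %d-node network, %d replicate sets (dropout %.2f, background %.3f)\n",
    length(x$module_genes), igraph::vcount(x$network), x$n_rs,
    x$dropout, x$background_rate))
  invisible(x)
}
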