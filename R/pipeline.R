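#' Run the methylation-driven network pipeline on gene calls
#'
#' Orchestrates the per-replicate-set propagation and filtering and the
#' cross-set consensus: every DmMG of every replicate set seeds a random
#' walk with restart on the reference network, its top-`k` candidates are
#' assessed against the degree-conditioned null (`p < alpha`) and the
#' direct-interaction rule (`L = 1`), kept seed-candidate pairs are
#' pooled, and edges recurring in at least `min_recurrence` sets form
#' the consensus network whose nodes are the predicted mDrGenes.
#'
#' @param genesets Per-replicate-set gene calls: a tibble with `rs_id`,
#'   `gene`, `n_sites`, `best_fdr`, `best_log2fc`, `label` (rows from
#'   [sites_to_genes()] bound together).
#' @param net The preprocessed reference `ppi_network`.
#' @param model A `null_pvalue_model` fitted on `net` (provenance is
#'   checked via the network hash).
#' @param k Top-k candidates per seed (default 10).
#' @param alpha Empirical p-value threshold (default 0.05).
#' @param min_recurrence Consensus recurrence rule; default: number of
#'   replicate sets.
#' @param weighted Also compute the weighted consensus score per edge.
#' @param restart,tol,max_iter Random-walk parameters.
#' @param quiet Suppress progress messages.
#' @return An `mdrnet_result`: list with `consensus`
#'   (a `consensus_network`), `assessments`, `pool`, `genesets`,
#'   `study_summary`, `mdr_summary`, and the parameters used.
#' @export
run_study <- function(genesets, net, model, k = 10L, alpha = 0.05,
                      min_recurrence = NULL, weighted = FALSE,
                      restart = 0.5, tol = 1e-6, max_iter = 10000L,
                      quiet = FALSE) {
  g <- as_ppi_network(net)
  stopifnot(inherits(model, "null_pvalue_model"))
  if (!is.null(model$network_hash) && !is.na(model$network_hash) &&
      model$network_hash != network_hash(g)) {
    abort("provenance error: null model was built on a different network")
  }
  rs_ids <- sort(unique(genesets$rs_id))
  if (length(rs_ids) == 0) abort("no replicate sets in `genesets`")
  nodes <- igraph::V(g)$name
  dmmg_union <- unique(genesets$gene)

  M <- transition_matrix(g)
  assessments <- purrr::map_dfr(rs_ids, function(rs) {
    calls <- filter(genesets, .data$rs_id == rs)
    seeds <- intersect(calls$gene, nodes)
    skipped <- setdiff(calls$gene, nodes)
    if (!quiet && length(skipped) > 0) {
      inform(sprintf("%s: %d DmMG(s) absent from the network skipped",
                     rs, length(skipped)))
    }
    purrr::map_dfr(seeds, function(sd) {
      p <- random_walk_restart(M, sd, restart = restart, tol = tol,
                               max_iter = max_iter)
      cand <- top_candidates(p, k = k)
      assess_candidates(cand, g, sd, model, alpha = alpha, rs_id = rs)
    })
  })
  if (nrow(assessments) == 0) {
    abort("no replicate set has any DmMG present in the network")
  }

  pool <- pool_edges(assessments, dmmg_union)
  if (weighted) {
    pool <- weighted_consensus_score(pool, genesets)
  }
  consensus <- build_consensus(pool, genesets, n_rs = length(rs_ids),
                               min_recurrence = min_recurrence)
  structure(
    list(
      consensus = consensus,
      assessments = assessments,
      pool = pool,
      genesets = genesets,
      study_summary = summarize_study(genesets),
      mdr_summary = summarize_study(genesets, genes = mdr_genes(consensus)),
      params = list(k = as.integer(k), alpha = alpha,
                    min_recurrence = consensus$min_recurrence,
                    restart = restart, tol = tol,
                    weighted = weighted, n_rs = length(rs_ids))
    ),
    class = "mdrnet_result"
  )
}

#' @method tidy mdrnet_result
#' @export
tidy.mdrnet_result <- function(x, ...) x$consensus$edges

#' @method glance mdrnet_result
#' @export
glance.mdrnet_result <- function(x, ...) {
  dplyr::bind_cols(
    glance(x$consensus),
    tibble(n_assessed = nrow(x$assessments),
           n_kept = sum(x$assessments$kept),
           alpha = x$params$alpha, k = x$params$k)
  )
}

#' @export
print.mdrnet_result <- function(x, ...) {
  cat("mdrnet pipeline result\n")
  print(x$consensus)
  cat(sprintf("  %d / %d assessed candidates kept (alpha = %g, k = %d)\n",
              sum(x$assessments$kept), nrow(x$assessments),
              x$params$alpha, x$params$k))
  invisible(x)
}

#' Read and validate a pipeline run configuration
#'
#' A flat YAML file mirroring the pipeline parameters: `network`
#' (path), `network_format`, `sites` (named map rs_id -> site-table
#' path), `model` (path to a serialized null model, optional),
#' `fdr_cutoff`, `k`, `alpha`, `restart`, `tol`, `min_recurrence`,
#' `weighted`, `n_networks`, `switches_per_edge`, `rng_seed`, `outdir`.
#'
#' @param path YAML file path.
#' @return A named list of validated options.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file '%s' not found", path))
  cfg <- yaml::read_yaml(path)
  defaults <- list(network_format = "tsv2col", fdr_cutoff = 0.05, k = 10L,
                   alpha = 0.05, restart = 0.5, tol = 1e-6,
                   min_recurrence = NULL, weighted = FALSE,
                   n_networks = 100L, switches_per_edge = 10L,
                   rng_seed = 1L, outdir = ".")
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  if (is.null(cfg[["network"]])) abort("config is missing `network`")
  if (!file.exists(cfg[["network"]])) {
    abort(sprintf("config error: network file '%s' not found",
                  cfg[["network"]]))
  }
  if (!is.null(cfg$sites)) {
    missing_files <- unlist(cfg$sites)[!file.exists(unlist(cfg$sites))]
    if (length(missing_files) > 0) {
      abort(sprintf("config error: site table(s) not found: %s",
                    paste(missing_files, collapse = ", ")))
    }
  }
  if (!is.null(cfg$model) && !file.exists(cfg$model)) {
    abort(sprintf("config error: model file '%s' not found", cfg$model))
  }
  cfg
}

#' Run the full pipeline from a configuration
#'
#' Convenience driver used by the command-line interface: loads and
#' preprocesses the network, loads or builds the null model, reads the
#' per-replicate-set site tables, aggregates them to gene calls, runs
#' [run_study()] and writes all outputs under `cfg$outdir`.
#'
#' @param cfg A list from [read_run_config()].
#' @param quiet Suppress progress messages.
#' @return The `mdrnet_result`, invisibly.
#' @export
run_from_config <- function(cfg, quiet = FALSE) {
  net <- preprocess_network(
    ppi_network(read_ppi_edges(cfg[["network"]],
                               format = cfg[["network_format"]])),
    quiet = quiet)
  model <- if (!is.null(cfg$model)) {
    read_null_model(cfg$model)
  } else {
    fit_null_model(null_occurrence_table(
      net, n_networks = cfg$n_networks, k = cfg$k,
      switches_per_edge = cfg$switches_per_edge,
      restart = cfg$restart, tol = cfg$tol, seed = cfg$rng_seed))
  }
  if (is.null(cfg$sites) || length(cfg$sites) == 0) {
    abort("config is missing `sites` (rs_id -> site table path map)")
  }
  genesets <- purrr::imap_dfr(cfg$sites, function(p, rs) {
    sites_to_genes(read_dmm_sites(p), rs, fdr_cutoff = cfg$fdr_cutoff)
  })
  res <- run_study(genesets, net, model, k = cfg$k, alpha = cfg$alpha,
                   min_recurrence = cfg$min_recurrence,
                   weighted = isTRUE(cfg$weighted),
                   restart = cfg$restart, tol = cfg$tol, quiet = quiet)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  write_consensus(res$consensus, file.path(cfg$outdir, "consensus"), "tsv")
  write_consensus(res$consensus, file.path(cfg$outdir, "consensus.sif"), "sif")
  write_assessments(res$assessments,
                    file.path(cfg$outdir, "assessments.tsv"))
  readr::write_tsv(res$genesets, file.path(cfg$outdir, "genesets.tsv"))
  readr::write_tsv(res$study_summary,
                   file.path(cfg$outdir, "study_summary.tsv"))
  readr::write_tsv(res$mdr_summary,
                   file.path(cfg$outdir, "mdrgene_summary.tsv"))
  invisible(res)
}
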