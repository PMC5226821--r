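# Hand-built assessment rows for pooling tests.
assessment_row <- function(rs, seed, cand, kept = TRUE, p = 0.01, L = 1,
                           rank = 1, prob = 0.1) {
  tibble::tibble(rs_id = rs, seed = seed, candidate = cand, rank = rank,
                 probability = prob, p = p, L = L, kept = kept)
}

test_that("pooling is undirected, per-set deduplicated, and DmMG-closed", {
  a <- dplyr::bind_rows(
    assessment_row("RS1", "g1", "g2"),          # g2 DmMG only in RS2
    assessment_row("RS1", "g2", "g1"),          # same pair, other direction
    assessment_row("RS2", "g1", "g2"),
    assessment_row("RS1", "g1", "g9"),          # g9 never a DmMG
    assessment_row("RS1", "g3", "g1", kept = FALSE) # dropped by the filter
  )
  pool <- pool_edges(a, dmmg_union = c("g1", "g2", "g3"))
  expect_equal(nrow(pool), 1)
  expect_equal(pool$from, "g1")
  expect_equal(pool$to, "g2")
  expect_equal(pool$recurrence, 2L) # RS1 counted once despite two rows
  expect_equal(pool$rs_ids, "RS1,RS2")
})

test_that("consensus keeps edges recurring in every replicate set by default", {
  a <- dplyr::bind_rows(
    assessment_row("RS1", "g1", "g2"),
    assessment_row("RS2", "g1", "g2"),
    assessment_row("RS1", "g1", "g3") # only one of two sets
  )
  gs <- tibble::tibble(
    rs_id = c("RS1", "RS2", "RS1"),
    gene = c("g1", "g2", "g3"),
    n_sites = 1L, best_fdr = c(1e-6, 1e-4, 1e-3),
    best_log2fc = c(1, 2, -1),
    label = c("hyper", "hyper", "hypo"))
  pool <- pool_edges(a, unique(gs$gene))
  cn <- build_consensus(pool, gs, n_rs = 2)
  expect_equal(nrow(cn$edges), 1)
  expect_equal(cn$edges$from, "g1")
  expect_setequal(mdr_genes(cn), c("g1", "g2"))
  expect_false("g3" %in% mdr_genes(cn)) # incident to no retained edge

  # permissive limit: min_recurrence = 1 equals the pooled network
  cn1 <- build_consensus(pool, gs, n_rs = 2, min_recurrence = 1)
  expect_equal(cn1$edges, pool)

  # monotonicity: lowering the threshold never removes an edge
  for (thr in 2:1) {
    lo <- build_consensus(pool, gs, n_rs = 2, min_recurrence = thr)$edges
    hi <- suppressWarnings(
      build_consensus(pool, gs, n_rs = 2, min_recurrence = thr + 1)$edges)
    expect_true(all(paste(hi$from, hi$to) %in% paste(lo$from, lo$to)))
  }
})

test_that("node labels use majority vote with best-FDR tie-breaking", {
  a <- dplyr::bind_rows(
    assessment_row("RS1", "g1", "g2"),
    assessment_row("RS2", "g1", "g2"),
    assessment_row("RS3", "g1", "g2"))
  gs <- tibble::tibble(
    rs_id = c("RS1", "RS2", "RS3", "RS1", "RS2"),
    gene = c("g1", "g1", "g1", "g2", "g2"),
    n_sites = 1L,
    best_fdr = c(1e-3, 1e-4, 1e-5, 1e-8, 1e-2),
    best_log2fc = c(1, 1, -1, -2, 3),
    label = c("hyper", "hyper", "hypo", "hypo", "hyper"))
  cn <- build_consensus(pool_edges(a, unique(gs$gene)), gs, n_rs = 3,
                        min_recurrence = 3)
  nodes <- cn$nodes
  expect_equal(nodes$label[nodes$gene == "g1"], "hyper") # 2-1 majority
  # g2 ties 1-1: global best FDR (1e-8) is the hypo call
  expect_equal(nodes$label[nodes$gene == "g2"], "hypo")
  expect_equal(nodes$n_rs_dmmg[nodes$gene == "g1"], 3L)
})

test_that("weighted consensus scores follow the half-sum-of-logs formula", {
  a <- dplyr::bind_rows(
    assessment_row("RS1", "g1", "g2"),
    assessment_row("RS2", "g1", "g2"))
  gs <- tibble::tibble(
    rs_id = c("RS1", "RS1", "RS2", "RS2"),
    gene = c("g1", "g2", "g1", "g2"),
    n_sites = 1L,
    best_fdr = c(0.01, 0.0001, 0.1, 0.01),
    best_log2fc = 1, label = "hyper")
  pool <- pool_edges(a, unique(gs$gene))
  scored <- weighted_consensus_score(pool, gs)
  # RS1: w = (2 + 4)/2 = 3; RS2: w = (1 + 2)/2 = 1.5; s = 4.5
  expect_equal(scored$score, 4.5)

  # null-signal case: FDR = 1 on both endpoints gives weight 0
  gs1 <- dplyr::mutate(gs, best_fdr = 1)
  expect_equal(weighted_consensus_score(pool, gs1)$score, 0)

  # an endpoint missing in one set is gap-filled with its best overall FDR
  gs_gap <- gs[-3, ] # g1 not called in RS2; best overall = 0.01
  expect_message(sc <- weighted_consensus_score(pool, gs_gap), "gap-filled")
  expect_equal(sc$score, 3 + (2 + 2) / 2)

  # FDR of zero is floored, not -Inf
  gs0 <- dplyr::mutate(gs, best_fdr = c(0, 0.0001, 0.1, 0.01))
  expect_warning(sc0 <- weighted_consensus_score(pool, gs0), "floored")
  expect_true(all(is.finite(sc0$score)))
})

test_that("consensus networks round-trip through TSV, GraphML, and SIF", {
  study <- cached_study()
  model <- cached_model()
  res <- run_study(study$genesets, study$network, model, quiet = TRUE)
  cn <- res$consensus
  expect_gt(nrow(cn$edges), 0)

  prefix <- file.path(withr::local_tempdir(), "net")
  write_consensus(cn, prefix, "tsv")
  back <- read_consensus(prefix)
  expect_equal(back$edges, cn$edges)
  expect_equal(back$nodes, cn$nodes)

  gml <- paste0(prefix, ".graphml")
  write_consensus(cn, gml, "graphml")
  reread <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(reread), nrow(cn$nodes))
  expect_equal(igraph::ecount(reread), nrow(cn$edges))

  sif <- paste0(prefix, ".sif")
  write_consensus(cn, sif, "sif")
  expect_equal(length(readLines(sif)), nrow(cn$edges))

  # empty network is writable and warns on construction
  expect_warning(
    empty <- build_consensus(cn$edges[0, ], res$genesets, n_rs = 4),
    "empty consensus")
  write_consensus(empty, paste0(prefix, "_empty"), "tsv")
  expect_equal(nrow(read_consensus(paste0(prefix, "_empty"))$edges), 0)
})

test_that("tidiers expose edges and headline counts", {
  study <- cached_study()
  res <- run_study(study$genesets, study$network, cached_model(),
                   quiet = TRUE)
  expect_equal(tidy(res), res$consensus$edges)
  g <- glance(res)
  expect_equal(g$n_mdr_genes, nrow(res$consensus$nodes))
  expect_equal(g$n_kept, sum(res$assessments$kept))
})
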