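test_that("randomization preserves the exact per-node degree map and simplicity", {
  net <- cached_study()$network
  deg <- igraph::degree(net)
  for (i in 1:5) {
    r <- randomize_network(net, seed = i)
    rdeg <- igraph::degree(r)
    expect_equal(rdeg[names(deg)], deg)
    expect_false(igraph::any_loop(r))
    expect_false(igraph::any_multiple(r))
  }
  # reproducible per seed
  expect_identical(network_hash(randomize_network(net, seed = 42)),
                   network_hash(randomize_network(net, seed = 42)))
})

test_that("randomizing a near-degenerate network errors cleanly", {
  one_edge <- suppressMessages(preprocess_network(
    ppi_network(data.frame(from = "A", to = "B")), quiet = TRUE))
  expect_error(randomize_network(one_edge), "at least 2 edges")
})

test_that("occurrence table satisfies the frequency and p-value formulas", {
  net <- cached_study()$network
  tab <- null_occurrence_table(net, n_networks = 3, seed = 5)
  # arithmetic contract on every row: freq = #random / #PPI, p = freq / n
  expect_equal(tab$freq, tab$n_random / tab$n_ppi)
  expect_equal(tab$p, tab$freq / 3)
  # the worked numbers: 500 occurrences, 100 PPI genes, 100 networks
  expect_equal(500 / 100, 5.0)
  expect_equal((500 / 100) / 100, 0.05)
  # grid is the full cartesian product of degree classes
  classes <- degree_classes(net)
  expect_equal(nrow(tab), length(classes)^2)
  # n_ppi is the degree census of the reference network
  census <- table(igraph::degree(net))
  expect_equal(
    unique(tab[tab$candidate_degree == classes[1], ]$n_ppi)[[1]],
    as.integer(census[[as.character(classes[1])]]))
  # cardinality bound: each seed class contributes at most k per network
  per_class <- tapply(tab$n_random, tab$seed_degree, sum)
  expect_true(all(per_class <= 3 * 10))
  # deterministic given the seed
  tab2 <- null_occurrence_table(net, n_networks = 3, seed = 5)
  expect_equal(tab$n_random, tab2$n_random)
})

test_that("fitted p-value surface is monotone, bounded, and respects boundaries", {
  model <- cached_model()
  classes <- model$classes
  grid <- seq(1, max(classes) * 2, by = 1)
  for (sd in classes) {
    vals <- empirical_pvalue(model, sd, grid)
    expect_true(all(vals >= 0 & vals <= 1))
    expect_true(all(diff(vals) >= -1e-12))
  }
  # queries beyond the largest observed degree return the boundary value
  top <- max(classes)
  expect_equal(empirical_pvalue(model, classes[1], top * 10),
               empirical_pvalue(model, classes[1], top))
})

test_that("constant raw surface fits to the same constant", {
  tab <- tidyr::crossing(seed_degree = c(1L, 2L, 5L),
                         candidate_degree = c(1L, 2L, 3L, 5L, 8L)) |>
    dplyr::mutate(n_random = 2L, n_ppi = 10L, freq = 0.2, p = 0.02)
  attr(tab, "n_networks") <- 10L
  attr(tab, "k") <- 10L
  model <- suppressMessages(fit_null_model(tab))
  expect_equal(empirical_pvalue(model, 2L, c(1, 4, 100)), rep(0.02, 3),
               tolerance = 1e-8)
})

test_that("increasing raw p-values keep their order after fitting", {
  tab <- tibble::tibble(
    seed_degree = 3L,
    candidate_degree = c(1L, 10L, 100L),
    n_random = c(1L, 20L, 90L), n_ppi = 100L,
    freq = c(0.01, 0.20, 0.90) * 100 / 100,
    p = c(0.01, 0.20, 0.90))
  model <- suppressMessages(fit_null_model(tab))
  f <- empirical_pvalue(model, 3L, c(1, 10, 100))
  expect_true(f[1] <= f[2] && f[2] <= f[3])
})

test_that("sparse classes fall back to step interpolation with a message", {
  tab <- tibble::tibble(
    seed_degree = 2L, candidate_degree = c(1L, 4L),
    n_random = c(0L, 3L), n_ppi = 10L,
    freq = c(0, 0.3), p = c(0, 0.03))
  expect_message(model <- fit_null_model(tab), "fallback")
  expect_equal(model$fallback_classes, 2L)
  expect_equal(empirical_pvalue(model, 2L, 4L), 0.03)
})

test_that("raw p-values above 1 are preserved in the table but clipped by the fit", {
  tab <- tibble::tibble(
    seed_degree = 1L, candidate_degree = c(1L, 2L),
    n_random = c(30L, 50L), n_ppi = c(2L, 3L),
    freq = c(15, 50 / 3), p = c(1.5, 5 / 3))
  expect_gt(max(tab$p), 1) # raw table keeps the overflow
  model <- suppressMessages(fit_null_model(tab))
  expect_true(all(model$fitted$p <= 1))
})

test_that("queries at unknown seed degrees use the nearest class with a warning", {
  model <- cached_model()
  absent <- max(model$classes) + 7L
  expect_warning(v <- empirical_pvalue(model, absent, 3L), "nearest class")
  expect_equal(v, empirical_pvalue(model, max(model$classes), 3L))
})

test_that("null-model serialization round-trips fitted values and provenance", {
  model <- cached_model()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_null_model(model, f)
  back <- read_null_model(f)
  expect_equal(back$fitted$p, model$fitted$p)
  expect_equal(back$fitted$seed_degree, model$fitted$seed_degree)
  expect_identical(back$network_hash, model$network_hash)
  expect_equal(back$n_networks, model$n_networks)
  expect_equal(back$k, model$k)
  expect_error(read_null_model(write_sites_tsv(example_sites(),
                                               withr::local_tempfile())),
               "not an mdrnet null model")
})
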