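test_that("edge-list reading deduplicates only at preprocessing", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "B\tC", "A\tB"), f)
  edges <- read_ppi_edges(f)
  expect_equal(nrow(edges), 3) # raw: duplicate row survives parsing
  net <- suppressMessages(preprocess_network(ppi_network(edges), quiet = TRUE))
  expect_equal(igraph::ecount(net), 2)
  expect_setequal(igraph::V(net)$name, c("A", "B", "C"))

  # self-loop survives the raw read, dies at preprocessing
  writeLines(c("A\tB", "C\tC"), f)
  raw <- ppi_network(read_ppi_edges(f))
  expect_equal(igraph::ecount(raw), 2)
  clean <- suppressMessages(preprocess_network(raw, quiet = TRUE))
  expect_setequal(igraph::V(clean)$name, c("A", "B"))

  expect_error(read_ppi_edges(file.path(tempdir(), "nope.tsv")), "no such file")
  writeLines("# only a comment", f)
  expect_error(read_ppi_edges(f), "no edges")
})

test_that("BioGRID-style tab export is parsed via its symbol columns", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    paste("#ID A", "ID B", "Official Symbol Interactor A",
          "Official Symbol Interactor B", sep = "\t"),
    "1\t2\tTP53\tMDM2",
    "3\t4\tBRCA1\tBARD1",
    "5\t6\tTP53\tBRCA1"), f)
  # strip the leading '#' readr would treat as data; BioGRID headers vary
  lines <- readLines(f)
  lines[1] <- sub("^#", "", lines[1])
  writeLines(lines, f)
  edges <- read_ppi_edges(f, format = "biogrid_tab")
  expect_equal(nrow(edges), 3)
  expect_setequal(unique(c(edges$from, edges$to)),
                  c("TP53", "MDM2", "BRCA1", "BARD1"))
  expect_error(read_ppi_edges(f, format = "biogrid_tab",
                              symbol_cols = c("Nope A", "Nope B")),
               "Nope A")
})

test_that("preprocessing removes loops then isolated nodes, idempotently", {
  raw <- ppi_network(data.frame(from = c("A", "C"), to = c("B", "C")))
  raw <- igraph::add_vertices(raw, 1, name = "D")
  class(raw) <- unique(c("ppi_network", class(raw)))
  clean <- suppressMessages(preprocess_network(raw, quiet = TRUE))
  # C loses its only (self) edge and becomes isolated; D was isolated
  expect_setequal(igraph::V(clean)$name, c("A", "B"))
  twice <- suppressMessages(preprocess_network(clean, quiet = TRUE))
  expect_equal(igraph::as_edgelist(twice), igraph::as_edgelist(clean))

  only_loop <- ppi_network(data.frame(from = "A", to = "A"))
  expect_error(suppressMessages(preprocess_network(only_loop, quiet = TRUE)),
               "empty network")
})

test_that("degree classes and handshake identity hold on canonical shapes", {
  expect_equal(degree_classes(path_net()), c(1L, 2L))
  star <- net_from("H-a H-b H-c H-d")
  expect_equal(degree_classes(star), c(1L, 4L))
  cyc <- net_from("a-b b-c c-d d-a")
  expect_equal(degree_classes(cyc), 2L)
  for (net in list(path_net(), star, cyc)) {
    expect_equal(sum(igraph::degree(net)), 2 * igraph::ecount(net))
  }
})

test_that("shortest-path queries return BFS distance or Inf across components", {
  net <- path_net()
  expect_equal(path_length(net, "A", "B"), 1)
  expect_equal(path_length(net, "A", "C"), 2)
  two <- net_from("A-B C-D")
  expect_equal(path_length(two, "A", "C"), Inf)
  expect_error(path_length(net, "A", "Z"), "not in network")
  # every edge of a preprocessed network is a distance-1 pair
  el <- igraph::as_edgelist(cached_study()$network)
  idx <- sample(nrow(el), 20)
  for (i in idx) {
    expect_equal(path_length(cached_study()$network, el[i, 1], el[i, 2]), 1)
  }
})

test_that("network hash is order-independent and edge-sensitive", {
  n1 <- ppi_network(data.frame(from = c("A", "B"), to = c("B", "C")))
  n2 <- ppi_network(data.frame(from = c("C", "B"), to = c("B", "A")))
  expect_identical(network_hash(n1), network_hash(n2))
  n3 <- ppi_network(data.frame(from = c("A", "B"), to = c("B", "D")))
  expect_false(network_hash(n1) == network_hash(n3))
})

test_that("edge-list and GraphML writers round-trip node and edge counts", {
  net <- cached_study()$network
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, tsv)
  back <- suppressMessages(preprocess_network(
    ppi_network(read_ppi_edges(tsv)), quiet = TRUE))
  expect_identical(network_hash(back), network_hash(net))

  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, gml)
  reread <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(reread), igraph::vcount(net))
  expect_equal(igraph::ecount(reread), igraph::ecount(net))

  expect_equal(nrow(tidy(net)), igraph::ecount(net))
  expect_equal(glance(net)$n_nodes, igraph::vcount(net))
})
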