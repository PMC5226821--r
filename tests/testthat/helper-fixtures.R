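# Shared fixtures, built in code at test time.

# A -- B -- C path network (preprocessed).
path_net <- function() {
  suppressMessages(preprocess_network(
    ppi_network(data.frame(from = c("A", "B"), to = c("B", "C"))),
    quiet = TRUE))
}

# Build a network from an edge string like "A-B B-C".
net_from <- function(edge_str) {
  pairs <- strsplit(strsplit(edge_str, " ")[[1]], "-")
  suppressMessages(preprocess_network(
    ppi_network(data.frame(from = vapply(pairs, `[`, "", 1),
                           to = vapply(pairs, `[`, "", 2))),
    quiet = TRUE))
}

# Direct linear-solve oracle for the random walk with restart:
# p* = restart * (I - (1 - restart) M)^{-1} p0. Independent of the
# iterative implementation.
rwr_oracle <- function(net, seeds, restart = 0.5) {
  M <- as.matrix(transition_matrix(net))
  nodes <- rownames(M)
  p0 <- numeric(length(nodes))
  names(p0) <- nodes
  p0[seeds] <- 1 / length(seeds)
  p <- restart * solve(diag(length(nodes)) - (1 - restart) * M, p0)
  tibble::tibble(node = nodes, probability = as.numeric(p))
}

# Small site table used by dmm tests.
example_sites <- function() {
  tibble::tibble(
    gene = c("GENE1", "GENE1", "GENE2", "GENE3"),
    chrom = "chr1",
    start = c(100L, 300L, 50L, 70L),
    end = c(150L, 360L, 90L, 120L),
    strand = "+",
    log2fc = c(2, -1, -0.5, 1.2),
    fdr = c(1e-8, 1e-3, 0.01, 0.2)
  )
}

write_sites_tsv <- function(sites, path) {
  out <- sites[, c("gene", "chrom", "start", "end", "strand", "log2fc", "fdr")]
  names(out) <- c("gene", "chr", "chromStart", "chromEnd", "strand",
                  "log2.fc", "fdr")
  readr::write_tsv(out, path)
  path
}

# A cached 100-node study + null model shared across test files (built
# once per test run; the seed is fixed so results are reproducible).
.fixture_cache <- new.env(parent = emptyenv())

cached_study <- function() {
  if (is.null(.fixture_cache$study)) {
    net <- generate_toy_ppi(100, seed = 7)
    .fixture_cache$study <- generate_planted_study(net, seed = 3)
  }
  .fixture_cache$study
}

cached_model <- function() {
  if (is.null(.fixture_cache$model)) {
    study <- cached_study()
    tab <- null_occurrence_table(study$network, n_networks = 5, seed = 11)
    .fixture_cache$model <- suppressMessages(fit_null_model(tab))
  }
  .fixture_cache$model
}
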