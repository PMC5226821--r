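#' Read a differential methylation site table
#'
#' Reads the tabular output of a MeRIP-seq differential methylation caller
#' (exomePeak-style): one row per differentially methylated m6A site with
#' its host gene, genomic interval (0-based half-open, BED convention),
#' strand, methylation log2 fold change (treated vs untreated) and FDR.
#'
#' @param path Tab-delimited file with a header row.
#' @param cols Named character vector mapping the canonical field names
#'   (`gene`, `chrom`, `start`, `end`, `strand`, `log2fc`, `fdr`) to the
#'   column names used in the file.
#' @return A tibble of sites with the canonical column names.
#' @export
read_dmm_sites <- function(path,
                           cols = c(gene = "gene", chrom = "chr",
                                    start = "chromStart", end = "chromEnd",
                                    strand = "strand", log2fc = "log2.fc",
                                    fdr = "fdr")) {
  if (!file.exists(path)) {
    abort(sprintf("cannot read site table '%s': no such file", path))
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("gene", "chrom", "start", "end", "strand", "log2fc", "fdr")
  stopifnot(all(required %in% names(cols)))
  missing_cols <- setdiff(unname(cols[required]), names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("format error: missing site-table column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  sites <- tibble(
    gene = raw[[cols[["gene"]]]],
    chrom = raw[[cols[["chrom"]]]],
    start = suppressWarnings(as.integer(raw[[cols[["start"]]]])),
    end = suppressWarnings(as.integer(raw[[cols[["end"]]]])),
    strand = raw[[cols[["strand"]]]],
    log2fc = suppressWarnings(as.numeric(raw[[cols[["log2fc"]]]])),
    fdr = suppressWarnings(as.numeric(raw[[cols[["fdr"]]]]))
  )
  bad <- which(is.na(sites$start) | is.na(sites$end) |
                 is.na(sites$log2fc) | is.na(sites$fdr))
  if (length(bad) > 0) {
    abort(sprintf("unparseable numeric value(s) in site table row(s): %s",
                  paste(bad, collapse = ", ")))
  }
  bad_fdr <- which(sites$fdr < 0 | sites$fdr > 1)
  if (length(bad_fdr) > 0) {
    abort(sprintf("validation error: fdr outside [0, 1] in row(s): %s",
                  paste(bad_fdr, collapse = ", ")))
  }
  bad_iv <- which(sites$start >= sites$end)
  if (length(bad_iv) > 0) {
    abort(sprintf("validation error: start >= end in row(s): %s",
                  paste(bad_iv, collapse = ", ")))
  }
  sites
}

#' Aggregate differential methylation sites to gene calls
#'
#' A gene is a differentially methylated gene (DmMG) in a replicate set if
#' its mRNA harbors at least one site passing the FDR cutoff. The gene's
#' hyper/hypo label is the direction of its most differential site:
#' smallest FDR, ties broken by larger |log2fc|, then genomic order.
#'
#' @param sites A site tibble as returned by [read_dmm_sites()].
#' @param rs_id Replicate-set label attached to every row of the result.
#' @param fdr_cutoff Site-level FDR threshold (default 0.05).
#' @return A tibble with one row per DmMG: `rs_id`, `gene`, `n_sites`,
#'   `best_fdr`, `best_log2fc`, `label` (`"hyper"` if the best site's
#'   log2fc > 0, else `"hypo"`).
#' @export
sites_to_genes <- function(sites, rs_id, fdr_cutoff = 0.05) {
  assert_scalar_prob(fdr_cutoff, "fdr_cutoff", lo = 0, hi = 1, lo_open = TRUE)
  keep <- filter(sites, .data$fdr <= fdr_cutoff)
  if (nrow(keep) == 0) {
    warn(sprintf("replicate set '%s': no sites pass fdr <= %g", rs_id, fdr_cutoff))
    return(tibble(rs_id = character(), gene = character(),
                  n_sites = integer(), best_fdr = double(),
                  best_log2fc = double(), label = character()))
  }
  keep |>
    arrange(.data$fdr, -abs(.data$log2fc), .data$chrom, .data$start) |>
    group_by(.data$gene) |>
    summarise(
      n_sites = n(),
      best_fdr = .data$fdr[1],
      best_log2fc = .data$log2fc[1],
      label = if (.data$log2fc[1] > 0) "hyper" else "hypo",
      .groups = "drop"
    ) |>
    mutate(rs_id = rs_id, .before = 1) |>
    arrange(.data$gene)
}

#' Summarize site and gene counts across replicate sets
#'
#' Produces the per-replicate-set study overview: total differential
#' sites, total called genes, average sites per gene, and hyper/hypo
#' gene counts. When `genes` is supplied (e.g. the final mDrGene set)
#' the summary is restricted to that subset.
#'
#' @param genesets A tibble of gene calls (rows from [sites_to_genes()],
#'   possibly several replicate sets bound together).
#' @param genes Optional character vector restricting the summary.
#' @return A tibble with one row per replicate set.
#' @export
summarize_study <- function(genesets, genes = NULL) {
  if (!is.null(genes)) {
    genesets <- filter(genesets, .data$gene %in% genes)
  }
  if (nrow(genesets) == 0) {
    return(tibble(rs_id = character(), n_sites = integer(),
                  n_genes = integer(), avg_sites_per_gene = double(),
                  n_hyper = integer(), n_hypo = integer()))
  }
  genesets |>
    group_by(.data$rs_id) |>
    summarise(
      n_sites = sum(.data$n_sites),
      n_genes = n(),
      avg_sites_per_gene = round(sum(.data$n_sites) / n(), 2),
      n_hyper = sum(.data$label == "hyper"),
      n_hypo = sum(.data$label == "hypo"),
      .groups = "drop"
    )
}

#' Write a per-replicate-set gene table
#' @param geneset Tibble from [sites_to_genes()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(geneset, path) {
  readr::write_tsv(geneset, path)
  invisible(path)
}
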