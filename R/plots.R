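#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_bar
#'   geom_col labs theme_minimal facet_wrap scale_y_continuous
#' @export
ggplot2::autoplot

#' Plot the fitted empirical p-value surface
#'
#' One monotone curve of p-value against candidate degree per seed degree
#' class (log-scaled degree axis). The characteristic shape: the chance
#' of being prioritized grows with candidate degree, faster for
#' high-degree seeds.
#'
#' @param object A `null_pvalue_model`.
#' @param classes Optional subset of seed degree classes to show.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot null_pvalue_model
#' @export
autoplot.null_pvalue_model <- function(object, classes = NULL, ...) {
  dat <- object$fitted
  if (!is.null(classes)) dat <- filter(dat, .data$seed_degree %in% classes)
  ggplot(dat, aes(x = .data$candidate_degree, y = .data$p,
                  group = .data$seed_degree,
                  colour = factor(.data$seed_degree))) +
    geom_line() +
    ggplot2::scale_x_log10() +
    labs(x = "candidate gene degree", y = "empirical p-value",
         colour = "seed degree") +
    theme_minimal()
}

#' Plot a consensus network
#'
#' Nodes are the predicted m6A-driven genes coloured by hyper/hypo
#' methylation label; edge width tracks the number of replicate sets the
#' interaction recurs in.
#'
#' @param object A `consensus_network`.
#' @param layout_seed Seed for the force-directed layout.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot consensus_network
#' @export
autoplot.consensus_network <- function(object, layout_seed = 1L, ...) {
  if (nrow(object$edges) == 0) {
    return(ggplot() + labs(title = "empty consensus network") + theme_minimal())
  }
  g <- igraph::graph_from_data_frame(object$edges, directed = FALSE,
                                     vertices = object$nodes)
  xy <- withr::with_seed(layout_seed, igraph::layout_with_fr(g))
  nodes <- mutate(object$nodes, x = xy[, 1], y = xy[, 2])
  edges <- object$edges |>
    left_join(select(nodes, "gene", x1 = "x", y1 = "y"),
              by = c(from = "gene")) |>
    left_join(select(nodes, "gene", x2 = "x", y2 = "y"),
              by = c(to = "gene"))
  ggplot() +
    ggplot2::geom_segment(
      data = edges,
      aes(x = .data$x1, y = .data$y1, xend = .data$x2, yend = .data$y2,
          linewidth = .data$recurrence), colour = "grey60", alpha = 0.6) +
    geom_point(data = nodes,
               aes(x = .data$x, y = .data$y, colour = .data$label), size = 3) +
    ggplot2::geom_text(data = nodes,
                       aes(x = .data$x, y = .data$y, label = .data$gene),
                       vjust = -1, size = 2.5) +
    ggplot2::scale_linewidth(range = c(0.2, 1.5)) +
    labs(colour = "methylation", linewidth = "recurrence") +
    ggplot2::theme_void()
}

#' Bar chart of hyper/hypo gene counts per replicate set
#'
#' @param summary A tibble from [summarize_study()].
#' @return A ggplot.
#' @export
plot_hyper_hypo <- function(summary) {
  dat <- summary |>
    select("rs_id", hyper = "n_hyper", hypo = "n_hypo") |>
    tidyr::pivot_longer(c("hyper", "hypo"), names_to = "label",
                        values_to = "n")
  ggplot(dat, aes(x = .data$rs_id, y = .data$n, fill = .data$label)) +
    geom_col(position = "dodge") +
    labs(x = NULL, y = "genes", fill = "methylation") +
    theme_minimal()
}
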