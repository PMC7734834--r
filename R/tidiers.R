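#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a selection curve
#'
#' @param x A [selection_curve()].
#' @param ... Unused.
#' @return The curve points as a tibble (`n_genes`, `average_bootstrap`,
#'   `log_lik`) with a logical `selected` column.
#' @export
tidy.selection_curve <- function(x, ...) {
  dplyr::mutate(x$points, selected = .data$n_genes == x$selected_n)
}

#' One-row summary of a selection curve
#'
#' @param x A [selection_curve()].
#' @param ... Unused.
#' @export
glance.selection_curve <- function(x, ...) {
  tibble::tibble(n_points = nrow(x$points),
                 selected_n = x$selected_n,
                 max_average_bootstrap = max(x$points$average_bootstrap),
                 min_average_bootstrap = min(x$points$average_bootstrap),
                 seed = x$seed)
}

#' Plot a selection curve
#'
#' Average bootstrap support against the number of concatenated genes, with
#' the selected gene count highlighted.
#'
#' @param object A [selection_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.selection_curve <- function(object, ...) {
  pts <- tidy(object)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$n_genes,
                                    y = .data$average_bootstrap)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$selected), size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black",
                                            `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::labs(x = "Number of concatenated genes",
                  y = "Average bootstrap support") +
    ggplot2::theme_minimal()
}

#' Tidy a bootstrap result
#'
#' @param x A [bootstrap_support()] result.
#' @param ... Unused.
#' @return One row per internal edge of the best tree with its support.
#' @export
tidy.bootstrap_result <- function(x, ...) {
  s <- internal_supports(x$best_tree)
  tibble::tibble(edge = seq_along(s), support = s)
}

#' One-row summary of a bootstrap result
#' @param x A [bootstrap_support()] result.
#' @param ... Unused.
#' @export
glance.bootstrap_result <- function(x, ...) {
  ab <- average_bootstrap(x)
  tibble::tibble(average_bootstrap = ab$average_bootstrap,
                 n_internal_edges = ab$n_internal_edges,
                 n_replicates = x$n_replicates,
                 log_lik = x$log_lik, seed = x$seed)
}

#' Tidy a recovery report
#' @param x A [recovery_report()].
#' @param ... Unused.
#' @return The long percent-recovery tibble.
#' @export
tidy.recovery_report <- function(x, ...) x$percent

#' Per-method summary of a recovery report
#' @param x A [recovery_report()].
#' @param ... Unused.
#' @export
glance.recovery_report <- function(x, ...) x$method_summary

#' Heatmap of percent gene recovery
#'
#' @param object A [recovery_report()].
#' @param method Optional single method to show; defaults to all, facetted.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.recovery_report <- function(object, method = NULL, ...) {
  pct <- object$percent
  if (!is.null(method)) pct <- dplyr::filter(pct, .data$method %in% !!method)
  ggplot2::ggplot(pct, ggplot2::aes(x = .data$locus, y = .data$taxon,
                                    fill = .data$percent)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~method) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100)) +
    ggplot2::labs(x = "Locus", y = "Taxon", fill = "% recovered") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @importFrom rlang .data
NULL
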