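# broom-style accessors and ggplot2 autoplot methods for the result types

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an ML fit into an edge table
#'
#' @param x an `ml_fit`
#' @param ... unused
#' @return tibble with `parent`, `child`, `child_label`, `length`
#' @export
tidy.ml_fit <- function(x, ...) {
  ntip <- length(x$tree$tip.label)
  tibble(
    parent = x$tree$edge[, 1],
    child = x$tree$edge[, 2],
    child_label = ifelse(x$tree$edge[, 2] <= ntip,
                         x$tree$tip.label[x$tree$edge[, 2]], NA_character_),
    length = x$tree$edge.length
  )
}

#' One-row summary of an ML fit
#'
#' @inheritParams tidy.ml_fit
#' @return tibble with `model`, `loglik`, `k`, `AIC`, `n_sites`,
#'   `n_patterns`
#' @export
glance.ml_fit <- function(x, ...) {
  k <- nrow(x$tree$edge) + (x$model$n_categories > 1) + (x$model$p_inv > 0)
  tibble(model = x$model$name, loglik = x$loglik, k = k,
         AIC = 2 * k - 2 * x$loglik, n_sites = x$n_sites,
         n_patterns = x$n_patterns)
}

#' Domain-architecture diagram
#'
#' @param object a `domain_map` (or row-bound maps of several records)
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.domain_map <- function(object, ...) {
  df <- as_tibble(object) |> filter(.data$klass != "GAP")
  ggplot2::ggplot(df, ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                   ymin = 0, ymax = 1,
                                   fill = .data$klass)) +
    ggplot2::geom_rect(colour = "grey30", linewidth = 0.2) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$record)) +
    ggplot2::scale_fill_brewer(palette = "Set3", name = "domain") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.ticks.y = ggplot2::element_blank()) +
    ggplot2::labs(x = "residue (0-based)", y = NULL)
}

#' Composition bar chart
#'
#' @param object a `composition_summary`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.composition_summary <- function(object, ...) {
  df <- object |>
    select("group", "table") |>
    tidyr::unnest("table") |>
    filter(.data$pct > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$residue, y = .data$pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$group)) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = "mean % of unique region")
}

#' Support-comparison heat map
#'
#' @param object a `support_comparison`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.support_comparison <- function(object, ...) {
  df <- as_tibble(object) |>
    tidyr::pivot_longer(-"split", names_to = "analysis",
                        values_to = "support")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$analysis, y = .data$split,
                                   fill = .data$support)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$support), "n/a",
                     formatC(.data$support, format = "fg", digits = 3))
    ), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "forestgreen",
                                 limits = c(0, 100), na.value = "grey90") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "support (%)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
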