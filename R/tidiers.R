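#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a centrality profile into per-window values
#'
#' @param x An `lsp_profile`.
#' @param ... Unused.
#' @return A long tibble: `window`, `residue_index`, `residue_label`,
#'   `dc`, `bc`, `construct`.
#' @export
tidy.lsp_profile <- function(x, ...) {
  dplyr::mutate(attr(x, "windows"), construct = attr(x, "construct"))
}

#' One-row summary of a centrality profile
#'
#' @param x An `lsp_profile`.
#' @param ... Unused.
#' @return A tibble with construct, sizes, mean DC and the residue of
#'   highest mean BC (the top "communicator").
#' @export
glance.lsp_profile <- function(x, ...) {
  top <- which.max(x$bc_mean)
  tibble::tibble(
    construct = attr(x, "construct"),
    n_residues = nrow(x), n_windows = x$n_windows[1],
    mean_dc = mean(x$dc_mean), max_bc = x$bc_mean[top],
    top_bc_residue = x$residue_label[top])
}

#' Tidy a residue network into an edge table
#'
#' @param x An `lsp_network`.
#' @param ... Unused.
#' @return A tibble `i`, `j`, `weight`, `distance`.
#' @export
tidy.lsp_network <- function(x, ...) {
  tibble::as_tibble(edge_distances(x))
}

#' One-row summary of a residue network
#'
#' @param x An `lsp_network`.
#' @param ... Unused.
#' @return A tibble with sizes, window id, aggregated pair count, mean and
#'   maximum edge weight.
#' @export
glance.lsp_network <- function(x, ...) {
  tibble::tibble(
    construct = attr(x, "construct"), window = attr(x, "window_id"),
    n_residues = nrow(attr(x, "roster")), n_edges = nrow(x),
    n_pairs_aggregated = attr(x, "n_pairs_aggregated"),
    mean_weight = if (nrow(x)) mean(x$weight) else NA_real_,
    max_weight = if (nrow(x)) max(x$weight) else NA_real_)
}

#' Scatter of degree versus betweenness centrality
#'
#' Reproduces the standard hub/communicator view: each point is a residue
#' at (mean DC, mean BC) with standard-error bars in both directions.
#'
#' @param object An `lsp_profile`.
#' @param label_top Label this many residues of highest BC. Default 5.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lsp_profile <- function(object, label_top = 5, ...) {
  df <- tibble::as_tibble(object)
  top <- df[order(-df$bc_mean), ][seq_len(min(label_top, nrow(df))), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dc_mean, y = .data$bc_mean)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$bc_mean - .data$bc_se,
                                        ymax = .data$bc_mean + .data$bc_se),
                           linewidth = 0.3, colour = "grey60", na.rm = TRUE) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$dc_mean - .data$dc_se,
                                         xmax = .data$dc_mean + .data$dc_se),
                            linewidth = 0.3, colour = "grey60", na.rm = TRUE) +
    ggplot2::geom_point(size = 1.8) +
    ggplot2::geom_text(data = top, ggplot2::aes(label = .data$residue_label),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(x = "Degree centrality (mean ± SE)",
                  y = "Betweenness centrality (mean ± SE)",
                  title = attr(object, "construct")) +
    ggplot2::theme_minimal()
}

#' Per-residue percent-difference profile
#'
#' @param object An `lsp_comparison`.
#' @param ... Unused.
#' @return A ggplot of percent difference versus residue position;
#'   undefined residues (reference mean 0) are omitted from the line but
#'   marked on the axis.
#' @export
autoplot.lsp_comparison <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df[!df$undefined, ],
                  ggplot2::aes(x = .data$residue_index, y = .data$pct_diff)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_rug(data = df[df$undefined, ], sides = "b",
                      ggplot2::aes(y = NULL), colour = "red") +
    ggplot2::labs(
      x = "Residue",
      y = sprintf("%% difference in %s vs %s", toupper(attr(object, "metric")),
                  attr(object, "reference_label")),
      title = attr(object, "mutant_label")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
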