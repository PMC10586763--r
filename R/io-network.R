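#' Convert a residue network to an igraph object
#'
#' Nodes carry `residue_label` and, when a profile/hub assignment is given,
#' `dc_mean`, `bc_mean` and `community`; edges carry `weight` (W) and
#' `distance` (D = −log W). Every roster residue becomes a node even if
#' isolated.
#'
#' @param net An `lsp_network`.
#' @param profile Optional `lsp_profile` with a matching roster.
#' @param hubs Optional [detect_hubs()] result with a matching roster.
#' @return An undirected `igraph` graph.
#' @export
as_igraph <- function(net, profile = NULL, hubs = NULL) {
  roster <- attr(net, "roster")
  vert <- data.frame(name = as.character(roster$residue_index),
                     residue_label = roster$residue_label)
  if (!is.null(profile)) {
    check_same_roster(roster, profile, "network and profile")
    vert$dc_mean <- profile$dc_mean
    vert$bc_mean <- profile$bc_mean
  }
  if (!is.null(hubs)) {
    check_same_roster(roster, hubs, "network and hub assignment")
    vert$community <- hubs$community
  }
  net <- edge_distances(net)
  edges <- data.frame(from = as.character(net$i), to = as.character(net$j),
                      weight = net$weight, distance = net$distance)
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vert)
}

#' Export a residue network for graph tools
#'
#' Writes GraphML (via igraph) or GEXF (Gephi's native format, where node
#' diameter is typically mapped to the `dc_mean` attribute to reproduce
#' hub maps).
#'
#' @inheritParams as_igraph
#' @param path Output file.
#' @param format `"graphml"` or `"gexf"`; default from the file extension.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, profile = NULL, hubs = NULL,
                          format = c("auto", "graphml", "gexf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gexf$", path, ignore.case = TRUE)) "gexf" else "graphml"
  }
  tryCatch({
    if (format == "graphml") {
      igraph::write_graph(as_igraph(net, profile, hubs), path, format = "graphml")
    } else {
      write_gexf(net, path, profile, hubs)
    }
  }, error = function(e) {
    stop(sprintf("failed to write network to '%s': %s", path,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

num_attr <- function(x) formatC(x, digits = 10, format = "g")

write_gexf <- function(net, path, profile = NULL, hubs = NULL) {
  roster <- attr(net, "roster")
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">')
  w('  <graph defaultedgetype="undirected" mode="static">')
  w('    <attributes class="node">')
  w('      <attribute id="label" title="residue_label" type="string"/>')
  if (!is.null(profile)) {
    w('      <attribute id="dc" title="dc_mean" type="double"/>')
    w('      <attribute id="bc" title="bc_mean" type="double"/>')
  }
  if (!is.null(hubs)) {
    w('      <attribute id="community" title="community" type="integer"/>')
  }
  w('    </attributes>')
  w('    <attributes class="edge">')
  w('      <attribute id="W" title="weight_W" type="double"/>')
  w('      <attribute id="D" title="distance_D" type="double"/>')
  w('    </attributes>')
  w('    <nodes>')
  for (r in seq_len(nrow(roster))) {
    idx <- roster$residue_index[r]
    w('      <node id="%d" label="%s">', idx, xml_escape(roster$residue_label[r]))
    w('        <attvalues>')
    w('          <attvalue for="label" value="%s"/>',
      xml_escape(roster$residue_label[r]))
    if (!is.null(profile)) {
      w('          <attvalue for="dc" value="%s"/>', num_attr(profile$dc_mean[r]))
      w('          <attvalue for="bc" value="%s"/>', num_attr(profile$bc_mean[r]))
    }
    if (!is.null(hubs)) {
      w('          <attvalue for="community" value="%d"/>', hubs$community[r])
    }
    w('        </attvalues>')
    w('      </node>')
  }
  w('    </nodes>')
  w('    <edges>')
  net <- edge_distances(net)
  for (k in seq_len(nrow(net))) {
    w('      <edge id="e%d" source="%d" target="%d" weight="%s">',
      k - 1L, net$i[k], net$j[k], num_attr(net$weight[k]))
    w('        <attvalues>')
    w('          <attvalue for="W" value="%s"/>', num_attr(net$weight[k]))
    w('          <attvalue for="D" value="%s"/>', num_attr(net$distance[k]))
    w('        </attvalues>')
    w('      </edge>')
  }
  w('    </edges>')
  w('  </graph>')
  w('</gexf>')
  invisible(path)
}

fmt6 <- function(x) {
  ifelse(is.na(x), NA_character_, formatC(x, digits = 6, format = "g"))
}

sanitize_label <- function(x) gsub("[^A-Za-z0-9_.-]+", "-", x)

#' Write centrality and comparison tables
#'
#' One TSV per construct (`centrality_<construct>.tsv`: residue, DC/BC
#' means and standard errors) and one per mutant comparison
#' (`comparison_<mutant>_vs_<reference>.tsv`, with `pct_diff_dc`).
#' Floats are written at 6 significant digits; undefined percent
#' differences are `NA` cells. Output is byte-deterministic.
#'
#' @param profiles A list of `lsp_profile` objects.
#' @param comparisons A list of `lsp_comparison` objects (may be empty).
#' @param out_dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_tables <- function(profiles, comparisons = list(), out_dir) {
  if (length(profiles) == 0) stop("no profiles to write", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) {
    stop(sprintf("output directory '%s' is not writable", out_dir), call. = FALSE)
  }
  files <- character()
  for (p in profiles) {
    f <- file.path(out_dir, sprintf("centrality_%s.tsv",
                                    sanitize_label(attr(p, "construct"))))
    tab <- tibble::tibble(
      residue_index = p$residue_index, residue_label = p$residue_label,
      dc_mean = fmt6(p$dc_mean), dc_se = fmt6(p$dc_se),
      bc_mean = fmt6(p$bc_mean), bc_se = fmt6(p$bc_se))
    readr::write_tsv(tab, f, na = "NA")
    files <- c(files, f)
  }
  for (cmp in comparisons) {
    f <- file.path(out_dir, sprintf("comparison_%s_vs_%s.tsv",
                                    sanitize_label(attr(cmp, "mutant_label")),
                                    sanitize_label(attr(cmp, "reference_label"))))
    tab <- tibble::tibble(
      residue_index = cmp$residue_index, residue_label = cmp$residue_label,
      reference_mean = fmt6(cmp$reference_mean),
      mutant_mean = fmt6(cmp$mutant_mean))
    tab[[paste0("pct_diff_", attr(cmp, "metric"))]] <- fmt6(cmp$pct_diff)
    readr::write_tsv(tab, f, na = "NA")
    files <- c(files, f)
  }
  invisible(files)
}

#' Consensus network across windows
#'
#' Averages window networks edge-wise: each edge's weight is the mean of
#' its per-window weights, counting windows where the edge is absent as 0.
#' Used for per-construct network map export.
#'
#' @param nets List of `lsp_network` with identical rosters.
#' @return An `lsp_network` (window id 0).
#' @export
consensus_network <- function(nets) {
  rosters <- purrr::map(nets, attr, "roster")
  for (r in rosters[-1]) check_same_roster(rosters[[1]], r, "windows")
  all_edges <- purrr::map_dfr(nets, ~ .x[, c("i", "j", "weight")]) |>
    dplyr::group_by(.data$i, .data$j) |>
    dplyr::summarise(weight = sum(.data$weight) / length(nets), .groups = "drop") |>
    dplyr::arrange(.data$i, .data$j)
  new_lsp_network(all_edges, rosters[[1]], window_id = 0L,
                  n_pairs_aggregated = sum(purrr::map_int(
                    nets, ~ as.integer(attr(.x, "n_pairs_aggregated")))),
                  construct = attr(nets[[1]], "construct"))
}
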