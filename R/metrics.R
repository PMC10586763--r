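#' Weighted degree centrality
#'
#' DC(v) is the sum of edge weights incident to v (node strength,
#' unnormalised). High DC marks residues whose local contacts are conserved
#' across the window's frame pairs — locally rigid structural context.
#'
#' @param net An `lsp_network`.
#' @return A tibble `residue_index`, `residue_label`, `dc` covering the
#'   whole roster (isolated residues get 0).
#' @export
degree_centrality <- function(net) {
  roster <- attr(net, "roster")
  dc <- stats::setNames(numeric(nrow(roster)), roster$residue_index)
  if (nrow(net) > 0) {
    s <- rowsum(c(net$weight, net$weight), c(net$i, net$j))
    dc[rownames(s)] <- dc[rownames(s)] + s[, 1]
  }
  tibble::tibble(residue_index = roster$residue_index,
                 residue_label = roster$residue_label,
                 dc = unname(dc))
}

#' Edge weights to path distances
#'
#' D(e) = −log(W(e)) (natural log). A link conserved in every frame pair
#' (W = 1) has zero length; links never conserved are absent, i.e. the
#' residues are disconnected through that edge.
#'
#' @param net An `lsp_network`.
#' @return The network with a `distance` column appended.
#' @export
edge_distances <- function(net) {
  if (nrow(net) > 0 && (any(net$weight <= 0) || any(net$weight > 1))) {
    stop("edge weights must lie in (0, 1]", call. = FALSE)
  }
  net$distance <- -log(net$weight)
  net
}

#' Weighted betweenness centrality
#'
#' Unnormalised shortest-path betweenness on the distances D = −log(W):
#' BC(v) sums, over all unordered residue pairs (s, t) with s ≠ v ≠ t, the
#' fraction of minimum-total-distance s–t paths passing through v. Pairs in
#' different components contribute nothing. High BC marks communicator
#' residues bridging stable communities.
#'
#' Zero-length edges (W = 1) are legal. When two routes tie in total
#' distance — certain inside clusters of fully conserved links — the path
#' count uses minimal-distance paths of minimal hop count (lexicographic
#' (distance, hops) Dijkstra). This convention is symmetric, deterministic
#' and equals plain shortest-path counting whenever distances are generic;
#' it avoids the combinatorial explosion of "wandering" zero-length paths
#' inside fully conserved cliques, where multiplicity conventions differ
#' between graph libraries anyway.
#'
#' @param net An `lsp_network`.
#' @return A tibble `residue_index`, `residue_label`, `bc`.
#' @export
betweenness_centrality <- function(net) {
  roster <- attr(net, "roster")
  net <- edge_distances(net)
  idx <- roster$residue_index
  n <- length(idx)
  ei <- match(net$i, idx); ej <- match(net$j, idx)
  adj <- vector("list", n)   # per node: list(nbr = int vec, w = dbl vec)
  for (k in seq_along(ei)) {
    adj[[ei[k]]]$nbr <- c(adj[[ei[k]]]$nbr, ej[k])
    adj[[ei[k]]]$w <- c(adj[[ei[k]]]$w, net$distance[k])
    adj[[ej[k]]]$nbr <- c(adj[[ej[k]]]$nbr, ei[k])
    adj[[ej[k]]]$w <- c(adj[[ej[k]]]$w, net$distance[k])
  }
  bc <- numeric(n)
  for (s in seq_len(n)) {
    res <- brandes_sssp(s, n, adj)
    delta <- numeric(n)
    for (w in rev(res$order)) {
      for (v in res$pred[[w]]) {
        delta[v] <- delta[v] + res$sigma[v] / res$sigma[w] * (1 + delta[w])
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  tibble::tibble(residue_index = idx, residue_label = roster$residue_label,
                 bc = bc / 2)  # each unordered pair counted from both ends
}

# Dijkstra with path counting (Brandes), lexicographic on (distance, hop
# count): a predecessor must be minimal in both, so the predecessor
# relation is a DAG even across zero-length edges (hops strictly
# increase). Tentative minima are scanned in index order, so the settle
# order is deterministic.
brandes_sssp <- function(s, n, adj) {
  dist <- rep(Inf, n); dist[s] <- 0
  hops <- rep(Inf, n); hops[s] <- 0
  sigma <- numeric(n); sigma[s] <- 1
  pred <- rep(list(integer()), n)
  done <- logical(n)
  order <- integer(0)
  repeat {
    u <- 0L; best <- Inf; besth <- Inf
    for (v in seq_len(n)) {
      if (!done[v] &&
          (dist[v] < best || (dist[v] == best && hops[v] < besth))) {
        best <- dist[v]; besth <- hops[v]; u <- v
      }
    }
    if (u == 0L) break
    done[u] <- TRUE
    order <- c(order, u)
    nb <- adj[[u]]
    if (!is.null(nb)) {
      for (k in seq_along(nb$nbr)) {
        v <- nb$nbr[k]
        if (done[v]) next
        nd <- dist[u] + nb$w[k]
        nh <- hops[u] + 1
        if (nd < dist[v] || (nd == dist[v] && nh < hops[v])) {
          dist[v] <- nd; hops[v] <- nh; sigma[v] <- sigma[u]; pred[[v]] <- u
        } else if (nd == dist[v] && nh == hops[v]) {
          sigma[v] <- sigma[v] + sigma[u]; pred[[v]] <- c(pred[[v]], u)
        }
      }
    }
  }
  list(dist = dist, sigma = sigma, pred = pred, order = order)
}

#' Degree and betweenness centrality of one network
#'
#' @param net An `lsp_network`.
#' @return A tibble `residue_index`, `residue_label`, `dc`, `bc`.
#' @export
network_centralities <- function(net) {
  dplyr::inner_join(degree_centrality(net), betweenness_centrality(net),
                    by = c("residue_index", "residue_label"))
}

#' Aggregate per-window centralities into a profile
#'
#' Per residue, the window values of DC and BC are averaged and their
#' standard errors computed as sample SD / sqrt(m) over the m windows (15
#' in the reference design). With a single window the SE is `NA`.
#'
#' @param per_window Either a list of `lsp_network` (centralities are
#'   computed here) or a long tibble with columns `window`,
#'   `residue_index`, `residue_label`, `dc`, `bc`.
#' @param construct Construct name; defaults to the networks' attribute.
#' @return An `lsp_profile`: a tibble `residue_index`, `residue_label`,
#'   `dc_mean`, `dc_se`, `bc_mean`, `bc_se`, `n_windows`, with the long
#'   per-window table as attribute `windows`.
#' @export
aggregate_windows <- function(per_window, construct = NULL) {
  if (is.data.frame(per_window)) {
    long <- tibble::as_tibble(per_window)
  } else {
    construct <- construct %||% attr(per_window[[1]], "construct")
    rosters <- purrr::map(per_window, attr, "roster")
    for (r in rosters[-1]) check_same_roster(rosters[[1]], r, "windows")
    long <- purrr::map_dfr(per_window, function(net) {
      dplyr::mutate(network_centralities(net),
                    window = attr(net, "window_id"), .before = 1)
    })
  }
  rosters_by_window <- dplyr::count(long, .data$window)
  if (length(unique(rosters_by_window$n)) != 1) {
    stop("windows carry different residue rosters", call. = FALSE)
  }
  m <- length(unique(long$window))
  prof <- long |>
    dplyr::group_by(.data$residue_index, .data$residue_label) |>
    dplyr::summarise(
      dc_mean = mean(.data$dc), dc_se = stats::sd(.data$dc) / sqrt(m),
      bc_mean = mean(.data$bc), bc_se = stats::sd(.data$bc) / sqrt(m),
      n_windows = m, .groups = "drop") |>
    dplyr::arrange(.data$residue_index)
  tibble::new_tibble(prof, windows = long,
                     construct = construct %||% "unnamed",
                     class = "lsp_profile")
}

#' @export
print.lsp_profile <- function(x, ...) {
  cat(sprintf("<lsp_profile> construct '%s': %d residues over %d windows\n",
              attr(x, "construct"), nrow(x), x$n_windows[1]))
  NextMethod()
}

#' Percent difference of a centrality versus a reference construct
#'
#' Per residue, 100 × (mutant mean − reference mean) / reference mean.
#' Residues whose reference mean is 0 are kept in the table with `pct_diff
#' = NA` and `undefined = TRUE`, never silently dropped.
#'
#' @param mutant,reference `lsp_profile` objects with identical rosters.
#' @param metric `"dc"` (default) or `"bc"`.
#' @return An `lsp_comparison` tibble: `residue_index`, `residue_label`,
#'   `reference_mean`, `mutant_mean`, `pct_diff`, `undefined`.
#' @export
percent_difference <- function(mutant, reference, metric = c("dc", "bc")) {
  metric <- match.arg(metric)
  check_same_roster(mutant, reference, "profiles")
  col <- paste0(metric, "_mean")
  ref <- reference[[col]]; mut <- mutant[[col]]
  out <- tibble::tibble(
    residue_index = reference$residue_index,
    residue_label = reference$residue_label,
    reference_mean = ref, mutant_mean = mut,
    pct_diff = ifelse(ref > 0, 100 * (mut - ref) / ref, NA_real_),
    undefined = !(ref > 0))
  tibble::new_tibble(out, metric = metric,
                     reference_label = attr(reference, "construct"),
                     mutant_label = attr(mutant, "construct"),
                     class = "lsp_comparison")
}

#' @export
print.lsp_comparison <- function(x, ...) {
  cat(sprintf("<lsp_comparison> %s: '%s' vs reference '%s'\n",
              toupper(attr(x, "metric")), attr(x, "mutant_label"),
              attr(x, "reference_label")))
  NextMethod()
}
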