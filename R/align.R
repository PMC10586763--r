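#' Do two link descriptors match?
#'
#' Two links are "similar" when all three distance differences and the
#' circular dihedral difference fall strictly below their tolerances.
#'
#' @param a,b Descriptor tables (columns `d_caca`, `d_ca1cb2`, `d_ca2cb1`,
#'   `theta`), compared row by row; rows recycle if one side has one row.
#' @param cutoffs An [lsp_cutoffs()] object.
#' @return A logical vector.
#' @export
descriptors_match <- function(a, b, cutoffs = lsp_cutoffs()) {
  abs(a$d_caca - b$d_caca) < cutoffs$tol_caca &
    abs(a$d_ca1cb2 - b$d_ca1cb2) < cutoffs$tol_cross &
    abs(a$d_ca2cb1 - b$d_ca2cb1) < cutoffs$tol_cross &
    circ_diff_deg(a$theta, b$theta) < cutoffs$tol_theta
}

check_same_roster <- function(r1, r2, what = "frames") {
  if (!identical(r1$residue_index, r2$residue_index)) {
    d <- which(!(r1$residue_index %in% r2$residue_index))
    lab <- if (length(d)) r1$residue_label[d[1]] else
      r2$residue_label[which(!(r2$residue_index %in% r1$residue_index))[1]]
    stop(sprintf("%s have discordant residue rosters (first mismatch: %s)",
                 what, lab), call. = FALSE)
  }
  invisible(TRUE)
}

#' LSP-align two frames of the same protein
#'
#' Candidate links are the intersection of the two frames' contact graphs;
#' a link is retained when its four-number descriptors from the two frames
#' match under the tolerances. No superposition is involved, so arbitrary
#' rigid motion of either frame leaves the result unchanged.
#'
#' @param f1,f2 One-frame residue tables with identical rosters.
#' @param cutoffs An [lsp_cutoffs()] object.
#' @return A tibble of retained links: columns `i`, `j` (`i < j`).
#' @export
align_pair <- function(f1, f2, cutoffs = lsp_cutoffs()) {
  check_same_roster(f1, f2)
  p1 <- contact_pairs(f1, cutoffs)
  p2 <- contact_pairs(f2, cutoffs)
  cand <- dplyr::inner_join(p1[, c("i", "j")], p2[, c("i", "j")],
                            by = c("i", "j"))
  if (nrow(cand) == 0) return(cand)
  d1 <- link_descriptors(f1, cand)
  d2 <- link_descriptors(f2, cand)
  cand[descriptors_match(d1, d2, cutoffs), ]
}

new_lsp_network <- function(edges, roster, window_id = 1L,
                            n_pairs_aggregated = NA_integer_,
                            construct = "unnamed") {
  tibble::new_tibble(
    edges,
    roster = roster, window_id = as.integer(window_id),
    n_pairs_aggregated = as.integer(n_pairs_aggregated),
    construct = construct,
    class = "lsp_network")
}

#' @export
print.lsp_network <- function(x, ...) {
  cat(sprintf(
    "<lsp_network> construct '%s', window %d: %d residues, %d edges (from %s frame pairs)\n",
    attr(x, "construct"), attr(x, "window_id"), nrow(attr(x, "roster")),
    nrow(x), attr(x, "n_pairs_aggregated")))
  NextMethod()
}

#' Residue network of one time window
#'
#' Performs all-to-all LSP alignment of the window's frames — C(n, 2)
#' frame pairs, e.g. 4950 for a 100-frame window — and averages the
#' resulting 0/1 adjacency matrices. The edge weight W(i, j) is the
#' fraction of frame pairs in which link (i, j) was retained, a retention
#' probability in (0, 1]; links never retained are absent.
#'
#' @param ens An `lsp_ensemble` (or plain residue table with a `frame`
#'   column).
#' @param frames Integer vector of frame numbers forming the window;
#'   default all frames.
#' @param cutoffs An [lsp_cutoffs()] object.
#' @param window_id Integer identifier stored on the result.
#' @return An `lsp_network`: a tibble of edges `i`, `j`, `weight` with the
#'   roster, window id, construct and number of aggregated frame pairs as
#'   attributes.
#' @export
window_network <- function(ens, frames = NULL, cutoffs = lsp_cutoffs(),
                           window_id = 1L) {
  if (is.null(frames)) frames <- sort(unique(ens$frame))
  if (length(frames) < 2) {
    stop("a window needs at least 2 frames for pairwise alignment", call. = FALSE)
  }
  sub <- ens[ens$frame %in% frames, ]
  arr <- ensemble_arrays(sub)
  nr <- nrow(arr$roster); nf <- length(arr$frames)
  pr <- pair_index(nr)
  P <- pr$n_pairs

  D1 <- D2 <- D3 <- TH <- matrix(0, P, nf)
  M <- matrix(FALSE, P, nf)
  for (f in seq_len(nf)) {
    ca <- t(arr$ca[, , f]); cb <- t(arr$cb[, , f])
    ca1 <- ca[pr$ii, , drop = FALSE]; ca2 <- ca[pr$jj, , drop = FALSE]
    cb1 <- cb[pr$ii, , drop = FALSE]; cb2 <- cb[pr$jj, , drop = FALSE]
    D1[, f] <- rownorm(ca2 - ca1)
    D2[, f] <- rownorm(cb2 - ca1)
    D3[, f] <- rownorm(cb1 - ca2)
    TH[, f] <- dihedral_deg(cb1, ca1, ca2, cb2)
    M[, f] <- D1[, f] < cutoffs$contact_cutoff
  }

  counts <- numeric(P)
  t1 <- cutoffs$tol_caca; t2 <- cutoffs$tol_cross; t4 <- cutoffs$tol_theta
  for (a in seq_len(nf - 1)) {
    d1a <- D1[, a]; d2a <- D2[, a]; d3a <- D3[, a]; tha <- TH[, a]; ma <- M[, a]
    for (b in (a + 1):nf) {
      dth <- abs(tha - TH[, b]) %% 360
      hit <- ma & M[, b] &
        abs(d1a - D1[, b]) < t1 &
        abs(d2a - D2[, b]) < t2 &
        abs(d3a - D3[, b]) < t2 &
        pmin(dth, 360 - dth) < t4
      counts <- counts + hit
    }
  }

  n_pairs <- nf * (nf - 1) / 2
  keep <- counts > 0
  edges <- tibble::tibble(
    i = arr$roster$residue_index[pr$ii[keep]],
    j = arr$roster$residue_index[pr$jj[keep]],
    weight = counts[keep] / n_pairs)
  new_lsp_network(edges, arr$roster, window_id = window_id,
                  n_pairs_aggregated = n_pairs,
                  construct = attr(ens, "construct") %||% "unnamed")
}

#' Split trajectories into consecutive, non-overlapping windows
#'
#' Windows never span trajectory boundaries; trailing frames that do not
#' fill a window are dropped with a warning. With the reference design —
#' 3 trajectories of 500 frames (50 ns at 0.1 ns), 100 frames (10 ns) per
#' window — this yields 15 windows.
#'
#' @param ensembles One `lsp_ensemble` or a list of them (one per
#'   trajectory of the same construct).
#' @param frames_per_window Frames per window, ≥ 2. Default 100.
#' @return A tibble with one row per window: `trajectory`, `window`
#'   (global 1-based id), and `frames` (list-column of frame numbers).
#' @export
split_windows <- function(ensembles, frames_per_window = 100) {
  if (inherits(ensembles, "lsp_ensemble") || !is.list(ensembles) ||
      is.data.frame(ensembles)) {
    ensembles <- list(ensembles)
  }
  if (frames_per_window < 2) {
    stop("frames_per_window must be >= 2", call. = FALSE)
  }
  out <- list(); wid <- 0L
  for (t in seq_along(ensembles)) {
    frames <- sort(unique(ensembles[[t]]$frame))
    nf <- length(frames)
    nw <- nf %/% frames_per_window
    if (nw < 1) {
      stop(sprintf("trajectory %d has %d frames, fewer than one window (%d)",
                   t, nf, frames_per_window), call. = FALSE)
    }
    drop <- nf - nw * frames_per_window
    if (drop > 0) {
      warning(sprintf("trajectory %d: dropping %d trailing frames that do not fill a window",
                      t, drop), call. = FALSE)
    }
    for (w in seq_len(nw)) {
      wid <- wid + 1L
      out[[wid]] <- tibble::tibble(
        trajectory = t, window = wid,
        frames = list(frames[((w - 1) * frames_per_window + 1):(w * frames_per_window)]))
    }
  }
  dplyr::bind_rows(out)
}

#' Networks of every window of one construct
#'
#' Convenience wrapper: [split_windows()] then [window_network()] per
#' window.
#'
#' @inheritParams split_windows
#' @inheritParams window_network
#' @return A list of `lsp_network`, one per window.
#' @export
ensemble_networks <- function(ensembles, frames_per_window = 100,
                              cutoffs = lsp_cutoffs()) {
  single <- inherits(ensembles, "lsp_ensemble") || is.data.frame(ensembles)
  lst <- if (single) list(ensembles) else ensembles
  win <- split_windows(lst, frames_per_window)
  purrr::pmap(win, function(trajectory, window, frames) {
    window_network(lst[[trajectory]], frames = frames, cutoffs = cutoffs,
                   window_id = window)
  })
}
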