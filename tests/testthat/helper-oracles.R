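# Independent oracles: deliberately naive implementations used only to
# check the package's optimised paths.

# all-pairs double loop, strict inequality
oracle_contact_pairs <- function(frame, cutoff = 12) {
  ca <- as.matrix(frame[, c("ca_x", "ca_y", "ca_z")])
  idx <- frame$residue_index
  out <- list()
  for (a in seq_len(nrow(ca) - 1)) {
    for (b in (a + 1):nrow(ca)) {
      if (sqrt(sum((ca[a, ] - ca[b, ])^2)) < cutoff) {
        out[[length(out) + 1]] <- c(idx[a], idx[b])
      }
    }
  }
  if (length(out) == 0) return(tibble::tibble(i = integer(), j = integer()))
  m <- do.call(rbind, out)
  tibble::tibble(i = m[, 1], j = m[, 2])
}

# per-pair recheck of an alignment, one residue pair at a time
oracle_align_pair <- function(f1, f2, cutoffs = lsp_cutoffs()) {
  p1 <- oracle_contact_pairs(f1, cutoffs$contact_cutoff)
  p2 <- oracle_contact_pairs(f2, cutoffs$contact_cutoff)
  cand <- merge(p1, p2)
  keep <- logical(nrow(cand))
  desc_of <- function(f, i, j) {
    r1 <- f[f$residue_index == i, ]; r2 <- f[f$residue_index == j, ]
    link_descriptor(c(r1$ca_x, r1$ca_y, r1$ca_z), c(r1$cb_x, r1$cb_y, r1$cb_z),
                    c(r2$ca_x, r2$ca_y, r2$ca_z), c(r2$cb_x, r2$cb_y, r2$cb_z))
  }
  for (k in seq_len(nrow(cand))) {
    d1 <- desc_of(f1, cand$i[k], cand$j[k])
    d2 <- desc_of(f2, cand$i[k], cand$j[k])
    dth <- abs(d1$theta - d2$theta) %% 360
    keep[k] <- abs(d1$d_caca - d2$d_caca) < cutoffs$tol_caca &&
      abs(d1$d_ca1cb2 - d2$d_ca1cb2) < cutoffs$tol_cross &&
      abs(d1$d_ca2cb1 - d2$d_ca2cb1) < cutoffs$tol_cross &&
      min(dth, 360 - dth) < cutoffs$tol_theta
  }
  res <- cand[keep, ]
  res[order(res$j, res$i), ]
}

# triple loop (frame pairs x residue pairs) window aggregation
oracle_window_weights <- function(ens, cutoffs = lsp_cutoffs()) {
  frames <- sort(unique(ens$frame))
  n <- length(frames)
  counts <- list()
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      al <- oracle_align_pair(get_frame(ens, frames[a]),
                              get_frame(ens, frames[b]), cutoffs)
      for (k in seq_len(nrow(al))) {
        key <- paste(al$i[k], al$j[k])
        counts[[key]] <- (counts[[key]] %||% 0) + 1
      }
    }
  }
  denom <- n * (n - 1) / 2
  if (length(counts) == 0) {
    return(tibble::tibble(i = integer(), j = integer(), weight = numeric()))
  }
  ij <- do.call(rbind, strsplit(names(counts), " "))
  out <- tibble::tibble(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
                        weight = unlist(counts) / denom)
  out[order(out$i, out$j), ]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exhaustive simple-path enumeration betweenness on distances D; among
# minimal-distance paths, only those of minimal hop count are counted
# (identical to plain minimal counting when distances are generic)
oracle_betweenness <- function(edges, n) {
  adj <- rep(list(integer()), n)
  wmat <- matrix(Inf, n, n)
  for (k in seq_len(nrow(edges))) {
    i <- edges$i[k]; j <- edges$j[k]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    wmat[i, j] <- wmat[j, i] <- edges$distance[k]
  }
  bc <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- list()
      walk <- function(v, visited, len) {
        if (v == t) {
          paths[[length(paths) + 1]] <<- list(len = len, via = visited)
          return(invisible())
        }
        for (u in adj[[v]]) {
          if (!(u %in% visited)) walk(u, c(visited, u), len + wmat[v, u])
        }
      }
      walk(s, s, 0)
      if (length(paths) == 0) next
      lens <- round(vapply(paths, `[[`, numeric(1), "len"), 9)
      minimal <- paths[lens == min(lens)]
      nhops <- vapply(minimal, function(p) length(p$via) - 1L, integer(1))
      minimal <- minimal[nhops == min(nhops)]
      sigma <- length(minimal)
      for (p in minimal) {
        inner <- setdiff(p$via, c(s, t))
        bc[inner] <- bc[inner] + 1 / sigma
      }
    }
  }
  bc
}

# ---- generators ----------------------------------------------------------

clique_edges <- function(members, w = 1) {
  pr <- t(utils::combn(members, 2))
  tibble::tibble(i = pr[, 1], j = pr[, 2], weight = w)
}

random_rotation_matrix <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# frame of n residues scattered in a box, unit-ish CA-CB bonds
random_frame <- function(n, box = 25, frame = 1L) {
  ca <- matrix(stats::runif(3 * n, 0, box), n, 3)
  dir <- matrix(stats::rnorm(3 * n), n, 3)
  dir <- dir / sqrt(rowSums(dir^2))
  tibble::tibble(frame = frame, residue_index = seq_len(n),
                 residue_label = paste0("A", seq_len(n)),
                 ca_x = ca[, 1], ca_y = ca[, 2], ca_z = ca[, 3],
                 cb_x = ca[, 1] + 1.53 * dir[, 1],
                 cb_y = ca[, 2] + 1.53 * dir[, 2],
                 cb_z = ca[, 3] + 1.53 * dir[, 3],
                 cb_virtual = FALSE)
}

# random connected-ish weighted network as lsp_network
random_network <- function(n, p = 0.45, w_one_frac = 0) {
  pairs <- t(utils::combn(n, 2))
  keep <- stats::runif(nrow(pairs)) < p
  pairs <- pairs[keep, , drop = FALSE]
  w <- stats::runif(nrow(pairs), 0.05, 0.999)
  if (w_one_frac > 0 && nrow(pairs) > 0) {
    ones <- stats::runif(nrow(pairs)) < w_one_frac
    w[ones] <- 1
  }
  roster <- tibble::tibble(residue_index = seq_len(n),
                           residue_label = paste0("A", seq_len(n)))
  lspprn:::new_lsp_network(
    tibble::tibble(i = pairs[, 1], j = pairs[, 2], weight = w),
    roster, window_id = 1L, n_pairs_aggregated = 1L)
}

make_lsp_network <- function(edges, n,
                             labels = paste0("A", seq_len(n))) {
  roster <- tibble::tibble(residue_index = seq_len(n), residue_label = labels)
  lspprn:::new_lsp_network(tibble::as_tibble(edges), roster,
                           window_id = 1L, n_pairs_aggregated = 1L)
}

rigidify <- function(frame, R = random_rotation_matrix(),
                     tr = stats::runif(3, -30, 30)) {
  for (p in list(c("ca_x", "ca_y", "ca_z"), c("cb_x", "cb_y", "cb_z"))) {
    m <- as.matrix(frame[, p])
    frame[, p] <- m %*% t(R) + matrix(tr, nrow(m), 3, byrow = TRUE)
  }
  frame
}
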