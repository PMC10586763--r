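#' Specification of a synthetic conformational ensemble
#'
#' Describes a stand-in for an MD trajectory of a small two-lobed domain:
#' a deterministic base geometry (two packed helical lobes joined by a
#' protruding surface loop), two internally rigid residue communities
#' emulating the Zn²⁺-organised clusters of a C1 domain, a flexible loop,
#' an optional coupling that makes the loop move with one lobe (the
#' "R42P-like" stiffening), and arbitrary per-frame global rigid-body
#' motion. The noise model is Gaussian coordinate jitter — the target is
#' the statistical behaviour of the LSP network pipeline, not force-field
#' realism.
#'
#' @param n_residues Number of residues (default 50, C1-domain-like).
#' @param rigid_blocks List of residue-index vectors, one per rigid lobe.
#'   Defaults to the two helical lobes of the base geometry.
#' @param flexible Residue indices of the flexible loop. Defaults to the
#'   loop of the base geometry.
#' @param sigma_rigid Per-residue jitter SD inside rigid blocks, Å.
#' @param sigma_flex Independent per-residue jitter SD on the loop, Å.
#' @param sigma_other Jitter SD for residues in neither set, Å.
#' @param block_rot_deg SD of each block's shared per-frame rotation, deg.
#' @param block_trans SD of each block's shared per-frame translation, Å.
#' @param coupling `NULL`, or `list(residues =, block =)` as produced by
#'   [apply_coupling()].
#' @param global_motion Apply a random per-frame global rotation +
#'   translation (LSP results must be invariant to it).
#' @param n_frames Frames to generate (100 ≙ one 10-ns window at 0.1 ns).
#' @param seed RNG seed; identical spec + seed gives a bit-identical
#'   ensemble.
#' @param construct Construct label carried into all downstream tables.
#' @return An `ensemble_spec` list.
#' @export
ensemble_spec <- function(n_residues = 50,
                          rigid_blocks = NULL,
                          flexible = NULL,
                          sigma_rigid = 0.15,
                          sigma_flex = 1.2,
                          sigma_other = 0.4,
                          block_rot_deg = 1.5,
                          block_trans = 0.3,
                          coupling = NULL,
                          global_motion = TRUE,
                          n_frames = 100,
                          seed = 1,
                          construct = "WT") {
  if (n_residues < 12) stop("n_residues must be >= 12", call. = FALSE)
  seg <- default_segments(n_residues)
  if (is.null(rigid_blocks)) rigid_blocks <- seg$blocks
  if (is.null(flexible)) flexible <- seg$flexible
  all_block <- unlist(rigid_blocks)
  if (anyDuplicated(all_block) || length(intersect(all_block, flexible))) {
    stop("rigid blocks and flexible set must be disjoint", call. = FALSE)
  }
  if (!(sigma_rigid < sigma_flex)) {
    stop("sigma_rigid must be < sigma_flex", call. = FALSE)
  }
  if (n_frames < 2) stop("n_frames must be >= 2", call. = FALSE)
  spec <- structure(list(
    n_residues = n_residues, rigid_blocks = rigid_blocks,
    flexible = sort(flexible), sigma_rigid = sigma_rigid,
    sigma_flex = sigma_flex, sigma_other = sigma_other,
    block_rot_deg = block_rot_deg, block_trans = block_trans,
    coupling = coupling, global_motion = global_motion,
    n_frames = n_frames, seed = seed, construct = construct),
    class = "ensemble_spec")
  if (!is.null(coupling)) check_coupling(spec, coupling$residues, coupling$block)
  spec
}

default_segments <- function(n) {
  n_a <- ceiling(0.4 * n)
  n_loop <- max(3, ceiling(0.2 * n))
  n_b <- n - n_a - n_loop
  list(blocks = list(seq_len(n_a), (n_a + n_loop + 1):n),
       flexible = (n_a + 1):(n_a + n_loop))
}

check_coupling <- function(spec, residues, block) {
  if (!is.numeric(block) || length(block) != 1 ||
      block < 1 || block > length(spec$rigid_blocks)) {
    stop("coupling block id out of range", call. = FALSE)
  }
  in_block <- residues %in% unlist(spec$rigid_blocks)
  if (any(in_block)) {
    stop(sprintf("residue %d is already in a rigid block and cannot be coupled",
                 residues[in_block][1]), call. = FALSE)
  }
  if (!all(residues %in% spec$flexible)) {
    stop("coupled residues must belong to the flexible set", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.ensemble_spec <- function(x, ...) {
  cat(sprintf(
    "<ensemble_spec> '%s': %d residues, %d frames, seed %d\n  blocks: %s | loop: %s%s\n",
    x$construct, x$n_residues, x$n_frames, x$seed,
    paste(vapply(x$rigid_blocks, function(b) sprintf("%d-%d", min(b), max(b)), ""),
          collapse = ", "),
    sprintf("%d-%d", min(x$flexible), max(x$flexible)),
    if (is.null(x$coupling)) "" else
      sprintf(" | coupled to block %d", x$coupling$block)))
  invisible(x)
}

#' Couple the flexible loop into a rigid block
#'
#' Returns a spec in which the given loop residues share the target
#' block's rigid-body motion and its small internal jitter — the
#' "R42P-like" stiffening in which the loop docks onto the core.
#' [remove_coupling()] is its exact inverse ("Q66N-rescue").
#'
#' @param spec An [ensemble_spec()].
#' @param residues Residues to couple; default the whole flexible set.
#' @param block Index of the target rigid block (default 2).
#' @param construct New construct label.
#' @return The modified spec.
#' @export
apply_coupling <- function(spec, residues = spec$flexible, block = 2,
                           construct = paste0(spec$construct, "+coupled")) {
  check_coupling(spec, residues, block)
  spec$coupling <- list(residues = sort(residues), block = block)
  spec$construct <- construct
  spec
}

#' @rdname apply_coupling
#' @export
remove_coupling <- function(spec, construct = spec$construct) {
  spec["coupling"] <- list(NULL)    # keep the slot, restoring spec equality
  spec$construct <- construct
  spec
}

# Deterministic base geometry: two antiparallel helical lobes ~10.5 A
# apart joined by a circular-arc loop that protrudes from the core.
base_geometry <- function(n_residues) {
  seg <- default_segments(n_residues)
  n_a <- length(seg$blocks[[1]]); n_loop <- length(seg$flexible)
  n_b <- length(seg$blocks[[2]])
  ca <- matrix(NA_real_, n_residues, 3)
  turn <- 100 * pi / 180; r_h <- 2.3; rise <- 1.5; sep <- 10.5
  for (k in seq_len(n_a)) {
    ca[k, ] <- c(r_h * cos(turn * k), r_h * sin(turn * k),
                 rise * (k - (n_a + 1) / 2))
  }
  for (k in seq_len(n_b)) {
    i <- n_a + n_loop + k
    ca[i, ] <- c(sep + r_h * cos(turn * k + pi), r_h * sin(turn * k + pi),
                 rise * ((n_b + 1) / 2 - k))
  }
  e0 <- ca[n_a, ]; e1 <- ca[n_a + n_loop + 1, ]
  chord <- sqrt(sum((e1 - e0)^2))
  target_len <- 3.8 * (n_loop + 1)
  mid <- (e0 + e1) / 2
  core <- c(sep / 2, 0, 0)
  u <- mid - core                       # outward direction, orthogonal to chord
  ch <- (e1 - e0) / chord
  u <- u - sum(u * ch) * ch
  if (sqrt(sum(u * u)) < 1e-6) u <- c(0, 0, -1) - sum(c(0, 0, -1) * ch) * ch
  u <- u / sqrt(sum(u * u))
  if (target_len <= 1.02 * chord) {
    # loop barely longer than the gap: straight interpolation
    for (k in seq_len(n_loop)) {
      ca[n_a + k, ] <- e0 + (k / (n_loop + 1)) * (e1 - e0)
    }
  } else {
    semi <- pi * chord / 2              # arc length of the half-circle limit
    major <- target_len > semi
    arc_len <- function(R) {
      half_ang <- asin(pmin(1, chord / (2 * R)))
      if (major) R * (2 * pi - 2 * half_ang) else 2 * R * half_ang
    }
    R <- stats::uniroot(function(R) arc_len(R) - target_len,
                        c(chord / 2 * (1 + 1e-9), 1e4))$root
    h <- sqrt(max(R^2 - (chord / 2)^2, 0))
    # major arc: centre offset outward, walk the long way (protruding loop);
    # minor arc: centre offset inward, walk the short way (shallow bulge)
    C <- if (major) mid + h * u else mid - h * u
    e1v <- (e0 - C) / sqrt(sum((e0 - C)^2))
    w <- (e1 - C) - sum((e1 - C) * e1v) * e1v
    e2v <- w / sqrt(sum(w * w))
    phi_c <- acos(pmin(1, pmax(-1, sum((e0 - C) * (e1 - C)) /
                                 (sqrt(sum((e0 - C)^2)) * sqrt(sum((e1 - C)^2))))))
    for (k in seq_len(n_loop)) {
      ang <- if (major) -(k / (n_loop + 1)) * (2 * pi - phi_c) else
        (k / (n_loop + 1)) * phi_c
      ca[n_a + k, ] <- C + R * (cos(ang) * e1v + sin(ang) * e2v)
    }
  }
  # synthetic C-beta: outward curvature normal, orthogonal to the local tangent
  cb <- matrix(NA_real_, n_residues, 3)
  for (i in seq_len(n_residues)) {
    lo <- max(1, i - 1); hi <- min(n_residues, i + 1)
    tang <- ca[hi, ] - ca[lo, ]
    ref <- ca[i, ] - colMeans(ca[lo:hi, , drop = FALSE])
    d <- ref - sum(ref * tang) / sum(tang * tang) * tang
    if (sqrt(sum(d * d)) < 1e-6) {
      d <- c(-tang[2], tang[1], 0)
      if (sqrt(sum(d * d)) < 1e-6) d <- c(0, -tang[3], tang[2])
    }
    cb[i, ] <- ca[i, ] + 1.521 * d / sqrt(sum(d * d))
  }
  list(ca = ca, cb = cb)
}

random_rotation <- function(angle_sd_deg = NULL) {
  if (is.null(angle_sd_deg)) {          # uniform over SO(3) via quaternion
    q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    return(matrix(c(
      1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
      2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
      2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
      3, 3, byrow = TRUE))
  }
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::rnorm(1, 0, angle_sd_deg) * pi / 180
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Generate a synthetic structural ensemble
#'
#' Each frame is built from the base geometry by (1) a small shared rigid
#' perturbation per block (coupled loop residues move with their target
#' block), (2) independent Gaussian translation of each residue's (Cα, Cβ)
#' pair — σ depends on whether the residue is rigid, flexible or coupled —
#' and (3) an optional global rigid motion. Jitter translates Cα and Cβ
#' together, so the Cα–Cβ bond geometry is preserved while relative
#' orientations between residues genuinely change.
#'
#' @param spec An [ensemble_spec()].
#' @return An `lsp_ensemble`.
#' @export
generate_ensemble <- function(spec) {
  base <- base_geometry(spec$n_residues)
  n <- spec$n_residues
  sigma <- rep(spec$sigma_other, n)
  for (b in spec$rigid_blocks) sigma[b] <- spec$sigma_rigid
  sigma[spec$flexible] <- spec$sigma_flex
  block_of <- rep(NA_integer_, n)
  for (bi in seq_along(spec$rigid_blocks)) block_of[spec$rigid_blocks[[bi]]] <- bi
  if (!is.null(spec$coupling)) {
    sigma[spec$coupling$residues] <- spec$sigma_rigid
    block_of[spec$coupling$residues] <- spec$coupling$block
  }
  centroids <- lapply(spec$rigid_blocks,
                      function(b) colMeans(base$ca[b, , drop = FALSE]))

  frames <- withr::with_seed(spec$seed, {
    lapply(seq_len(spec$n_frames), function(f) {
      ca <- base$ca; cb <- base$cb
      for (bi in seq_along(spec$rigid_blocks)) {
        R <- random_rotation(spec$block_rot_deg)
        tr <- stats::rnorm(3, 0, spec$block_trans)
        sel <- which(block_of == bi)
        cen <- centroids[[bi]]
        ca[sel, ] <- sweep(sweep(ca[sel, , drop = FALSE], 2, cen) %*% t(R),
                           2, cen + tr, `+`)
        cb[sel, ] <- sweep(sweep(cb[sel, , drop = FALSE], 2, cen) %*% t(R),
                           2, cen + tr, `+`)
      }
      eps <- matrix(stats::rnorm(3 * n), n, 3) * sigma
      ca <- ca + eps; cb <- cb + eps
      if (spec$global_motion) {
        R <- random_rotation()
        tr <- stats::runif(3, -15, 15)
        ca <- ca %*% t(R) + matrix(tr, n, 3, byrow = TRUE)
        cb <- cb %*% t(R) + matrix(tr, n, 3, byrow = TRUE)
      }
      tibble::tibble(frame = f, residue_index = seq_len(n),
                     residue_label = paste0("A", seq_len(n)),
                     ca_x = ca[, 1], ca_y = ca[, 2], ca_z = ca[, 3],
                     cb_x = cb[, 1], cb_y = cb[, 2], cb_z = cb[, 3],
                     cb_virtual = FALSE)
    })
  })
  as_lsp_ensemble(dplyr::bind_rows(frames), construct = spec$construct,
                  source = sprintf("synthetic (seed %d)", spec$seed))
}
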