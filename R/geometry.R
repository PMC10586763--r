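#' LSP similarity cutoffs
#'
#' Bundles the contact cutoff used to build each frame's residue graph and
#' the four tolerances under which two links count as "similar" when two
#' frames are aligned. All comparisons are strict (`<`), so results are
#' bit-reproducible at the printed boundaries.
#'
#' @param contact_cutoff Cα–Cα contact distance in Å below which a residue
#'   pair is linked within one frame. Default 12 Å.
#' @param tol_caca Tolerance (Å) on the Cα1–Cα2 distance difference.
#' @param tol_cross Tolerance (Å) on both cross distances
#'   (Cα1–Cβ2 and Cα2–Cβ1).
#' @param tol_theta Tolerance (degrees) on the circular difference of the
#'   Cβ1–Cα1–Cα2–Cβ2 dihedral.
#' @return A list of class `lsp_cutoffs`.
#' @examples
#' lsp_cutoffs()
#' @export
lsp_cutoffs <- function(contact_cutoff = 12, tol_caca = 0.2,
                        tol_cross = 0.45, tol_theta = 10) {
  vals <- c(contact_cutoff = contact_cutoff, tol_caca = tol_caca,
            tol_cross = tol_cross, tol_theta = tol_theta)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("all cutoffs must be finite and strictly positive", call. = FALSE)
  }
  if (tol_theta > 180) stop("tol_theta must be <= 180 degrees", call. = FALSE)
  structure(as.list(vals), class = "lsp_cutoffs")
}

#' @export
print.lsp_cutoffs <- function(x, ...) {
  cat(sprintf(
    "<lsp_cutoffs> contact < %g Å | tolerances: ΔCαCα < %g Å, Δcross < %g Å, Δθ < %g°\n",
    x$contact_cutoff, x$tol_caca, x$tol_cross, x$tol_theta))
  invisible(x)
}

# row-wise cross product of two n x 3 matrices
cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

rownorm <- function(a) sqrt(rowSums(a * a))

as_coord_matrix <- function(x, arg) {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 3)
  x <- as.matrix(x)
  if (ncol(x) != 3 || !all(is.finite(x))) {
    stop(sprintf("`%s` must be finite 3-vectors (n x 3)", arg), call. = FALSE)
  }
  x
}

# Direction constants for the ideal tetrahedral C-beta, expressed in the
# local frame {b = CA-N, c = C-CA, a = b x c}. Reproduces ideal L-amino-acid
# side-chain geometry to < 0.1 A; the result is rescaled to exactly
# `bond_length` from CA.
.vcb_coef <- c(a = -0.58273431, b = 0.56802827, c = -0.54067466)

#' Construct a virtual Cβ from backbone N, Cα, C
#'
#' Places an ideal tetrahedral β-carbon for residues that have none
#' (glycine), on the side of the N–Cα–C plane consistent with L-amino-acid
#' chirality. The construction uses only internal geometry, so it commutes
#' with any rigid motion of the inputs.
#'
#' @param n,ca,c Backbone coordinates in Å: numeric 3-vectors or n×3
#'   matrices (rows are residues).
#' @param bond_length Cα–Cβ distance of the constructed atom, Å.
#' @param labels Optional residue labels used in error messages.
#' @return An n×3 matrix (or 3-vector if all inputs were vectors) with
#'   `|result - ca| == bond_length` to 1e-6 Å.
#' @examples
#' virtual_cb(n = c(-1.458, 0, 0), ca = c(0, 0, 0), c = c(0.551, 1.420, 0))
#' @export
virtual_cb <- function(n, ca, c, bond_length = 1.521, labels = NULL) {
  drop_out <- is.null(dim(n)) && is.null(dim(ca)) && is.null(dim(c))
  n <- as_coord_matrix(n, "n"); ca <- as_coord_matrix(ca, "ca")
  c <- as_coord_matrix(c, "c")
  b <- ca - n
  cv <- c - ca
  a <- cross3(b, cv)
  # |b x c| ~ 0 catches both collinear and coincident backbone atoms
  bad <- rownorm(a) < 1e-8 * pmax(rownorm(b) * rownorm(cv), 1e-12)
  if (any(bad)) {
    who <- if (is.null(labels)) which(bad)[1] else labels[which(bad)[1]]
    stop(sprintf("degenerate backbone geometry (collinear N/CA/C) at residue %s",
                 who), call. = FALSE)
  }
  d <- .vcb_coef["a"] * a + .vcb_coef["b"] * b + .vcb_coef["c"] * cv
  d <- d / rownorm(d)
  out <- ca + bond_length * d
  if (drop_out) drop(out) else out
}

# Signed dihedral (degrees, (-180, 180]) of atom sequence p1-p2-p3-p4,
# vectorised over rows. IUPAC sign convention. atan2(0, 0) = 0, so pairs
# with a degenerate dihedral yield 0 rather than NaN; callers that must
# reject degeneracy check the normal norms themselves.
dihedral_deg <- function(p1, p2, p3, p4) {
  u1 <- p2 - p1; u2 <- p3 - p2; u3 <- p4 - p3
  n1 <- cross3(u1, u2)
  n2 <- cross3(u2, u3)
  m <- cross3(n1, u2 / pmax(rownorm(u2), 1e-300))
  th <- atan2(rowSums(m * n2), rowSums(n1 * n2)) * 180 / pi
  th[th <= -180] <- 180
  th
}

#' Four-number LSP link descriptor of a residue pair
#'
#' Describes the mutual orientation of two residues' Cα–Cβ vectors by three
#' distances (Cα1–Cα2, Cα1–Cβ2, Cα2–Cβ1) and the signed dihedral θ of the
#' atom sequence Cβ1–Cα1–Cα2–Cβ2. All four numbers are internal coordinates:
#' invariant under rigid motion, with θ changing sign under reflection.
#'
#' @param ca1,cb1,ca2,cb2 Coordinates in Å (3-vectors or n×3 matrices).
#' @return A tibble with columns `d_caca`, `d_ca1cb2`, `d_ca2cb1`, `theta`
#'   (degrees in (−180, 180]).
#' @examples
#' link_descriptor(ca1 = c(0, 0, 0), cb1 = c(0, 0, 1.5),
#'                 ca2 = c(6, 0, 0), cb2 = c(6, 0, 1.5))
#' @export
link_descriptor <- function(ca1, cb1, ca2, cb2) {
  ca1 <- as_coord_matrix(ca1, "ca1"); cb1 <- as_coord_matrix(cb1, "cb1")
  ca2 <- as_coord_matrix(ca2, "ca2"); cb2 <- as_coord_matrix(cb2, "cb2")
  d_caca <- rownorm(ca2 - ca1)
  if (any(d_caca < 1e-9)) {
    stop("coincident Cα atoms: link descriptor undefined", call. = FALSE)
  }
  u2 <- ca2 - ca1
  n1 <- cross3(ca1 - cb1, u2)
  n2 <- cross3(u2, cb2 - ca2)
  degen <- rownorm(n1) < 1e-9 | rownorm(n2) < 1e-9
  if (any(degen)) {
    stop(sprintf("degenerate dihedral (Cβ on the Cα-Cα axis) for pair row %d",
                 which(degen)[1]), call. = FALSE)
  }
  tibble::tibble(
    d_caca = d_caca,
    d_ca1cb2 = rownorm(cb2 - ca1),
    d_ca2cb1 = rownorm(cb1 - ca2),
    theta = dihedral_deg(cb1, ca1, ca2, cb2)
  )
}

#' Cα contact pairs of one frame
#'
#' Links every residue pair whose Cα–Cα distance is strictly below the
#' contact cutoff. Sequence-adjacent residues are not excluded.
#'
#' @param frame A one-frame residue table (see [as_lsp_ensemble()]): columns
#'   `residue_index`, `ca_x`, `ca_y`, `ca_z`.
#' @param cutoffs An [lsp_cutoffs()] object (only `contact_cutoff` is used).
#' @return A tibble with columns `i`, `j` (residue indices, `i < j`) and
#'   `d_caca` (Å).
#' @export
contact_pairs <- function(frame, cutoffs = lsp_cutoffs()) {
  ca <- as.matrix(frame[, c("ca_x", "ca_y", "ca_z")])
  idx <- frame$residue_index
  n <- nrow(ca)
  if (n < 2) return(tibble::tibble(i = integer(), j = integer(), d_caca = numeric()))
  pr <- pair_index(n)
  d <- rownorm(ca[pr$jj, , drop = FALSE] - ca[pr$ii, , drop = FALSE])
  keep <- d < cutoffs$contact_cutoff
  tibble::tibble(i = idx[pr$ii[keep]], j = idx[pr$jj[keep]], d_caca = d[keep])
}

# upper-triangle pair indices (ii < jj) of n items, in column-major
# (j ascending, then i) order; fixed ordering keeps runs reproducible
pair_index <- function(n) {
  jj <- rep.int(seq_len(n), seq_len(n) - 1L)
  ii <- sequence(seq_len(n) - 1L)
  list(ii = ii, jj = jj, n_pairs = (n * (n - 1L)) %/% 2L)
}

#' Link descriptors of residue pairs within one frame
#'
#' @param frame A one-frame residue table.
#' @param pairs A tibble of residue-index pairs (`i`, `j`); defaults to the
#'   frame's contact pairs.
#' @param cutoffs An [lsp_cutoffs()] object used when `pairs` is derived.
#' @return `pairs` with descriptor columns `d_caca`, `d_ca1cb2`, `d_ca2cb1`,
#'   `theta` appended.
#' @export
link_descriptors <- function(frame, pairs = NULL, cutoffs = lsp_cutoffs()) {
  if (is.null(pairs)) pairs <- contact_pairs(frame, cutoffs)
  ca <- as.matrix(frame[, c("ca_x", "ca_y", "ca_z")])
  cb <- as.matrix(frame[, c("cb_x", "cb_y", "cb_z")])
  pos <- match(c(pairs$i, pairs$j), frame$residue_index)
  np <- nrow(pairs)
  pi1 <- pos[seq_len(np)]; pi2 <- pos[np + seq_len(np)]
  d <- link_descriptor(ca[pi1, , drop = FALSE], cb[pi1, , drop = FALSE],
                       ca[pi2, , drop = FALSE], cb[pi2, , drop = FALSE])
  dplyr::bind_cols(pairs[, c("i", "j")], d)
}

# circular difference of two angle vectors in degrees, result in [0, 180]
circ_diff_deg <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}
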