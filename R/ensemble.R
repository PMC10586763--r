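#' Conformational-ensemble container
#'
#' An `lsp_ensemble` is a tibble with one row per residue per frame and
#' columns `frame` (1-based), `residue_index` (1-based chain ordinal),
#' `residue_label` (free text, display only), `ca_x/ca_y/ca_z`,
#' `cb_x/cb_y/cb_z` (Å) and `cb_virtual` (logical). The construct name and
#' source are carried as attributes. All computations key on
#' `residue_index`; `residue_label` is never interpreted, so renumbering
#' conventions are a pure display mapping.
#'
#' @param x A data frame with the columns above (`residue_label` and
#'   `cb_virtual` optional).
#' @param construct Construct name, e.g. `"WT"` or `"R42P"`.
#' @param source Free-text provenance note.
#' @return An `lsp_ensemble` tibble.
#' @export
as_lsp_ensemble <- function(x, construct = "unnamed", source = "") {
  x <- tibble::as_tibble(x)
  need <- c("frame", "residue_index", "ca_x", "ca_y", "ca_z",
            "cb_x", "cb_y", "cb_z")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("ensemble table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"residue_label" %in% names(x)) {
    x$residue_label <- paste0("X", x$residue_index)
  }
  if (!"cb_virtual" %in% names(x)) x$cb_virtual <- FALSE
  x <- x[order(x$frame, x$residue_index),
         c("frame", "residue_index", "residue_label",
           "ca_x", "ca_y", "ca_z", "cb_x", "cb_y", "cb_z", "cb_virtual")]
  out <- tibble::new_tibble(x, construct = construct, source = source,
                            class = "lsp_ensemble")
  validate_ensemble(out)
  out
}

validate_ensemble <- function(ens) {
  coords <- as.matrix(ens[, c("ca_x", "ca_y", "ca_z", "cb_x", "cb_y", "cb_z")])
  if (!all(is.finite(coords))) {
    stop("non-finite coordinates in ensemble", call. = FALSE)
  }
  bl <- rownorm(as.matrix(ens[, c("ca_x", "ca_y", "ca_z")]) -
                  as.matrix(ens[, c("cb_x", "cb_y", "cb_z")]))
  if (any(bl < 0.5 | bl > 3.0)) {
    bad <- which(bl < 0.5 | bl > 3.0)[1]
    stop(sprintf("Cα-Cβ distance %.3f Å outside [0.5, 3] Å at residue %s, frame %d",
                 bl[bad], ens$residue_label[bad], ens$frame[bad]), call. = FALSE)
  }
  frames <- unique(ens$frame)
  if (length(frames) < 1) stop("empty ensemble", call. = FALSE)
  ros <- ens[ens$frame == frames[1], c("residue_index", "residue_label")]
  if (anyDuplicated(ros$residue_index)) {
    stop("duplicated residue_index within a frame", call. = FALSE)
  }
  for (f in frames[-1]) {
    r2 <- ens[ens$frame == f, c("residue_index", "residue_label")]
    if (!identical(ros$residue_index, r2$residue_index) ||
        !identical(ros$residue_label, r2$residue_label)) {
      d <- which(!(ros$residue_index %in% r2$residue_index) |
                   ros$residue_label != r2$residue_label[
                     match(ros$residue_index, r2$residue_index)])[1]
      stop(sprintf("residue roster drifts at frame %d (first discordant residue: %s)",
                   f, ros$residue_label[d]), call. = FALSE)
    }
  }
  invisible(ens)
}

#' @export
print.lsp_ensemble <- function(x, ...) {
  cat(sprintf("<lsp_ensemble> construct '%s': %d frames x %d residues\n",
              ensemble_construct(x), n_frames(x), n_residues_of(x)))
  NextMethod()
}

#' Number of frames / residues of an ensemble
#' @param ens An `lsp_ensemble`.
#' @return An integer.
#' @export
n_frames <- function(ens) length(unique(ens$frame))

#' @rdname n_frames
#' @export
n_residues_of <- function(ens) length(unique(ens$residue_index))

#' @rdname n_frames
#' @export
ensemble_construct <- function(ens) attr(ens, "construct") %||% "unnamed"

#' Extract one frame of an ensemble as a residue table
#' @param ens An `lsp_ensemble`.
#' @param f Frame number (1-based, as stored in `frame`).
#' @return A tibble with one row per residue.
#' @export
get_frame <- function(ens, f) {
  out <- ens[ens$frame == f, ]
  if (nrow(out) == 0) stop(sprintf("frame %s not present", f), call. = FALSE)
  tibble::as_tibble(out)
}

#' Residue roster of an ensemble
#' @param ens An `lsp_ensemble`.
#' @return A tibble with `residue_index` and `residue_label`.
#' @export
residue_roster <- function(ens) {
  f1 <- ens$frame[1]
  tibble::as_tibble(ens[ens$frame == f1, c("residue_index", "residue_label")])
}

# dense array view used by the aligner: list(ca, cb) of [n_res x 3 x n_frames]
ensemble_arrays <- function(ens) {
  frames <- sort(unique(ens$frame))
  roster <- residue_roster(ens)
  nr <- nrow(roster); nf <- length(frames)
  ord <- order(match(ens$frame, frames), ens$residue_index)
  ca <- as.matrix(ens[ord, c("ca_x", "ca_y", "ca_z")])
  cb <- as.matrix(ens[ord, c("cb_x", "cb_y", "cb_z")])
  list(ca = array(t(ca), c(3, nr, nf)), cb = array(t(cb), c(3, nr, nf)),
       frames = frames, roster = roster)
}

#' Relabel residues for display
#'
#' Applies a renumbering map (e.g. file numbering to another isoform's
#' numbering convention) to the `residue_label` column only. Computations
#' are keyed on `residue_index` and therefore invariant to this.
#'
#' @param x An `lsp_ensemble` or any tibble with a `residue_label` column.
#' @param map A named character vector, `old label -> new label`. Must be
#'   injective; labels absent from the map pass through unchanged.
#' @return `x` with labels rewritten.
#' @export
relabel_residues <- function(x, map) {
  if (anyDuplicated(unname(map))) {
    stop("renumbering map must be injective", call. = FALSE)
  }
  hit <- x$residue_label %in% names(map)
  x$residue_label[hit] <- unname(map[x$residue_label[hit]])
  x
}

#' Apply a rigid transform to every frame of an ensemble
#'
#' Utility for invariance testing: rotates and translates all atoms of the
#' selected frames. LSP descriptors are internal coordinates, so downstream
#' networks are unchanged.
#'
#' @param ens An `lsp_ensemble`.
#' @param rotation A 3×3 rotation matrix, or a function `frame -> matrix`
#'   giving a per-frame rotation.
#' @param translation A 3-vector (Å), or a function `frame -> 3-vector`.
#' @return The transformed ensemble.
#' @export
transform_ensemble <- function(ens, rotation = diag(3), translation = c(0, 0, 0)) {
  rot_of <- if (is.function(rotation)) rotation else function(f) rotation
  tr_of <- if (is.function(translation)) translation else function(f) translation
  for (f in unique(ens$frame)) {
    sel <- ens$frame == f
    R <- rot_of(f); tr <- tr_of(f)
    for (p in list(c("ca_x", "ca_y", "ca_z"), c("cb_x", "cb_y", "cb_z"))) {
      m <- as.matrix(ens[sel, p])
      ens[sel, p] <- m %*% t(R) + matrix(tr, nrow(m), 3, byrow = TRUE)
    }
  }
  ens
}

`%||%` <- function(a, b) if (is.null(a)) b else a
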