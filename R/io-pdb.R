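AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
AA1TO3 <- stats::setNames(names(AA3TO1), AA3TO1)

#' Read a multi-model PDB file as an ensemble
#'
#' Parses ATOM records of a (possibly multi-MODEL) PDB file and extracts
#' one `StructureFrame` per retained model. Only Cα and Cβ are kept;
#' glycine gets a virtual Cβ built from backbone N/Cα/C (or is dropped,
#' per `glycine`). Alternate locations resolve to the highest occupancy,
#' first-seen on ties.
#'
#' @param path PDB file.
#' @param chain Chain identifier; default the first chain in the file.
#' @param models Integer vector of model ordinals (1-based, in file order)
#'   to retain before striding; default all.
#' @param stride Keep every `stride`-th retained model (models 1, 1+s, …).
#' @param glycine `"virtual"` (default) or `"drop"`.
#' @param construct Construct label for the ensemble.
#' @param bond_length Virtual Cβ bond length, Å.
#' @return An `lsp_ensemble`. Residue ordinals are 1-based positions along
#'   the chain; labels are one-letter code + author residue number.
#' @export
read_pdb_ensemble <- function(path, chain = NULL, models = NULL, stride = 1,
                              glycine = c("virtual", "drop"),
                              construct = "unnamed", bond_length = 1.521) {
  glycine <- match.arg(glycine)
  if (stride < 1) stop("stride must be >= 1", call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  model_no <- cumsum(trimws(rec) == "MODEL")
  is_atom <- rec == "ATOM  "
  if (!any(is_atom)) stop(sprintf("no ATOM records in '%s'", path), call. = FALSE)
  atoms <- tibble::tibble(
    model = pmax(model_no[is_atom], 1L),
    name = trimws(substr(lines[is_atom], 13, 16)),
    altloc = substr(lines[is_atom], 17, 17),
    resname = trimws(substr(lines[is_atom], 18, 20)),
    chain = substr(lines[is_atom], 22, 22),
    resseq = trimws(substr(lines[is_atom], 23, 27)),  # resSeq + insert code
    x = as.numeric(substr(lines[is_atom], 31, 38)),
    y = as.numeric(substr(lines[is_atom], 39, 46)),
    z = as.numeric(substr(lines[is_atom], 47, 54)),
    occ = suppressWarnings(as.numeric(substr(lines[is_atom], 55, 60))))
  atoms$occ[is.na(atoms$occ)] <- 1
  if (is.null(chain)) chain <- atoms$chain[1]
  atoms <- atoms[atoms$chain == chain, ]
  if (nrow(atoms) == 0) {
    stop(sprintf("no atoms on chain '%s' in '%s'", chain, path), call. = FALSE)
  }
  all_models <- unique(atoms$model)
  keep <- if (is.null(models)) all_models else all_models[models]
  keep <- keep[!is.na(keep)]
  keep <- keep[seq(1, length(keep), by = stride)]
  if (length(keep) == 0) stop("empty model selection", call. = FALSE)
  atoms <- atoms[atoms$model %in% keep, ]

  frames <- lapply(seq_along(keep), function(fi) {
    m <- atoms[atoms$model == keep[fi], ]
    res_ids <- unique(m$resseq)
    rows <- lapply(seq_along(res_ids), function(ri) {
      r <- m[m$resseq == res_ids[ri], ]
      pick <- function(nm) {
        a <- r[r$name == nm, ]
        if (nrow(a) == 0) return(NULL)
        a <- a[order(-a$occ), ][1, ]       # highest occupancy, first on tie
        c(a$x, a$y, a$z)
      }
      ca <- pick("CA")
      if (is.null(ca)) {
        stop(sprintf("residue %s%s (model %d) lacks a CA atom",
                     r$resname[1], res_ids[ri], fi), call. = FALSE)
      }
      cb <- pick("CB")
      is_gly <- r$resname[1] == "GLY"
      virt <- FALSE
      if (is.null(cb)) {
        if (!is_gly) {
          stop(sprintf("non-glycine residue %s%s lacks a CB atom",
                       r$resname[1], res_ids[ri]), call. = FALSE)
        }
        if (glycine == "drop") return(NULL)
        nn <- pick("N"); cc <- pick("C")
        if (is.null(nn) || is.null(cc)) {
          stop(sprintf("glycine %s needs backbone N and C for a virtual CB",
                       res_ids[ri]), call. = FALSE)
        }
        cb <- virtual_cb(nn, ca, cc, bond_length,
                         labels = paste0("G", res_ids[ri]))
        virt <- TRUE
      }
      letter <- unname(AA3TO1[r$resname[1]])
      if (is.na(letter)) letter <- "X"
      tibble::tibble(
        frame = fi, residue_index = NA_integer_,
        residue_label = paste0(letter, gsub(" ", "", res_ids[ri])),
        ca_x = ca[1], ca_y = ca[2], ca_z = ca[3],
        cb_x = cb[1], cb_y = cb[2], cb_z = cb[3], cb_virtual = virt)
    })
    out <- dplyr::bind_rows(rows)
    out$residue_index <- seq_len(nrow(out))
    out
  })
  tab <- dplyr::bind_rows(frames)
  as_lsp_ensemble(tab, construct = construct,
                  source = sprintf("%s (chain %s)", path, chain))
}

#' Write an ensemble as a multi-model PDB file
#'
#' One MODEL per frame with CA and CB ATOM records per residue. Residue
#' names are recovered from the first letter of `residue_label` where it is
#' a standard one-letter code, else UNK; resSeq is taken from the digits of
#' the label (falling back to the ordinal).
#'
#' @param ens An `lsp_ensemble`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pdb_ensemble <- function(ens, path) {
  con <- file(path, "w")
  on.exit(close(con))
  frames <- sort(unique(ens$frame))
  roster <- residue_roster(ens)
  resname <- unname(AA1TO3[substr(roster$residue_label, 1, 1)])
  resname[is.na(resname)] <- "UNK"
  resseq <- suppressWarnings(as.integer(gsub("[^0-9]", "", roster$residue_label)))
  if (anyNA(resseq) || anyDuplicated(resseq)) resseq <- roster$residue_index
  atom_line <- function(serial, name, rn, rs, xyz) {
    sprintf("ATOM  %5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            serial, name, rn, rs, xyz[1], xyz[2], xyz[3])
  }
  for (f in seq_along(frames)) {
    fr <- get_frame(ens, frames[f])
    writeLines(sprintf("MODEL     %4d", f), con)
    serial <- 0L
    for (r in seq_len(nrow(fr))) {
      serial <- serial + 1L
      writeLines(atom_line(serial, "CA", resname[r], resseq[r],
                           c(fr$ca_x[r], fr$ca_y[r], fr$ca_z[r])), con)
      serial <- serial + 1L
      writeLines(atom_line(serial, "CB", resname[r], resseq[r],
                           c(fr$cb_x[r], fr$cb_y[r], fr$cb_z[r])), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Simulate an ensemble and write it as a multi-model PDB
#'
#' @param spec An [ensemble_spec()].
#' @param path Output PDB file.
#' @return `path`, invisibly.
#' @export
simulate_to_pdb <- function(spec, path) {
  write_pdb_ensemble(generate_ensemble(spec), path)
}
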