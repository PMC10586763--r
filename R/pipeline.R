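#' Configure an LSP network analysis run
#'
#' @param constructs Named list, one entry per construct. Each entry is an
#'   [ensemble_spec()] (simulated trajectory), an `lsp_ensemble`, or a list
#'   of either (multiple trajectories of the same construct).
#' @param reference Name of the reference construct (e.g. `"WT"`); must
#'   appear in `names(constructs)`.
#' @param cutoffs An [lsp_cutoffs()] object. Defaults are the standard
#'   12 Å / 0.2 Å / 0.45 Å / 10° set.
#' @param frames_per_window Frames per window (100 ≙ 10 ns at 0.1 ns).
#' @param out_dir Output directory.
#' @param seed Master seed; simulated constructs derive their per-spec
#'   seeds from it so a config rerun is bit-identical.
#' @param verbose Log one line per window (edge and component counts).
#' @return An `lsp_run_config` list.
#' @export
lsp_run_config <- function(constructs, reference, cutoffs = lsp_cutoffs(),
                           frames_per_window = 100,
                           out_dir = tempfile("lsp_run_"), seed = 1,
                           verbose = TRUE) {
  if (is.null(names(constructs)) || any(names(constructs) == "")) {
    stop("constructs must be a named list", call. = FALSE)
  }
  if (!reference %in% names(constructs)) {
    stop(sprintf("reference construct '%s' not among constructs", reference),
         call. = FALSE)
  }
  structure(list(constructs = constructs, reference = reference,
                 cutoffs = cutoffs, frames_per_window = frames_per_window,
                 out_dir = out_dir, seed = as.integer(seed),
                 verbose = verbose),
            class = "lsp_run_config")
}

#' The four-construct demonstration design
#'
#' Mirrors the WT / stiffened-loop / neutral / rescued comparison: `WT` and
#' `Q66N` use the base spec (the Q66N-like construct is a neutral mutant —
#' statistically identical dynamics, independent seed), `R42P` couples the
#' flexible loop into the second rigid block, and `R42P-Q66N` removes that
#' coupling again.
#'
#' @param n_frames Frames per construct (default 200 → 2 windows of 100).
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @param ... Passed to [lsp_run_config()].
#' @return An `lsp_run_config`.
#' @export
demo_run_config <- function(n_frames = 200, seed = 1,
                            out_dir = tempfile("lsp_demo_"), ...) {
  base <- ensemble_spec(n_frames = n_frames, construct = "WT")
  constructs <- list(
    WT = base,
    R42P = apply_coupling(base, construct = "R42P"),
    Q66N = ensemble_spec(n_frames = n_frames, construct = "Q66N"),
    `R42P-Q66N` = remove_coupling(apply_coupling(base), construct = "R42P-Q66N"))
  lsp_run_config(constructs, reference = "WT", out_dir = out_dir,
                 seed = seed, ...)
}

# seeds for simulated constructs derive from the master seed, the construct
# LABEL (never its position, so reordering a config cannot change numbers)
# and the trajectory index
label_seed_offset <- function(label) {
  sum(utf8ToInt(label) * (seq_len(nchar(label)) %% 7 + 1)) %% 100003L
}

resolve_construct <- function(entry, label, master_seed) {
  as_traj_list <- function(x) if (inherits(x, c("ensemble_spec", "lsp_ensemble")) ||
                                    is.data.frame(x)) list(x) else x
  trajs <- as_traj_list(entry)
  lapply(seq_along(trajs), function(t) {
    x <- trajs[[t]]
    if (inherits(x, "ensemble_spec")) {
      x$seed <- (x$seed + 1009 * master_seed + 97 * label_seed_offset(label) +
                   t) %% 2147483647
      x$construct <- label
      generate_ensemble(x)
    } else {
      attr(x, "construct") <- label
      x
    }
  })
}

#' Run the full LSP network pipeline
#'
#' For every construct: split trajectories into windows, perform all-to-all
#' LSP alignment per window, compute degree and betweenness centralities,
#' aggregate across windows (mean ± SE); then compare every non-reference
#' construct to the reference as percent difference of mean DC. Writes
#' per-construct centrality TSVs, DC comparison TSVs, consensus network
#' GraphML + GEXF files and a JSON provenance manifest. Partial outputs are
#' removed if any stage fails.
#'
#' @param config An [lsp_run_config()].
#' @return Invisibly, a list with `profiles`, `comparisons`, `networks`
#'   (consensus per construct), `hubs`, `manifest` and `files`.
#' @export
run_lsp_pipeline <- function(config) {
  stopifnot(inherits(config, "lsp_run_config"))
  out_dir <- config$out_dir
  created <- !dir.exists(out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) {
    if (created) unlink(out_dir, recursive = TRUE) else {
      unlink(list.files(out_dir, full.names = TRUE), recursive = TRUE)
    }
  })
  say <- function(...) if (isTRUE(config$verbose)) message(sprintf(...))

  labels <- names(config$constructs)
  ensembles <- purrr::imap(config$constructs, function(entry, label) {
    resolve_construct(entry, label, config$seed)
  })
  rosters <- purrr::map(ensembles, ~ residue_roster(.x[[1]]))
  for (k in seq_along(rosters)[-1]) {
    check_same_roster(rosters[[1]], rosters[[k]],
                      sprintf("constructs '%s' and '%s'", labels[1], labels[k]))
  }

  profiles <- list(); networks <- list(); hubs <- list()
  windows_per_construct <- integer()
  for (label in labels) {
    say("construct %s: aligning windows ...", label)
    nets <- ensemble_networks(ensembles[[label]],
                              frames_per_window = config$frames_per_window,
                              cutoffs = config$cutoffs)
    for (net in nets) {
      g <- as_igraph(net)
      say("  window %d: %d edges, %d components", attr(net, "window_id"),
          nrow(net), igraph::count_components(g))
    }
    profiles[[label]] <- aggregate_windows(nets, construct = label)
    networks[[label]] <- consensus_network(nets)
    hubs[[label]] <- detect_hubs(networks[[label]])
    windows_per_construct[label] <- length(nets)
  }

  comparisons <- purrr::map(setdiff(labels, config$reference), function(lab) {
    percent_difference(profiles[[lab]], profiles[[config$reference]], "dc")
  })

  files <- write_tables(profiles, comparisons, out_dir)
  for (label in labels) {
    for (ext in c("graphml", "gexf")) {
      f <- file.path(out_dir, sprintf("network_%s.%s", sanitize_label(label), ext))
      write_network(networks[[label]], f, profile = profiles[[label]],
                    hubs = hubs[[label]])
      files <- c(files, f)
    }
  }

  manifest <- list(
    package = "lspprn",
    version = as.character(utils::packageVersion("lspprn")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    reference = config$reference,
    constructs = labels,
    frames_per_window = config$frames_per_window,
    cutoffs = unclass(config$cutoffs),
    windows_per_construct = as.list(windows_per_construct),
    config_hash = config_hash(config))
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  files <- c(files, mf)
  ok <- TRUE
  invisible(list(profiles = profiles, comparisons = comparisons,
                 networks = networks, hubs = hubs, manifest = manifest,
                 files = files))
}

config_hash <- function(config) {
  clean <- config
  clean$out_dir <- NULL; clean$verbose <- NULL
  tmp <- tempfile(fileext = ".rds")
  on.exit(unlink(tmp))
  saveRDS(clean, tmp, version = 2, compress = FALSE)
  unname(tools::md5sum(tmp))
}

#' Read a pipeline configuration from YAML
#'
#' Expected layout:
#' ```yaml
#' reference: WT
#' frames_per_window: 100
#' seed: 1
#' out_dir: results/run1
#' cutoffs: {contact_cutoff: 12, tol_caca: 0.2, tol_cross: 0.45, tol_theta: 10}
#' constructs:
#'   WT:
#'     pdb: [wt_traj1.pdb, wt_traj2.pdb]
#'   R42P:
#'     simulate: {n_residues: 50, n_frames: 100, couple_loop: true}
#' ```
#' `pdb` entries are read with [read_pdb_ensemble()] (optional `chain`,
#' `stride` fields apply to all paths); `simulate` entries become
#' [ensemble_spec()]s, with `couple_loop: true` applying [apply_coupling()]
#' with its defaults.
#'
#' @param path YAML file.
#' @return An `lsp_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cuts <- do.call(lsp_cutoffs, as.list(y$cutoffs %||% list()))
  constructs <- purrr::imap(y$constructs, function(entry, label) {
    if (!is.null(entry$simulate)) {
      args <- entry$simulate
      couple <- isTRUE(args$couple_loop)
      args$couple_loop <- NULL
      spec <- do.call(ensemble_spec, c(args, list(construct = label)))
      if (couple) spec <- apply_coupling(spec, construct = label)
      spec
    } else if (!is.null(entry$pdb)) {
      lapply(entry$pdb, function(p) {
        read_pdb_ensemble(p, chain = entry$chain,
                          stride = entry$stride %||% 1, construct = label)
      })
    } else {
      stop(sprintf("construct '%s' has neither 'pdb' nor 'simulate'", label),
           call. = FALSE)
    }
  })
  lsp_run_config(constructs, reference = y$reference, cutoffs = cuts,
                 frames_per_window = y$frames_per_window %||% 100,
                 out_dir = y$out_dir %||% tempfile("lsp_run_"),
                 seed = y$seed %||% 1)
}
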