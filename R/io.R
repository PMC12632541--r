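#' Write a multi-state model as a multi-model PDB (or mmCIF) file
#'
#' Each state becomes one MODEL/ENDMDL block; the unit cell (if present)
#' goes into CRYST1. PDB has no field for state weights, so the weight
#' matrix is always written to a JSON sidecar `<path>.weights.json`.
#'
#' @param model A [multi_state_model()].
#' @param path Output path.
#' @param format `"pdb"` (default) or `"cif"` (minimal mmCIF atom_site
#'   loop).
#' @return Invisibly, `path`.
#' @export
write_model <- function(model, path, format = c("pdb", "cif")) {
  format <- match.arg(format)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path: directory does not exist: ", dir)
  st1 <- model$states[[1]]
  lines <- character()
  if (format == "pdb") {
    if (!is.null(model$cell)) {
      grp <- if (!is.null(model$ops)) attr(model$ops, "name") else "P 1"
      lines <- c(lines, sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s",
                                model$cell$a, model$cell$b, model$cell$c,
                                model$cell$alpha, model$cell$beta,
                                model$cell$gamma, grp))
    }
    for (i in seq_along(model$states)) {
      s <- model$states[[i]]
      lines <- c(lines, sprintf("MODEL     %4d", i))
      for (a in seq_len(nrow(s$xyz))) {
        lines <- c(lines, sprintf(
          "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          a, substr(s$name[a], 1, 4), "TOY", "A", s$resid[a],
          s$xyz[a, 1], s$xyz[a, 2], s$xyz[a, 3], s$occ[a], s$b[a],
          s$element[a]))
      }
      lines <- c(lines, "ENDMDL")
    }
    lines <- c(lines, "END")
  } else {
    lines <- c("data_msxtal", "#")
    if (!is.null(model$cell)) {
      lines <- c(lines,
                 sprintf("_cell.length_a %.4f", model$cell$a),
                 sprintf("_cell.length_b %.4f", model$cell$b),
                 sprintf("_cell.length_c %.4f", model$cell$c),
                 sprintf("_cell.angle_alpha %.4f", model$cell$alpha),
                 sprintf("_cell.angle_beta %.4f", model$cell$beta),
                 sprintf("_cell.angle_gamma %.4f", model$cell$gamma), "#")
    }
    # canonical PDBx atom_site column set so third-party readers accept it
    lines <- c(lines, "loop_",
               paste0("_atom_site.",
                      c("group_PDB", "id", "type_symbol", "label_atom_id",
                        "label_alt_id", "label_comp_id", "label_asym_id",
                        "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                        "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                        "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
                        "auth_comp_id", "auth_asym_id", "auth_atom_id",
                        "pdbx_PDB_model_num")))
    aid <- 0
    for (i in seq_along(model$states)) {
      s <- model$states[[i]]
      for (a in seq_len(nrow(s$xyz))) {
        aid <- aid + 1
        lines <- c(lines, sprintf(
          "ATOM %d %s %s . TOY A 1 %d ? %.3f %.3f %.3f %.2f %.2f ? %d TOY A %s %d",
          aid, s$element[a], s$name[a], s$resid[a],
          s$xyz[a, 1], s$xyz[a, 2], s$xyz[a, 3], s$occ[a], s$b[a],
          s$resid[a], s$name[a], i))
      }
    }
    lines <- c(lines, "#")
  }
  writeLines(lines, path)
  jsonlite::write_json(
    list(weights = unclass(model$weights),
         n_states = n_states(model), n_conditions = n_conditions(model)),
    paste0(path, ".weights.json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a (multi-model) PDB file as a multi-state model
#'
#' MODEL/ENDMDL blocks become states; all blocks must share composition.
#' The unit cell comes from CRYST1 (overridable), the weight matrix from
#' the `<path>.weights.json` sidecar when present (uniform otherwise).
#'
#' @param path PDB file path.
#' @param cell Optional [unit_cell()] overriding the header.
#' @param ops Optional [symmetry_ops()]; defaults to the CRYST1 group when
#'   it is in the built-in table, else P1.
#' @param topology Optional [topology()] attached to every state.
#' @return A [multi_state_model()] with `cell` and `ops` fields.
#' @export
read_model <- function(path, cell = NULL, ops = NULL, topology = NULL) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  nmod <- dim(pdb$xyz)[1]
  el <- trimws(at$elesy)
  if (any(!nzchar(el))) el <- substr(trimws(at$elety), 1, 1)
  states <- lapply(seq_len(nmod), function(i) {
    xyz <- matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE)
    atomic_state(el, xyz, b = at$b, occ = at$o, topology = topology,
                 name = trimws(at$elety), resid = at$resno)
  })
  sidecar <- paste0(path, ".weights.json")
  if (file.exists(sidecar)) {
    js <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    W <- if (is.matrix(js$weights)) js$weights
         else matrix(unlist(js$weights), nrow = js$n_states, byrow = TRUE)
  } else {
    W <- matrix(1 / nmod, nmod, 1)
  }
  model <- multi_state_model(states, W)
  if (is.null(cell)) {
    cr <- grep("^CRYST1", readLines(path, n = 50), value = TRUE)
    if (length(cr)) {
      num <- function(a, b) as.numeric(substr(cr[1], a, b))
      cell <- unit_cell(num(7, 15), num(16, 24), num(25, 33),
                        num(34, 40), num(41, 47), num(48, 54))
      if (is.null(ops)) {
        g <- gsub(" ", "", substr(cr[1], 56, 66))
        if (g %in% names(builtin_symmetry_table())) ops <- symmetry_ops(g)
      }
    }
  }
  model$cell <- cell
  model$ops <- if (is.null(ops)) symmetry_ops("P1") else ops
  model
}

#' Read reflections from the CSV dialect
#'
#' Columns `h,k,l,F` (or `f_obs`), optional `sigma` and `free`. The set is
#' symmetry-reduced and annotated (d, centric, epsilon) on load.
#'
#' @param path CSV file path.
#' @param cell An [unit_cell()].
#' @param ops An [symmetry_ops()] set (default P1).
#' @param condition_id Condition label (defaults to the file stem).
#' @return A [reflection_set()].
#' @export
read_reflections <- function(path, cell, ops = symmetry_ops("P1"),
                             condition_id = NULL) {
  df <- utils::read.csv(path)
  names(df) <- tolower(names(df))
  if ("f" %in% names(df) && !"f_obs" %in% names(df))
    names(df)[names(df) == "f"] <- "f_obs"
  if (is.null(condition_id))
    condition_id <- sub("\\.[^.]*$", "", basename(path))
  if ("free" %in% names(df)) df$free <- as.logical(df$free)
  reflection_set(df, cell, ops, condition_id)
}

#' Write reflections to the CSV dialect (lossless round trip)
#'
#' @param refls A [reflection_set()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_reflections <- function(refls, path) {
  tab <- refls$data[, c("h", "k", "l", "f_obs", "sigma", "free")]
  names(tab)[4] <- "F"
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration (YAML or JSON)
#'
#' Paths referenced by the configuration are checked for existence at
#' validation time.
#'
#' @param path Config file path.
#' @param validate_paths Check that referenced files exist.
#' @return Named list with any `sampler` entry converted to a
#'   [sampler_config()] and `free` to a [free_set_spec()].
#' @export
read_run_config <- function(path, validate_paths = TRUE) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (validate_paths) {
    for (key in intersect(names(cfg), c("model", "forcefield"))) {
      if (!file.exists(cfg[[key]]))
        stop("configured path does not exist (", key, "): ", cfg[[key]])
    }
    for (p in unlist(cfg$datasets)) {
      if (!file.exists(p)) stop("configured dataset does not exist: ", p)
    }
  }
  if (!is.null(cfg$sampler)) cfg$sampler <- do.call(sampler_config, cfg$sampler)
  if (!is.null(cfg$free)) cfg$free <- do.call(free_set_spec, cfg$free)
  cfg
}
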