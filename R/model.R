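#' Atomic state
#'
#' One complete conformation: elements, Cartesian coordinates (Angstrom),
#' isotropic B-factors and occupancies, plus an optional bonded-topology
#' reference used by the molecular-mechanics prior. Under the default
#' discrete-state representation all B-factors are 15 and all occupancies 1;
#' conformational heterogeneity is carried by the states themselves.
#'
#' @param element Character vector of element symbols (e.g. "C").
#' @param xyz n x 3 numeric matrix of Cartesian coordinates (Angstrom).
#' @param b Isotropic B-factors (Angstrom^2), recycled; default 15.
#' @param occ Occupancies, recycled; default 1.
#' @param topology Optional [topology()] describing bonded terms and atom
#'   types (shared across states of one model).
#' @param name Optional per-atom names (for PDB output); default element+index.
#' @param resid Optional per-atom residue indices (for PDB output).
#' @return An object of class `atomic_state`.
#' @export
atomic_state <- function(element, xyz, b = 15, occ = 1, topology = NULL,
                         name = NULL, resid = NULL) {
  xyz <- rbind(xyz); storage.mode(xyz) <- "double"
  n <- nrow(xyz)
  stopifnot(ncol(xyz) == 3, length(element) == n)
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  if (is.null(name)) name <- paste0(element, seq_len(n))
  if (is.null(resid)) resid <- rep(1L, n)
  structure(list(element = as.character(element), xyz = xyz,
                 b = rep_len(as.numeric(b), n), occ = rep_len(as.numeric(occ), n),
                 topology = topology, name = as.character(name),
                 resid = as.integer(resid)),
            class = "atomic_state")
}

#' @export
print.atomic_state <- function(x, ...) {
  cat(sprintf("<atomic state> %d atoms (%s)\n", nrow(x$xyz),
              paste(names(sort(-table(x$element))), collapse = ",")))
  invisible(x)
}

#' Bonded topology
#'
#' Index tables (1-based atom indices) of bonds, angles, dihedrals and
#' improper dihedrals, plus per-atom force-field type labels. Used by the
#' molecular-mechanics prior; the scattering forward model ignores it.
#'
#' @param types Character vector of per-atom type labels.
#' @param bonds,angles,dihedrals,impropers Integer matrices with 2, 3, 4 and
#'   4 columns respectively (may be empty).
#' @return An object of class `topology`.
#' @export
topology <- function(types, bonds = NULL, angles = NULL, dihedrals = NULL,
                     impropers = NULL) {
  as_idx <- function(m, k) {
    if (is.null(m) || length(m) == 0) return(matrix(integer(), 0, k))
    m <- rbind(m); storage.mode(m) <- "integer"
    stopifnot(ncol(m) == k)
    m
  }
  structure(list(types = as.character(types),
                 bonds = as_idx(bonds, 2), angles = as_idx(angles, 3),
                 dihedrals = as_idx(dihedrals, 4), impropers = as_idx(impropers, 4)),
            class = "topology")
}

#' State weight matrix
#'
#' N x J matrix of per-condition state populations: entries in [0, 1], each
#' column summing to 1 (within 1e-12). Column j weights the N states under
#' condition j.
#'
#' @param w Numeric matrix (or vector for a single condition).
#' @return A validated numeric matrix of class `weight_matrix`.
#' @export
weight_matrix <- function(w) {
  w <- cbind(w); storage.mode(w) <- "double"
  if (any(w < -1e-12) || any(w > 1 + 1e-12)) stop("weights must lie in [0, 1]")
  cs <- colSums(w)
  if (any(abs(cs - 1) > 1e-12)) stop("weight-matrix columns must sum to 1")
  structure(pmin(pmax(w, 0), 1), class = c("weight_matrix", "matrix", "array"))
}

#' Multi-state model
#'
#' N atomic states of identical composition plus the N x J weight matrix;
#' the object being refined.
#'
#' @param states List of [atomic_state()]s with identical atom count,
#'   ordering and element sequence.
#' @param weights An N x J [weight_matrix()] (or plain matrix/vector).
#' @return An object of class `multi_state_model`.
#' @export
multi_state_model <- function(states, weights) {
  if (inherits(states, "atomic_state")) states <- list(states)
  stopifnot(length(states) >= 1)
  el <- states[[1]]$element
  for (s in states) {
    if (!identical(s$element, el) || nrow(s$xyz) != length(el))
      stop("all states must have identical atom count, ordering and elements")
  }
  W <- weight_matrix(weights)
  if (nrow(W) != length(states))
    stop("weight matrix has ", nrow(W), " rows but model has ",
         length(states), " states")
  structure(list(states = states, weights = W), class = "multi_state_model")
}

#' @export
print.multi_state_model <- function(x, ...) {
  cat(sprintf("<multi-state model> N=%d states x %d atoms, J=%d conditions\n",
              length(x$states), nrow(x$states[[1]]$xyz), ncol(x$weights)))
  invisible(x)
}

n_states <- function(model) length(model$states)
n_conditions <- function(model) ncol(model$weights)

#' Replace the coordinates of every state
#' @param model A [multi_state_model()].
#' @param xyz_list List of n x 3 matrices, one per state.
#' @return The model with updated coordinates.
#' @keywords internal
set_coordinates <- function(model, xyz_list) {
  stopifnot(length(xyz_list) == n_states(model))
  for (i in seq_along(xyz_list)) model$states[[i]]$xyz <- xyz_list[[i]]
  model
}
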