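#' @keywords internal
sf_coefficients <- function(state, refls) {
  tab <- refls$data
  stol <- 1 / (2 * tab$d)
  els <- unique(state$element)
  fmat <- sapply(els, function(el) form_factor(el, stol))
  fmat <- matrix(fmat, nrow = length(stol),
                 dimnames = list(NULL, els))  # nrefl x nelem
  idx <- match(state$element, els)
  coef <- fmat[, idx, drop = FALSE] * exp(-outer(stol^2, state$b))
  sweep(coef, 2, state$occ, `*`)
}

#' @keywords internal
fractional_coords <- function(xyz, cell) {
  xyz %*% t(solve(orthogonalization_matrix(cell)))
}

#' Single-state structure factors
#'
#' Direct summation over atoms and symmetry operators,
#' `F(h) = sum_ops sum_atoms occ f(stol) exp(-B stol^2) exp(2 pi i h.(R x + t))`
#' with `stol = 1/(2d)` and the `exp(+2 pi i h.x)` phase convention.
#'
#' @param state An [atomic_state()].
#' @param refls A [reflection_set()] (amplitude columns are ignored; only the
#'   index list, cell and symmetry are used).
#' @return Complex vector of structure factors, one per reflection.
#' @export
single_state_sf <- function(state, refls) {
  stopifnot(inherits(state, "atomic_state"), inherits(refls, "reflection_set"))
  if (any(state$b < 0)) stop("negative B-factors")
  H <- as.matrix(refls$data[, c("h", "k", "l")]); storage.mode(H) <- "double"
  Xf <- fractional_coords(state$xyz, refls$cell)
  coef <- sf_coefficients(state, refls)
  F <- complex(nrow(H))
  for (op in refls$ops) {
    HR <- H %*% op$R
    ph <- exp(2i * pi * as.vector(H %*% op$t))
    F <- F + ph * sf_forward(HR, Xf, coef)
  }
  F
}

#' Multi-state protein structure factors
#'
#' The weighted complex sum over states, `F_C(h) = sum_i w_i F_i(h)`.
#'
#' @param f_states Complex matrix (n_refl x N) of per-state structure
#'   factors, or a list of complex vectors.
#' @param weights Numeric weight vector of length N summing to 1 (one column
#'   of the weight matrix).
#' @return Complex vector `F_C`.
#' @export
multi_state_sf <- function(f_states, weights) {
  if (is.list(f_states)) f_states <- do.call(cbind, f_states)
  weights <- as.numeric(weights)
  if (ncol(f_states) != length(weights))
    stop("state count (", ncol(f_states), ") does not match weight count (",
         length(weights), ")")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  as.vector(f_states %*% weights)
}

.vdw_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, P = 1.80,
                S = 1.80, Zn = 1.39)

#' Bulk-solvent structure factors (flat mask)
#'
#' A binary solvent mask on a regular grid over the unit cell: a voxel is
#' solvent when its minimum periodic distance to any atom of the weighted-
#' average structure exceeds the element's van der Waals radius plus the
#' probe radius minus the shrink radius. `F_B` is the discrete Fourier
#' transform of the mask scaled by the voxel volume.
#'
#' @param states List of [atomic_state()]s.
#' @param weights Length-N weight vector for the condition being modeled.
#' @param refls A [reflection_set()].
#' @param probe Probe radius in Angstrom (default 1.1).
#' @param shrink Shrink radius in Angstrom (default 0.9).
#' @param spacing Grid spacing in Angstrom (default `min(d)/4`); must be
#'   at most `d_min/2`.
#' @return List with complex `f_bulk` per reflection and the solvent
#'   `volume_fraction`.
#' @export
bulk_solvent_sf <- function(states, weights, refls, probe = 1.1, shrink = 0.9,
                            spacing = NULL) {
  cell <- refls$cell
  d_min <- min(refls$data$d)
  if (is.null(spacing)) spacing <- d_min / 4
  if (spacing > d_min / 2)
    stop("mask grid too coarse: spacing ", spacing, " > d_min/2 = ", d_min / 2)
  ng <- pmax(4L, as.integer(ceiling(c(cell$a, cell$b, cell$c) / spacing)))
  M <- orthogonalization_matrix(cell)
  if (length(states)) {
    weights <- as.numeric(weights)
    xyz <- Reduce(`+`, Map(function(s, w) w * s$xyz, states, weights))
    Xf <- fractional_coords(xyz, cell) %% 1
    # a voxel is protein if inside any atom's own exclusion radius
    # (vdW + probe - shrink); one distance pass per element present
    solvent <- rep(TRUE, prod(ng))
    for (el in unique(states[[1]]$element)) {
      sel <- states[[1]]$element == el
      dmin_el <- mask_min_distance(Xf[sel, , drop = FALSE], ng, M)
      solvent <- solvent & (dmin_el > .vdw_radii[[el]] + probe - shrink)
    }
  } else {
    solvent <- rep(TRUE, prod(ng))
  }
  mask <- array(as.numeric(solvent), dim = ng)
  Fgrid <- fft(mask, inverse = TRUE) * (cell$volume / prod(ng))
  H <- as.matrix(refls$data[, c("h", "k", "l")])
  idx <- cbind(H[, 1] %% ng[1], H[, 2] %% ng[2], H[, 3] %% ng[3]) + 1L
  list(f_bulk = Fgrid[idx], volume_fraction = mean(solvent))
}

#' Total model amplitude
#'
#' `F_M = k_total (F_C + k_mask F_B)`; returns magnitude and phase.
#'
#' @param f_calc Complex protein structure factors `F_C`.
#' @param f_bulk Complex bulk-solvent factors `F_B` (or NULL when solvent is
#'   disabled).
#' @param nuis A [nuisance_parameters()] object (only `k_total`, `k_mask`
#'   are used).
#' @return List with `f_model` (complex), `amp` (`|F_M|`) and `phi` (radians).
#' @export
total_amplitude <- function(f_calc, f_bulk, nuis) {
  if (is.null(f_bulk)) f_bulk <- complex(length(f_calc))
  fm <- nuis$k_total * (f_calc + nuis$k_mask * f_bulk)
  list(f_model = fm, amp = Mod(fm), phi = Arg(fm))
}

#' Evaluate the full forward model for one condition
#'
#' Computes per-state structure factors, the weighted multi-state sum, the
#' optional bulk-solvent term, fits (or applies) nuisance parameters, and
#' returns the total model amplitude and phase.
#'
#' @param model A [multi_state_model()].
#' @param refls A [reflection_set()].
#' @param condition Column of the weight matrix to use (default 1).
#' @param nuis A [nuisance_parameters()] object, or NULL to fit one from the
#'   work reflections.
#' @param solvent Logical; include the flat-mask bulk-solvent term (default
#'   FALSE for toy/synthetic work).
#' @param n_shells Resolution shells for the nuisance fit.
#' @return Object of class `model_sf`: list with `f_states` (complex matrix,
#'   n_refl x N), `f_calc`, `f_bulk`, `f_model`, `amp`, `phi`, `nuisance`.
#' @export
model_structure_factors <- function(model, refls, condition = 1, nuis = NULL,
                                    solvent = FALSE, n_shells = 10) {
  stopifnot(inherits(model, "multi_state_model"))
  w <- model$weights[, condition]
  f_states <- vapply(model$states, single_state_sf, complex(nrow(refls$data)),
                     refls = refls)
  f_states <- matrix(f_states, ncol = n_states(model))
  f_calc <- multi_state_sf(f_states, w)
  f_bulk <- NULL
  if (solvent) f_bulk <- bulk_solvent_sf(model$states, w, refls)$f_bulk
  if (is.null(nuis)) nuis <- fit_nuisance(refls, f_calc, f_bulk, n_shells)
  tot <- total_amplitude(f_calc, f_bulk, nuis)
  structure(list(f_states = f_states, f_calc = f_calc, f_bulk = f_bulk,
                 f_model = tot$f_model, amp = tot$amp, phi = tot$phi,
                 nuisance = nuis),
            class = "model_sf")
}

#' Coordinate gradients of an amplitude-weighted sum
#'
#' Gradient with respect to every atom of every state of the scalar
#' `sum_h dL/d|F_M|_h * |F_M|_h`, i.e. the chain rule of a per-reflection
#' target through the forward model. The gradient on state i scales with its
#' weight under the modeled condition; a state with zero weight receives a
#' zero X-ray gradient. The bulk-solvent term is held fixed (it is refreshed
#' with the nuisance parameters, not differentiated).
#'
#' @param model A [multi_state_model()].
#' @param refls A [reflection_set()].
#' @param msf A `model_sf` from [model_structure_factors()] evaluated at the
#'   current coordinates.
#' @param dl_damp Per-reflection derivative of the target with respect to
#'   `|F_M|` (free reflections should carry 0).
#' @param condition Weight-matrix column (default 1).
#' @return List of n_atom x 3 Cartesian gradient matrices, one per state.
#' @export
amplitude_coordinate_gradients <- function(model, refls, msf, dl_damp,
                                           condition = 1) {
  H <- as.matrix(refls$data[, c("h", "k", "l")]); storage.mode(H) <- "double"
  Minv <- solve(orthogonalization_matrix(refls$cell))
  w <- model$weights[, condition]
  base_pref <- dl_damp * msf$nuisance$k_total * exp(-1i * msf$phi)
  lapply(seq_len(n_states(model)), function(i) {
    if (w[i] == 0) return(matrix(0, nrow(model$states[[i]]$xyz), 3))
    st <- model$states[[i]]
    Xf <- fractional_coords(st$xyz, refls$cell)
    coef <- sf_coefficients(st, refls)
    G <- matrix(0, nrow(st$xyz), 3)
    for (op in refls$ops) {
      HR <- H %*% op$R
      SR <- HR %*% Minv
      pref <- w[i] * base_pref * exp(2i * pi * as.vector(H %*% op$t))
      G <- G + sf_gradient(HR, Xf, coef, Re(pref), Im(pref), SR)
    }
    G
  })
}

#' Nuisance parameters
#'
#' Container for the scaling/error model: global scale `k_total` (> 0),
#' bulk-solvent scale `k_mask` (>= 0), and per-resolution-shell `alpha`,
#' `beta` of the amplitude likelihood. `beta` is floored at a positive value
#' in every shell.
#'
#' @param k_total,k_mask Scalars.
#' @param shells Tibble with columns `d_max,d_min,alpha,beta,n_work,n_free`
#'   (shell edges strictly decreasing in d).
#' @return Object of class `nuisance_parameters`.
#' @export
nuisance_parameters <- function(k_total = 1, k_mask = 0, shells = NULL) {
  stopifnot(k_total > 0, k_mask >= 0)
  if (is.null(shells))
    shells <- tibble::tibble(d_max = Inf, d_min = 0, alpha = 1, beta = 1,
                             n_work = NA_integer_, n_free = NA_integer_)
  stopifnot(all(shells$beta > 0), all(shells$alpha >= 0))
  structure(list(k_total = k_total, k_mask = k_mask, shells = shells),
            class = "nuisance_parameters")
}

#' @export
print.nuisance_parameters <- function(x, ...) {
  cat(sprintf("<nuisance> k_total=%.4g k_mask=%.4g, %d shells\n",
              x$k_total, x$k_mask, nrow(x$shells)))
  invisible(x)
}

#' Map reflections to resolution shells
#' @param d Resolutions of the reflections.
#' @param nuis A [nuisance_parameters()] object.
#' @return Integer shell index per reflection.
#' @keywords internal
shell_index <- function(d, nuis) {
  sh <- nuis$shells
  idx <- rep(nrow(sh), length(d))
  for (s in seq_len(nrow(sh))) idx[d <= sh$d_max[s] & d > sh$d_min[s]] <- s
  idx[d > max(sh$d_max)] <- 1L
  idx[d <= min(sh$d_min)] <- nrow(sh)
  idx
}

#' Per-reflection alpha and beta
#' @inheritParams shell_index
#' @return List with vectors `alpha`, `beta`.
#' @keywords internal
shell_alpha_beta <- function(d, nuis) {
  idx <- shell_index(d, nuis)
  list(alpha = nuis$shells$alpha[idx], beta = nuis$shells$beta[idx])
}

#' Fit nuisance parameters against observed amplitudes
#'
#' `k_total` and `k_mask` minimize the work-set least-squares residual
#' `sum (F_obs - |F_M|)^2` (with `k_mask >= 0`); `alpha` is initialized to 1
#' and `beta` per shell is the moment estimate `mean((F_obs - |F_M|)^2 /
#' epsilon)`, floored at `1e-3 * mean(F_obs^2)`. Only work reflections are
#' used, so free reflections never influence the model.
#'
#' @param refls A [reflection_set()] with observed amplitudes.
#' @param f_calc Complex protein structure factors.
#' @param f_bulk Complex bulk-solvent factors, or NULL (solvent off).
#' @param n_shells Target number of resolution shells (default 10); shells
#'   are merged until each holds at least 20 work reflections.
#' @return A [nuisance_parameters()] object.
#' @export
fit_nuisance <- function(refls, f_calc, f_bulk = NULL, n_shells = 10) {
  tab <- refls$data
  work <- !tab$free
  if (!any(work)) stop("empty work set")
  if (all(tab$f_obs[work] == 0)) stop("unscalable dataset: all-zero F_obs")
  fo <- tab$f_obs[work]
  fc <- f_calc[work]
  fb <- if (is.null(f_bulk)) NULL else f_bulk[work]

  ktot_for <- function(kmask) {
    fm <- if (is.null(fb)) fc else fc + kmask * fb
    a <- Mod(fm)
    max(sum(fo * a) / max(sum(a^2), .Machine$double.eps), .Machine$double.eps)
  }
  if (is.null(fb)) {
    k_mask <- 0
  } else {
    obj <- function(km) {
      kt <- ktot_for(km)
      sum((fo - kt * Mod(fc + km * fb))^2)
    }
    # the profile in k_mask need not be unimodal: coarse scan, then refine
    grid <- seq(0, 2, by = 0.05)
    vals <- vapply(grid, obj, 0)
    i <- which.min(vals)
    lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
    k_mask <- optimize(obj, c(lo, hi))$minimum
    if (obj(0) <= obj(k_mask)) k_mask <- 0
  }
  k_total <- ktot_for(k_mask)

  # resolution shells: equal work counts, >= 20 per shell
  n_shells <- max(1L, min(n_shells, floor(sum(work) / 20)))
  ord_d <- tab$d
  edges <- stats::quantile(ord_d[work], probs = seq(1, 0, length.out = n_shells + 1),
                           type = 7, names = FALSE)
  edges[1] <- Inf; edges[n_shells + 1] <- 0
  nuis <- nuisance_parameters(k_total, k_mask,
                              tibble::tibble(d_max = edges[-(n_shells + 1)],
                                             d_min = edges[-1],
                                             alpha = 1, beta = 1,
                                             n_work = 0L, n_free = 0L))
  amp_all <- total_amplitude(f_calc, f_bulk, nuis)$amp
  idx <- shell_index(tab$d, nuis)
  beta_floor <- 1e-3 * mean(tab$f_obs[work]^2)
  sh <- nuis$shells
  for (s in seq_len(nrow(sh))) {
    in_s <- idx == s
    sw <- in_s & work
    sh$n_work[s] <- sum(sw)
    sh$n_free[s] <- sum(in_s & !work)
    res2 <- (tab$f_obs[sw] - amp_all[sw])^2 / tab$epsilon[sw]
    sh$beta[s] <- max(mean(res2), beta_floor)
    if (!sum(sw)) sh$beta[s] <- beta_floor
  }
  nuis$shells <- sh
  nuis
}
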