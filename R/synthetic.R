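# NeRF-style internal-coordinate placement: position D bonded to C with
# given bond length, angle B-C-D and dihedral A-B-C-D (degrees).
place_atom <- function(A, B, C, bond, angle, dihedral) {
  th <- angle * pi / 180; ph <- dihedral * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  C + bond * (-cos(th) * bc + sin(th) * (cos(ph) * m + sin(ph) * n))
}

# peptide-like chain: residues of N-CA-C=O with a CB-HB side group
build_toy_chain <- function(n_residues, phi = -60, psi = -45) {
  nat <- 6 * n_residues
  X <- matrix(0, nat, 3)
  idx <- function(res, a) (res - 1) * 6 + a  # a: 1=N 2=CA 3=C 4=O 5=CB 6=HB
  X[1, ] <- c(0, 0, 0)
  X[2, ] <- c(1.455, 0, 0)
  X[3, ] <- place_atom(c(0, 1, 0), X[1, ], X[2, ], 1.522, 107, 150)
  for (r in seq_len(n_residues)) {
    iN <- idx(r, 1); iCA <- idx(r, 2); iC <- idx(r, 3)
    if (r > 1) {
      pCA <- idx(r - 1, 2); pC <- idx(r - 1, 3); pN <- idx(r - 1, 1)
      X[iN, ] <- place_atom(X[pN, ], X[pCA, ], X[pC, ], 1.345, 116.5, psi)
      X[iCA, ] <- place_atom(X[pCA, ], X[pC, ], X[iN, ], 1.455, 120, 180)
      X[iC, ] <- place_atom(X[pC, ], X[iN, ], X[iCA, ], 1.522, 107, phi)
    }
    nref <- if (r < n_residues) psi + 180 else 60
    X[idx(r, 4), ] <- place_atom(X[iN, ], X[iCA, ], X[iC, ], 1.23, 121, nref)
    X[idx(r, 5), ] <- place_atom(X[iC, ], X[iN, ], X[iCA, ], 1.538, 110, 122)
    X[idx(r, 6), ] <- place_atom(X[iN, ], X[iCA, ], X[idx(r, 5), ], 1.111, 110.1, 60)
  }
  element <- rep(c("N", "C", "C", "O", "C", "H"), n_residues)
  name <- rep(c("N", "CA", "C", "O", "CB", "HB"), n_residues)
  types <- rep(c("NB", "CA", "CC", "OC", "CB", "HB"), n_residues)
  resid <- rep(seq_len(n_residues), each = 6)
  bonds <- NULL; angles <- NULL; dihedrals <- NULL; impropers <- NULL
  for (r in seq_len(n_residues)) {
    iN <- idx(r, 1); iCA <- idx(r, 2); iC <- idx(r, 3)
    iO <- idx(r, 4); iCB <- idx(r, 5); iHB <- idx(r, 6)
    bonds <- rbind(bonds, c(iN, iCA), c(iCA, iC), c(iC, iO),
                   c(iCA, iCB), c(iCB, iHB))
    angles <- rbind(angles, c(iN, iCA, iC), c(iCA, iC, iO),
                    c(iN, iCA, iCB), c(iC, iCA, iCB), c(iCA, iCB, iHB))
    dihedrals <- rbind(dihedrals, c(iN, iCA, iC, iO), c(iN, iCA, iCB, iHB))
    if (r > 1) {
      pCA <- idx(r - 1, 2); pC <- idx(r - 1, 3); pO <- idx(r - 1, 4)
      bonds <- rbind(bonds, c(pC, iN))
      angles <- rbind(angles, c(pCA, pC, iN), c(pO, pC, iN), c(pC, iN, iCA))
      dihedrals <- rbind(dihedrals, c(pC, iN, iCA, iC),
                         c(idx(r - 1, 1), pCA, pC, iN), c(pCA, pC, iN, iCA))
      impropers <- rbind(impropers, c(pC, pCA, iN, pO))
    }
  }
  topo <- topology(types, bonds, angles, dihedrals, impropers)
  atomic_state(element, X, b = 15, occ = 1, topology = topo,
               name = name, resid = resid)
}

.default_native_weights <- function() matrix(c(0.8, 0.2, 0.3, 0.7), 2, 2)

#' Build a toy two-state native model
#'
#' A peptide-like helical chain (6 atoms per residue: backbone N-CA-C=O plus
#' a CB-HB side group) duplicated into two states. State 2 differs from
#' state 1 by a smooth seeded backbone displacement (default 0.3 Angstrom
#' RMS) and per-residue rigid side-group rotations about CA scaled to a
#' large side-chain displacement (default 1.5 Angstrom RMS) -- the small
#' backbone / large side-chain heterogeneity typical of a real crystal.
#' All B-factors are 15 and occupancies 1. The default weight matrix makes
#' state 1 dominant under condition 1 (a low-temperature-like condition)
#' and state 2 dominant under condition 2.
#'
#' @param n_residues Residues in the chain (default 16, ~100 atoms/state).
#' @param displacement_backbone Target RMS backbone displacement between
#'   states (Angstrom, default 0.3).
#' @param displacement_side Target RMS side-group displacement (Angstrom,
#'   default 1.5).
#' @param weights 2 x J weight matrix (default 2 conditions,
#'   `[0.8 0.3; 0.2 0.7]`).
#' @param padding Empty margin around the chain when boxing the P1 cell
#'   (Angstrom, default 4).
#' @param group Space-group symbol for the cell (default "P1").
#' @param seed Seed for the displacement draw.
#' @return A [multi_state_model()] with `cell` and `ops` fields attached.
#' @export
build_toy_native <- function(n_residues = 16, displacement_backbone = 0.3,
                             displacement_side = 1.5,
                             weights = .default_native_weights(),
                             padding = 4, group = "P1", seed = 1) {
  st1 <- build_toy_chain(n_residues)
  n <- nrow(st1$xyz)
  backbone <- st1$name %in% c("N", "CA", "C", "O")
  side <- !backbone
  set.seed(seed)
  # smooth per-residue backbone displacement field, rigid within a residue
  raw <- matrix(rnorm(n_residues * 3), n_residues, 3)
  sm <- apply(raw, 2, function(v) stats::filter(c(v[1], v[1], v, v[n_residues],
                                                  v[n_residues]),
                                                rep(1 / 5, 5))[3:(n_residues + 2)])
  disp_res <- matrix(sm, n_residues, 3)
  disp <- disp_res[st1$resid, ]
  disp <- disp * displacement_backbone / sqrt(mean(rowSums(disp[backbone, ]^2)))
  X2 <- st1$xyz + disp
  # per-residue rigid rotation of the CB-HB group about (displaced) CA;
  # among a fixed pool of candidate axes per residue the least-clashing
  # rotation is kept, so state 2 resembles an alternate rotamer rather
  # than a steric disaster
  n_try <- 24
  axes <- array(rnorm(n_residues * n_try * 3), c(n_residues, n_try, 3))
  base_angle <- abs(rnorm(n_residues, 1, 0.3))
  rot_about <- function(X2, scale) {
    Xr <- X2
    for (r in seq_len(n_residues)) {
      th <- min(base_angle[r] * scale, pi)
      ica <- (r - 1) * 6 + 2
      moved <- (r - 1) * 6 + 5:6
      others <- setdiff(seq_len(nrow(X2)), c(moved, ica))
      best <- NULL; best_clear <- -Inf
      for (t in seq_len(n_try)) {
        ax <- axes[r, t, ]; ax <- ax / sqrt(sum(ax^2))
        K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1],
                      -ax[2], ax[1], 0), 3, 3, byrow = TRUE)
        R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
        cand <- t(R %*% t(X2[moved, , drop = FALSE] -
                            rep(X2[ica, ], each = 2))) +
          rep(X2[ica, ], each = 2)
        clear <- min(sqrt(rowSums((Xr[others, , drop = FALSE][rep(seq_along(others), each = 2), ] -
                                     cand[rep(1:2, length(others)), ])^2)))
        if (clear > best_clear) { best_clear <- clear; best <- cand }
        if (clear > 2.2) break
      }
      Xr[moved, ] <- best
    }
    Xr
  }
  realized <- function(scale) {
    Xr <- rot_about(X2, scale)
    sqrt(mean(rowSums((Xr[side, ] - st1$xyz[side, ])^2)))
  }
  sc <- 1
  for (it in 1:10) {
    r <- realized(sc)
    if (abs(r - displacement_side) < 0.01 * displacement_side) break
    sc <- sc * displacement_side / r
  }
  X2 <- rot_about(X2, sc)
  st2 <- st1; st2$xyz <- X2
  # P1 box around both states
  allx <- rbind(st1$xyz, st2$xyz)
  span <- apply(allx, 2, range)
  shift <- -span[1, ] + padding
  st1$xyz <- sweep(st1$xyz, 2, shift, `+`)
  st2$xyz <- sweep(st2$xyz, 2, shift, `+`)
  dims <- span[2, ] - span[1, ] + 2 * padding
  model <- multi_state_model(list(st1, st2), weights)
  model$cell <- unit_cell(dims[1], dims[2], dims[3])
  model$ops <- symmetry_ops(group)
  model
}

#' Gaussian coordinate jitter of every state
#'
#' Displaces every state by a seeded Gaussian field with the exact target
#' RMS. The field is smoothed along the residue index (rigid within a
#' residue, correlated between neighbours) plus a small independent
#' per-atom component, so the perturbation moves the model without tearing
#' its covalent geometry apart.
#'
#' @param model A [multi_state_model()].
#' @param rms Target RMS per-atom displacement (Angstrom).
#' @param seed Seed.
#' @param atom_frac Fraction of the displacement variance carried by the
#'   independent per-atom component (default 0.1).
#' @return The perturbed model.
#' @export
perturb_model <- function(model, rms = 0.4, seed = 1, atom_frac = 0.1) {
  set.seed(seed)
  for (i in seq_len(n_states(model))) {
    st <- model$states[[i]]
    n <- nrow(st$xyz)
    res <- st$resid
    nres <- max(res)
    raw <- matrix(rnorm(nres * 3), nres, 3)
    sm <- apply(raw, 2, function(v)
      stats::filter(c(v[1], v[1], v, v[nres], v[nres]), rep(1 / 5, 5))[3:(nres + 2)])
    d <- matrix(sm, nres, 3)[res, , drop = FALSE] * sqrt(1 - atom_frac) +
      matrix(rnorm(n * 3), n, 3) * sqrt(atom_frac)
    d <- d * rms / sqrt(mean(rowSums(d^2)))
    model$states[[i]]$xyz <- st$xyz + d
  }
  model
}

#' Simulate noisy multi-condition amplitude datasets from a native
#'
#' Enumerates the complete unique reflection list to `d_min` (default 2.0
#' Angstrom), computes noiseless amplitudes through the forward model with
#' the native's weight column for each condition (`k_total = 1`, solvent
#' off), adds independent Gaussian noise with standard deviation
#' `sigma * amplitude` (relative noise; negative results are clamped to 0),
#' records the sigma column, and assigns one shared free set across all
#' conditions.
#'
#' @param native A [multi_state_model()] with `cell`/`ops` (see
#'   [build_toy_native()]).
#' @param d_min Resolution limit in Angstrom (default 2.0).
#' @param sigma Relative noise level (default 0.05, i.e. 5 percent).
#' @param free A [free_set_spec()].
#' @param seed Seed for the noise draw.
#' @return List of J [reflection_set()]s with identical free flags.
#' @export
simulate_datasets <- function(native, d_min = 2.0, sigma = 0.05,
                              free = free_set_spec(), seed = 1) {
  stopifnot(!is.null(native$cell), !is.null(native$ops))
  hkl <- generate_hkl(native$cell, native$ops, d_min)
  base <- reflection_set(data.frame(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                                    f_obs = 1, sigma = 0),
                         native$cell, native$ops)
  f_states <- vapply(native$states, single_state_sf,
                     complex(nrow(base$data)), refls = base)
  f_states <- matrix(f_states, ncol = n_states(native))
  set.seed(seed)
  out <- lapply(seq_len(n_conditions(native)), function(j) {
    f_true <- Mod(multi_state_sf(f_states, native$weights[, j]))
    noise <- rnorm(length(f_true), 0, sigma * f_true)
    rs <- base
    rs$data$f_obs <- pmax(f_true + noise, 0)
    rs$data$sigma <- sigma * f_true
    rs$condition_id <- paste0("cond", j)
    rs
  })
  assign_free_flags(out, free)
}

# short prior-only Langevin burst used by the decoy generator
prior_burst <- function(model, rp, steps, temperature, friction, seed) {
  set.seed(seed)
  mass <- element_mass(model$states[[1]]$element)
  dt <- 1
  gam <- friction / 1000
  c1 <- exp(-gam * dt); c2 <- sqrt(1 - c1^2)
  sig_v <- sqrt(KB_KCAL * temperature / mass * KCAL_PER_MOL_TO_AKMA)
  xyz <- lapply(model$states, `[[`, "xyz")
  N <- length(xyz); natom <- nrow(xyz[[1]])
  vel <- lapply(seq_len(N), function(i) matrix(rnorm(natom * 3), natom, 3) * sig_v)
  snaps <- list()
  f <- lapply(seq_len(N), function(i) {
    s <- model$states[[i]]; s$xyz <- xyz[[i]]
    -potential_energy(s, rp)$gradient
  })
  for (step in seq_len(steps)) {
    for (i in seq_len(N)) {
      acc <- f[[i]] / mass * KCAL_PER_MOL_TO_AKMA
      vel[[i]] <- vel[[i]] + 0.5 * dt * acc
      xyz[[i]] <- xyz[[i]] + 0.5 * dt * vel[[i]]
      vel[[i]] <- c1 * vel[[i]] + c2 * sig_v * matrix(rnorm(natom * 3), natom, 3)
      xyz[[i]] <- xyz[[i]] + 0.5 * dt * vel[[i]]
    }
    for (i in seq_len(N)) {
      s <- model$states[[i]]; s$xyz <- xyz[[i]]
      f[[i]] <- -potential_energy(s, rp)$gradient
      vel[[i]] <- vel[[i]] + 0.5 * dt * f[[i]] / mass * KCAL_PER_MOL_TO_AKMA
    }
    if (step %% 5 == 0) snaps[[length(snaps) + 1]] <- xyz
  }
  snaps
}

#' Generate decoy models around a native
#'
#' Conformation decoys come from short prior-only dynamics bursts started
#' at the native (weights kept native), binned by their RMSD* to the native
#' and sampled to approximately uniform coverage of the requested accuracy
#' range. The `"weights"` variant keeps the native conformations and draws
#' flat-Dirichlet weight matrices instead; `"both"` mixes the two.
#'
#' @param native A [multi_state_model()].
#' @param datasets Unused by the generator itself (kept for interface
#'   symmetry with the landscape analysis); may be NULL.
#' @param n_decoys Number of decoys to return.
#' @param accuracy_range RMSD* range to span (Angstrom, default c(0, 1)).
#' @param mode `"conformations"` (default), `"weights"`, or `"both"`.
#' @param prior Force field for the dynamics bursts.
#' @param n_bins Accuracy bins for uniform coverage.
#' @param seed Seed.
#' @return List of [multi_state_model()]s with attribute `accuracy` (their
#'   RMSD* to the native).
#' @export
generate_decoys <- function(native, datasets = NULL, n_decoys = 200,
                            accuracy_range = c(0, 1),
                            mode = c("conformations", "weights", "both"),
                            prior = toy_forcefield(), n_bins = 10, seed = 1) {
  mode <- match.arg(mode)
  if (n_decoys == 1 && diff(accuracy_range) == 0 && accuracy_range[1] == 0) {
    out <- list(native); attr(out, "accuracy") <- 0
    return(out)
  }
  if (mode == "weights") {
    set.seed(seed)
    out <- lapply(seq_len(n_decoys), function(k) {
      m <- native
      m$weights <- sample_weight_matrix(n_states(native), n_conditions(native))
      m
    })
    attr(out, "accuracy") <- vapply(out, rmsd_star, 0, b = native)
    return(out)
  }
  if (mode == "both") {
    half <- n_decoys %/% 2
    a <- generate_decoys(native, datasets, n_decoys - half, accuracy_range,
                         "conformations", prior, n_bins, seed)
    b <- generate_decoys(native, datasets, half, accuracy_range, "weights",
                         prior, n_bins, seed + 1)
    out <- c(a, b)
    attr(out, "accuracy") <- c(attr(a, "accuracy"), attr(b, "accuracy"))
    return(out)
  }
  rp <- resolve_forcefield(native$states[[1]]$topology, prior)
  lo <- accuracy_range[1]; hi <- accuracy_range[2]
  edges <- seq(lo, hi, length.out = n_bins + 1)
  pool <- vector("list", n_bins)
  target_per_bin <- ceiling(n_decoys / n_bins)
  set.seed(seed)
  burst_seeds <- sample.int(1e8, 40 * n_bins)
  bi <- 0
  while (bi < length(burst_seeds) &&
         any(vapply(pool, length, 0L) < 2 * target_per_bin)) {
    bi <- bi + 1
    steps <- sample(20:160, 1)
    temp <- stats::runif(1, 1000, 5000)
    snaps <- prior_burst(native, rp, steps, temp, friction = 5,
                         seed = burst_seeds[bi])
    for (s in snaps) {
      m <- set_coordinates(native, s)
      acc <- rmsd_star(m, native)
      if (acc >= lo && acc <= hi) {
        b <- min(max(findInterval(acc, edges, all.inside = TRUE), 1), n_bins)
        pool[[b]] <- c(pool[[b]], list(list(m = m, acc = acc)))
      }
    }
  }
  counts <- vapply(pool, length, 0L)
  short <- which(counts < floor(n_decoys / n_bins))
  if (length(short))
    warning("insufficient decoys in accuracy bin(s): ",
            paste(sprintf("[%.2f,%.2f]", edges[short], edges[short + 1]),
                  collapse = ", "))
  out <- list(); accs <- numeric()
  k <- 0
  while (length(out) < n_decoys && any(vapply(pool, length, 0L) > 0)) {
    k <- k %% n_bins + 1
    if (length(pool[[k]])) {
      pick <- sample.int(length(pool[[k]]), 1)
      out <- c(out, list(pool[[k]][[pick]]$m))
      accs <- c(accs, pool[[k]][[pick]]$acc)
      pool[[k]][[pick]] <- NULL
    }
  }
  attr(out, "accuracy") <- accs
  out
}
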