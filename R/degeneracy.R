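#' Finite-crystal scattering degeneracy experiment
#'
#' Builds finite crystals of n x n x n unit cells from two single-cell
#' density templates (state 1, state 2) under five cell-assignment
#' configurations and measures how fast their Bragg amplitudes converge to
#' the infinite-crystal weighted sum:
#'
#' 1. per-cell Bernoulli assignment (state 1 with probability w1);
#' 2. two contiguous blocks with cell fractions w1 / w2;
#' 3. every cell a w1/w2 occupancy-weighted mixture (the reference --
#'    identical to the weighted sum by linearity, so its error is exactly 0);
#' 4. configuration 1 with the state labels swapped (statistically the same
#'    crystal sampled with the complementary draw);
#' 5. per-cell, per-atom independent assignment with expected proportions
#'    w1 / w2.
#'
#' The crystal DFT restricted to the single-cell reciprocal lattice equals
#' the DFT of the cell-folded (summed) density, which is what is computed;
#' the per-point error is `|F - F_ref| / |F_ref|`, averaged over lattice
#' points within `|h|,|k|,|l| <= hmax` and over `n_rep` independent crystal
#' realizations.
#'
#' @param state1,state2 [atomic_state()]s giving the two single-cell
#'   templates (defaults: a built-in 3-atom toy whose state 2 is displaced
#'   by ~0.5 Angstrom per atom).
#' @param cell Unit cell (default cubic 10 Angstrom).
#' @param weights Length-2 state weights `(w1, w2)`, summing to 1.
#' @param n_cells Crystal sizes in cells per axis (default c(2, 3, 4, 6, 8)).
#' @param grid Grid divisions per cell axis (default 32).
#' @param hmax Largest Miller index retained per axis (default 4).
#' @param blob_b Gaussian width of the atom blobs as a B-factor (Angstrom^2,
#'   default 20).
#' @param n_rep Independent crystal realizations averaged per configuration
#'   and size (default 8).
#' @param configs Which configurations to run (default 1:5).
#' @param coherent_blocks Model configuration 2 as two blocks in one
#'   coherent volume (default). `FALSE` treats them as two separate
#'   crystals whose intensities add incoherently.
#' @param seed Seed for the random assignments.
#' @return Tibble of class `degeneracy_result` with columns
#'   `config, n, error`.
#' @export
degeneracy_experiment <- function(state1 = NULL, state2 = NULL,
                                  cell = unit_cell(10, 10, 10),
                                  weights = c(0.6, 0.4),
                                  n_cells = c(2, 3, 4, 6, 8), grid = 32,
                                  hmax = 4, blob_b = 20, n_rep = 8,
                                  configs = 1:5, coherent_blocks = TRUE,
                                  seed = 1) {
  stopifnot(abs(sum(weights) - 1) < 1e-9, all(n_cells >= 1))
  if (is.null(state1) || is.null(state2)) {
    p1 <- rbind(c(3.0, 3.2, 5.0), c(5.2, 6.0, 4.4), c(6.8, 4.0, 6.1))
    d <- rbind(c(0.35, -0.25, 0.2), c(-0.3, 0.3, 0.25), c(0.2, 0.3, -0.35))
    el <- c("C", "N", "O")
    state1 <- atomic_state(el, p1)
    state2 <- atomic_state(el, p1 + d)
  }
  if (!identical(state1$element, state2$element))
    stop("templates must share composition")
  ng <- as.integer(grid)
  if (ng < 2 * hmax + 2) stop("grid incompatible with hmax: need grid >= 2*hmax+2")
  M <- orthogonalization_matrix(cell)
  fr <- (seq_len(ng) - 1) / ng
  gridf <- as.matrix(expand.grid(x = fr, y = fr, z = fr))
  sigma2 <- blob_b / (8 * pi^2)
  zval <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16, Zn = 30)
  atom_template <- function(xyz_cart, el) {
    xf <- as.vector(solve(M) %*% xyz_cart)
    d <- sweep(gridf, 2, xf)
    d <- d - round(d)
    dc <- d %*% t(M)
    array(zval[[el]] * exp(-rowSums(dc^2) / (2 * sigma2)), dim = c(ng, ng, ng))
  }
  natom <- nrow(state1$xyz)
  T1a <- lapply(seq_len(natom), function(a) atom_template(state1$xyz[a, ], state1$element[a]))
  T2a <- lapply(seq_len(natom), function(a) atom_template(state2$xyz[a, ], state2$element[a]))
  T1 <- Reduce(`+`, T1a); T2 <- Reduce(`+`, T2a)
  take_F <- function(rho) {
    Fg <- fft(rho, inverse = TRUE) * (cell$volume / ng^3)
    hs <- -hmax:hmax
    idx <- as.matrix(expand.grid(h = hs, k = hs, l = hs))
    Fg[(idx %% ng) + 1]
  }
  F_ref <- take_F(weights[1] * T1 + weights[2] * T2)
  keep <- Mod(F_ref) > 1e-10 * max(Mod(F_ref))
  err_of <- function(rho) {
    Fv <- take_F(rho)
    mean(Mod(Fv - F_ref)[keep] / Mod(F_ref)[keep])
  }
  set.seed(seed)
  rows <- list()
  for (n in n_cells) {
    ncell <- n^3
    for (cfg in configs) {
      reps <- if (cfg %in% c(2, 3)) 1L else n_rep
      errs <- vapply(seq_len(reps), function(rep) {
        rho <- switch(as.character(cfg),
          "1" = {
            c1 <- stats::rbinom(1, ncell, weights[1])
            (c1 * T1 + (ncell - c1) * T2) / ncell
          },
          "2" = {
            # two contiguous blocks inside one coherent volume; at the
            # single-cell lattice points only the cell counts matter
            c1 <- round(weights[1] * ncell)
            if (coherent_blocks) {
              (c1 * T1 + (ncell - c1) * T2) / ncell
            } else {
              # incoherent variant: two separate crystals, intensities add
              F1 <- take_F(T1); F2 <- take_F(T2)
              amp <- sqrt((c1 / ncell)^2 * Mod(F1)^2 +
                          ((ncell - c1) / ncell)^2 * Mod(F2)^2)
              return(mean(abs(amp - Mod(F_ref))[keep] / Mod(F_ref)[keep]))
            }
          },
          "3" = weights[1] * T1 + weights[2] * T2,
          "4" = {
            c2 <- stats::rbinom(1, ncell, weights[2])
            ((ncell - c2) * T1 + c2 * T2) / ncell
          },
          "5" = {
            acc <- 0
            for (a in seq_len(natom)) {
              c1a <- stats::rbinom(1, ncell, weights[1])
              acc <- acc + c1a * T1a[[a]] + (ncell - c1a) * T2a[[a]]
            }
            acc / ncell
          },
          stop("unknown configuration ", cfg))
        err_of(rho)
      }, 0)
      rows[[length(rows) + 1]] <- tibble::tibble(config = cfg, n = n,
                                                 error = mean(errs))
    }
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("degeneracy_result", class(out)),
            weights = weights)
}
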