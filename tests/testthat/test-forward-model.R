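test_that("form factors reproduce electron counts and decay", {
  expect_equal(form_factor("C", 0), 6, tolerance = 0.05)
  expect_equal(form_factor("O", 0), 8, tolerance = 0.05)
  # independent arithmetic on the published coefficients
  tab <- msxtal:::form_factor_env$table["C", ]
  s2 <- 0.25^2
  expected <- sum(tab[1:4] * exp(-tab[5:8] * s2)) + tab[9]
  expect_equal(form_factor("C", 0.25), unname(expected), tolerance = 1e-12)
  for (el in c("C", "N", "O")) {
    f <- form_factor(el, seq(0, 0.6, by = 0.02))
    expect_true(all(diff(f) < 0))
    expect_true(all(f > 0))
  }
  expect_error(form_factor("Xx", 0.1), "Xx")
})

test_that("single-state structure factors obey point-scatterer and shift laws", {
  cell <- unit_cell(10, 10, 10)
  refl <- reflection_set(
    data.frame(h = c(1, 2, 3), k = c(0, 1, 0), l = c(0, 0, 2),
               f_obs = 1, sigma = 0), cell)
  st <- atomic_state("C", matrix(0, 1, 3), b = 0)
  F <- single_state_sf(st, refl)
  expect_equal(Im(F), rep(0, 3), tolerance = 1e-12)
  expect_equal(Re(F), form_factor("C", 1 / (2 * refl$data$d)), tolerance = 1e-10)

  # Fourier shift theorem: translation multiplies by exp(2 pi i h.t)
  set.seed(4)
  st2 <- atomic_state(c("C", "N", "O"), matrix(runif(9, 0, 9), 3, 3), b = 12)
  F0 <- single_state_sf(st2, refl)
  tshift <- c(0.21, -0.13, 0.37)  # fractional
  st3 <- st2
  st3$xyz <- st2$xyz + matrix(10 * tshift, 3, 3, byrow = TRUE)
  F1 <- single_state_sf(st3, refl)
  H <- as.matrix(refl$data[, c("h", "k", "l")])
  expect_equal(Mod(F1), Mod(F0), tolerance = 1e-10)
  expect_equal(F1, F0 * exp(2i * pi * as.vector(H %*% tshift)), tolerance = 1e-10)
})

test_that("direct summation matches a gridded-density DFT oracle", {
  # B-smeared gaussian density sampled on a fine grid, transformed with fft:
  # an independent route to the same amplitudes
  set.seed(9)
  cell <- unit_cell(12, 12, 12)
  n_atoms <- 8
  st <- atomic_state(sample(c("C", "N", "O"), n_atoms, replace = TRUE),
                     matrix(runif(n_atoms * 3, 2, 10), n_atoms, 3), b = 20)
  refl <- reflection_set(
    as.data.frame(cbind(generate_hkl(cell, symmetry_ops("P1"), 3.0),
                        f_obs = 1, sigma = 0)), cell)
  F_direct <- single_state_sf(st, refl)

  ng <- 48
  fr <- (seq_len(ng) - 1) / ng * 12
  gridc <- as.matrix(expand.grid(x = fr, y = fr, z = fr))
  rho <- 0
  for (a in seq_len(n_atoms)) {
    d <- sweep(gridc, 2, st$xyz[a, ])
    d <- d - 12 * round(d / 12)
    # 3-D fourier pair of the atom: f(s) exp(-B s^2) <-> sum of gaussians;
    # build the density as the inverse transform of the 4-gaussian model
    tab <- msxtal:::form_factor_env$table[st$element[a], ]
    r2 <- rowSums(d^2)
    for (gi in 1:4) {
      Bi <- tab[[paste0("b", gi)]] + 20  # coefficient b + atomic B
      rho <- rho + tab[[paste0("a", gi)]] * (4 * pi / Bi)^1.5 *
        exp(-4 * pi^2 * r2 / Bi)
    }
    Bc <- 20
    rho <- rho + tab[["c"]] * (4 * pi / Bc)^1.5 * exp(-4 * pi^2 * r2 / Bc)
  }
  Fg <- fft(array(rho, c(ng, ng, ng)), inverse = TRUE) * (12 / ng)^3
  H <- as.matrix(refl$data[, c("h", "k", "l")])
  F_oracle <- Fg[cbind(H[, 1] %% ng, H[, 2] %% ng, H[, 3] %% ng) + 1]
  rel <- Mod(F_direct - F_oracle) / Mod(F_oracle)
  expect_lt(mean(rel), 0.005)
})

test_that("multi-state sum is the exact weighted complex combination", {
  study <- tiny_study()
  refl <- study$datasets[[1]]
  F1 <- single_state_sf(study$native$states[[1]], refl)
  F2 <- single_state_sf(study$native$states[[2]], refl)
  expect_equal(multi_state_sf(cbind(F1), 1), F1)
  expect_equal(multi_state_sf(cbind(F1, F1), c(0.3, 0.7)), F1, tolerance = 1e-12)
  expect_equal(multi_state_sf(cbind(F1, F2), c(0.7, 0.3)),
               0.7 * F1 + 0.3 * F2, tolerance = 1e-14)
  expect_error(multi_state_sf(cbind(F1, F2), c(1)), "does not match")
  expect_error(multi_state_sf(cbind(F1, F2), c(0.7, 0.6)), "sum to 1")
})

test_that("partial-occupancy single state equals the weighted two-state sum", {
  # the scattering degeneracy that justifies the multi-state forward model:
  # one cell holding both conformations at occupancies (w1, w2) gives
  # bit-identical amplitudes to the weighted sum of the two pure states
  study <- tiny_study()
  refl <- study$datasets[[1]]
  s1 <- study$native$states[[1]]; s2 <- study$native$states[[2]]
  w <- c(0.62, 0.38)
  merged <- atomic_state(c(s1$element, s2$element), rbind(s1$xyz, s2$xyz),
                         b = c(s1$b, s2$b), occ = c(w[1] * s1$occ, w[2] * s2$occ))
  F_merged <- single_state_sf(merged, refl)
  F_sum <- multi_state_sf(cbind(single_state_sf(s1, refl),
                                single_state_sf(s2, refl)), w)
  expect_rel_equal(F_merged, F_sum, 1e-12)
})

test_that("Friedel symmetry holds without anomalous terms", {
  cell <- unit_cell(11, 9, 13)
  set.seed(2)
  st <- atomic_state(c("C", "N", "O", "S"), matrix(runif(12, 0, 9), 4, 3), b = 15)
  hkl <- rbind(c(1, 2, 3), c(-2, 1, 4), c(3, -1, -2))
  colnames(hkl) <- c("h", "k", "l")
  refl_p <- reflection_set(as.data.frame(cbind(hkl, f_obs = 1, sigma = 0)), cell)
  refl_m <- reflection_set(as.data.frame(cbind(-hkl, f_obs = 1, sigma = 0)), cell)
  expect_equal(Mod(single_state_sf(st, refl_p)),
               Mod(single_state_sf(st, refl_m)), tolerance = 1e-12)
})

test_that("total amplitude composes scales and solvent", {
  f_c <- complex(real = c(3, -1), imaginary = c(4, 2))
  nuis <- nuisance_parameters(k_total = 1, k_mask = 0)
  expect_equal(total_amplitude(f_c, NULL, nuis)$amp, Mod(f_c))
  nuis2 <- nuisance_parameters(k_total = 2, k_mask = 0)
  expect_equal(total_amplitude(f_c, NULL, nuis2)$amp, 2 * Mod(f_c))
  nuis3 <- nuisance_parameters(k_total = 1, k_mask = 1)
  expect_equal(total_amplitude(f_c, -f_c, nuis3)$amp, c(0, 0))
})

test_that("bulk solvent mask behaves at the extremes", {
  study <- tiny_study()
  refl <- study$datasets[[1]]
  empty <- bulk_solvent_sf(list(), NULL, refl)
  expect_equal(empty$volume_fraction, 1)
  expect_lt(max(Mod(empty$f_bulk)), 1e-6 * refl$cell$volume)

  # single-atom cell: volume fraction vs an independent voxel count
  cell <- unit_cell(10, 10, 10)
  hkl <- generate_hkl(cell, symmetry_ops("P1"), 2.5)
  rs <- reflection_set(as.data.frame(cbind(hkl, f_obs = 1, sigma = 0)), cell)
  st <- atomic_state("C", matrix(5, 1, 3))
  bs <- bulk_solvent_sf(list(st), 1, rs, probe = 1.1, shrink = 0.9)
  ng <- ceiling(10 / (2.5 / 4))
  fr <- (seq_len(ng) - 1) / ng * 10
  g <- as.matrix(expand.grid(fr, fr, fr))
  d <- sweep(g, 2, c(5, 5, 5)); d <- d - 10 * round(d / 10)
  excl <- 1.70 + 1.1 - 0.9
  frac_oracle <- mean(sqrt(rowSums(d^2)) > excl)
  expect_equal(bs$volume_fraction, frac_oracle, tolerance = 1e-12)
  expect_error(bulk_solvent_sf(list(st), 1, rs, spacing = 2), "too coarse")
})

test_that("nuisance fitting recovers exact scale and respects the work set", {
  study <- tiny_study()
  refl <- study$datasets[[1]]
  f_c <- single_state_sf(study$native$states[[1]], refl)
  refl$data$f_obs <- 3 * Mod(f_c)
  nuis <- fit_nuisance(refl, f_c)
  expect_equal(nuis$k_total, 3, tolerance = 1e-9)
  expect_equal(nuis$k_mask, 0)
  # zero residuals -> beta clamped at the floor, not zero
  floor_expected <- 1e-3 * mean(refl$data$f_obs[!refl$data$free]^2)
  expect_true(all(nuis$shells$beta >= floor_expected - 1e-12))
  expect_true(all(diff(nuis$shells$d_max) < 0))

  refl$data$f_obs[1] <- 0
  refl$data$f_obs[-1] <- 0
  expect_error(fit_nuisance(refl, f_c), "unscalable")
})

test_that("k_total/k_mask match a 2-D grid-search oracle with solvent on", {
  cell <- unit_cell(12, 12, 12)
  hkl <- generate_hkl(cell, symmetry_ops("P1"), 3.4)
  rs <- reflection_set(as.data.frame(cbind(hkl, f_obs = 1, sigma = 0)), cell)
  set.seed(5)
  st <- atomic_state(rep(c("C", "N"), 3), matrix(runif(18, 3, 9), 6, 3), b = 15)
  f_c <- single_state_sf(st, rs)
  f_b <- bulk_solvent_sf(list(st), 1, rs)$f_bulk
  truth <- nuisance_parameters(k_total = 1.7, k_mask = 0.4)
  rs$data$f_obs <- total_amplitude(f_c, f_b, truth)$amp
  fit <- fit_nuisance(rs, f_c, f_b)
  grid_obj <- function(kt, km) sum((rs$data$f_obs[!rs$data$free] -
    kt * Mod(f_c + km * f_b)[!rs$data$free])^2)
  kts <- seq(1.5, 1.9, by = 0.004); kms <- seq(0.2, 0.6, by = 0.004)
  vals <- outer(kts, kms, Vectorize(grid_obj))
  best <- arrayInd(which.min(vals), dim(vals))
  expect_equal(fit$k_total, kts[best[1]], tolerance = 0.01)
  expect_equal(fit$k_mask, kms[best[2]], tolerance = 0.01)
})

test_that("scale invariance: rescaled data move k_total, not R factors", {
  study <- tiny_study(sigma = 0.05)
  refl <- study$datasets[[1]]
  msf1 <- model_structure_factors(study$native, refl, condition = 1)
  r1 <- model_r_factors(study$native, list(refl))
  refl2 <- refl
  refl2$data$f_obs <- 7 * refl2$data$f_obs
  msf2 <- model_structure_factors(study$native, refl2, condition = 1)
  r2 <- model_r_factors(study$native, list(refl2))
  expect_equal(msf2$nuisance$k_total, 7 * msf1$nuisance$k_total,
               tolerance = 1e-9)
  expect_equal(r2$rwork, r1$rwork, tolerance = 1e-9)
  expect_equal(r2$rfree, r1$rfree, tolerance = 1e-9)
})

test_that("coordinate gradients match finite differences and weight linearity", {
  study <- tiny_study(sigma = 0.05)
  refl <- study$datasets[[1]]
  model <- study$native
  msf <- model_structure_factors(model, refl, condition = 1)
  qw <- quadratic_gradient_weights(refl, msf)
  G <- amplitude_coordinate_gradients(model, refl, msf, qw$gradient)
  nuis <- msf$nuisance
  target <- function(m) {
    msf2 <- model_structure_factors(m, refl, condition = 1, nuis = nuis)
    dataset_neg_log_likelihood(refl, msf2)
  }
  set.seed(3)
  for (istate in 1:2) for (pick in sample(nrow(model$states[[1]]$xyz), 3)) {
    for (d in 1:3) {
      h <- 1e-4
      mp <- model; mp$states[[istate]]$xyz[pick, d] <- mp$states[[istate]]$xyz[pick, d] + h
      mm <- model; mm$states[[istate]]$xyz[pick, d] <- mm$states[[istate]]$xyz[pick, d] - h
      fd <- (target(mp) - target(mm)) / (2 * h)
      expect_equal(G[[istate]][pick, d], fd, tolerance = 1e-4)
    }
  }
  # a state with zero weight under the condition feels no X-ray force
  m0 <- model
  m0$weights <- weight_matrix(matrix(c(1, 0, 0, 1), 2, 2))
  msf0 <- model_structure_factors(m0, refl, condition = 1)
  G0 <- amplitude_coordinate_gradients(m0, refl, msf0,
                                       quadratic_gradient_weights(refl, msf0)$gradient)
  expect_equal(G0[[2]], matrix(0, nrow(m0$states[[2]]$xyz), 3))
  # stationarity: zero per-reflection weights give a zero gradient
  Gz <- amplitude_coordinate_gradients(model, refl, msf, rep(0, nrow(refl$data)))
  expect_equal(max(abs(unlist(Gz))), 0)
})
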