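test_that("w_auto equalizes average gradient magnitudes", {
  g1 <- list(matrix(1, 4, 3))
  expect_equal(compute_wauto(g1, g1), 1)
  expect_equal(compute_wauto(lapply(g1, `/`, 2), g1), 2)
  set.seed(12)
  lik <- list(matrix(rnorm(30), 10, 3), matrix(rnorm(30), 10, 3))
  pri <- list(matrix(rnorm(30, 2), 10, 3), matrix(rnorm(30, 2), 10, 3))
  w <- compute_wauto(lik, pri)
  # independent two-pass recomputation
  mags <- function(gl) mean(c(sqrt(rowSums(gl[[1]]^2)), sqrt(rowSums(gl[[2]]^2))))
  expect_equal(w, mags(pri) / mags(lik), tolerance = 1e-12)
  # post-scaling contract: the two averages agree to 1e-10 relative
  expect_rel_equal(mags(lapply(lik, `*`, w)), mags(pri), 1e-10)
  expect_warning(w0 <- compute_wauto(list(matrix(0, 4, 3)), g1), "clamped")
  expect_equal(w0, 1e6)
})

test_that("flat-Dirichlet weight draws have simplex geometry and uniform means", {
  set.seed(31)
  expect_equal(sample_weight_matrix(1, 3)[1, ], c(1, 1, 1))
  draws <- replicate(1e4, sample_weight_matrix(3, 1)[, 1])
  expect_true(all(draws >= 0))
  expect_true(all(abs(colSums(draws) - 1) < 1e-12))
  se <- sqrt(1 / 3 * 2 / 3 / (3 + 1)) / sqrt(1e4)  # Dirichlet(1,1,1) moments
  expect_true(all(abs(rowMeans(draws) - 1 / 3) < 3 * se + 1e-3))
})

test_that("biased force is the weighted sum of score gradients", {
  study <- tiny_study(sigma = 0.05)
  model <- study$native
  f0 <- biased_force(model, study$datasets, study$ff, w_xray = 0, w_auto = 1)
  pri <- lapply(model$states, function(s) -potential_energy(s, study$ff)$gradient)
  expect_equal(f0, pri, tolerance = 1e-9)
  # affine in w_xray
  f1 <- biased_force(model, study$datasets, study$ff, w_xray = 1, w_auto = 2)
  f2 <- biased_force(model, study$datasets, study$ff, w_xray = 2, w_auto = 2)
  f3 <- biased_force(model, study$datasets, study$ff, w_xray = 3, w_auto = 2)
  expect_equal(f3[[1]] - f2[[1]], f2[[1]] - f1[[1]], tolerance = 1e-8)
  # matches the finite-difference gradient of w_xray*w_auto*(-logL) + E
  wx <- 0.5; wa <- 1.7
  nuis1 <- model_structure_factors(model, study$datasets[[1]], 1)$nuisance
  nuis2 <- model_structure_factors(model, study$datasets[[2]], 2)$nuisance
  fb <- biased_force(model, study$datasets, study$ff, wx, wa)
  weighted_score <- function(m) {
    jl <- joint_neg_log_likelihood(m, study$datasets,
                                   nuis_list = list(nuis1, nuis2))
    wx * wa * jl$total +
      sum(vapply(m$states, function(s) potential_energy(s, study$ff)$energy, 0))
  }
  set.seed(8)
  for (pick in sample(nrow(model$states[[1]]$xyz), 2)) {
    h <- 1e-4
    mp <- model; mp$states[[1]]$xyz[pick, 1] <- mp$states[[1]]$xyz[pick, 1] + h
    mm <- model; mm$states[[1]]$xyz[pick, 1] <- mm$states[[1]]$xyz[pick, 1] - h
    fd <- (weighted_score(mp) - weighted_score(mm)) / (2 * h)
    expect_equal(fb[[1]][pick, 1], -fd,
                 tolerance = 1e-5 * max(1, abs(fd)))
  }
})

test_that("trajectories are deterministic, recorded, and truncate on blow-up", {
  study <- tiny_study(sigma = 0.05)
  start <- perturb_model(study$native, 0.3, seed = 2)
  cfg <- sampler_config(steps = 30, macro_cycle = 15, seed = 42,
                        temperature = 2000)
  t1 <- run_trajectory(start, study$datasets, study$ff, cfg, w_xray = 1)
  t2 <- run_trajectory(start, study$datasets, study$ff, cfg, w_xray = 1)
  expect_identical(t1[[length(t1)]]$model$states[[1]]$xyz,
                   t2[[length(t2)]]$model$states[[1]]$xyz)
  expect_identical(t1[[length(t1)]]$model$weights,
                   t2[[length(t2)]]$model$weights)
  expect_equal(vapply(t1, `[[`, 0L, "step"), c(0L, 15L, 30L))
  # weight snapshots keep column normalization
  for (r in t1) expect_equal(colSums(r$model$weights), c(1, 1), tolerance = 1e-12)
  # zero steps: only the initial record
  t0 <- run_trajectory(start, study$datasets, study$ff,
                       sampler_config(steps = 0, seed = 1))
  expect_length(t0, 1)
  expect_equal(t0[[1]]$step, 0L)
})

test_that("state relabeling with permuted per-state seeds permutes the trajectory", {
  study <- tiny_study(sigma = 0.05)
  start <- perturb_model(study$native, 0.2, seed = 5)
  seeds <- c(101L, 202L)
  W <- start$weights
  cfg_a <- sampler_config(steps = 20, macro_cycle = 10, seed = 9,
                          state_seeds = seeds)
  ta <- run_trajectory(start, study$datasets, study$ff, cfg_a, w_xray = 1,
                       weights = W)
  perm <- multi_state_model(start$states[c(2, 1)], weight_matrix(W[c(2, 1), ]))
  perm$cell <- start$cell; perm$ops <- start$ops
  cfg_b <- sampler_config(steps = 20, macro_cycle = 10, seed = 9,
                          state_seeds = seeds[c(2, 1)])
  tb <- run_trajectory(perm, study$datasets, study$ff, cfg_b, w_xray = 1,
                       weights = weight_matrix(W[c(2, 1), ]))
  expect_equal(ta[[length(ta)]]$model$states[[1]]$xyz,
               tb[[length(tb)]]$model$states[[2]]$xyz, tolerance = 1e-12)
  expect_equal(ta[[length(ta)]]$model$states[[2]]$xyz,
               tb[[length(tb)]]$model$states[[1]]$xyz, tolerance = 1e-12)
})

test_that("frictionless unbiased dynamics conserve energy on a diatomic", {
  ff <- toy_forcefield()
  topo <- topology(c("CA", "CB"), bonds = c(1, 2))
  st <- atomic_state(c("C", "C"), rbind(c(0, 0, 0), c(1.7, 0, 0)),
                     topology = topo)
  rp <- resolve_forcefield(topo, ff)
  mass <- element_mass(st$element)
  dt <- 0.25
  xyz <- st$xyz
  vel <- matrix(0, 2, 3)
  conv <- msxtal:::KCAL_PER_MOL_TO_AKMA
  etot <- function(xyz, vel) {
    s <- st; s$xyz <- xyz
    potential_energy(s, rp)$energy + sum(0.5 * mass * rowSums(vel^2)) / conv
  }
  e0 <- etot(xyz, vel)
  f <- -potential_energy(st, rp)$gradient
  for (k in 1:400) {   # velocity Verlet = BAOAB with zero friction
    vel <- vel + 0.5 * dt * f / mass * conv
    xyz <- xyz + dt * vel
    s <- st; s$xyz <- xyz
    f <- -potential_energy(s, rp)$gradient
    vel <- vel + 0.5 * dt * f / mass * conv
  }
  drift <- abs(etot(xyz, vel) - e0) / abs(e0)
  expect_lt(drift, 0.02)
})

test_that("conjugate-gradient polish descends to analytic minima", {
  # single harmonic bond plus data simulated at equilibrium: the joint
  # objective's minimum is the equilibrium geometry
  ff <- toy_forcefield()
  topo <- topology(c("CA", "CB"), bonds = c(1, 2))
  eq <- atomic_state(c("C", "C"), rbind(c(4, 5, 5), c(4 + 1.538, 5, 5)),
                     topology = topo)
  model_eq <- multi_state_model(list(eq), matrix(1, 1, 1))
  cell <- unit_cell(10, 10, 10)
  model_eq$cell <- cell; model_eq$ops <- symmetry_ops("P1")
  ds <- simulate_datasets(model_eq, d_min = 2.5, sigma = 0,
                          free = free_set_spec(0), seed = 1)
  stretched <- model_eq
  stretched$states[[1]]$xyz[2, 1] <- 4 + 2.1
  cfg <- sampler_config(cg_max_iter = 200, cg_tol = 1e-5)
  # fixed, correct scaling with a tight error model: the joint objective's
  # minimum is then the equilibrium geometry itself
  nuis <- nuisance_parameters(
    k_total = 1, k_mask = 0,
    shells = tibble::tibble(d_max = Inf, d_min = 0, alpha = 1,
                            beta = 1e-6 * mean(ds[[1]]$data$f_obs^2),
                            n_work = NA_integer_, n_free = NA_integer_))
  pol <- cg_polish(stretched, ds, ff, cfg, nuis_list = list(nuis))
  b_len <- sqrt(sum(diff(pol$states[[1]]$xyz)^2))
  expect_equal(b_len, 1.538, tolerance = 1e-3)
  trace <- attr(pol, "score_trace")
  expect_true(all(diff(trace) <= 1e-9))
  # already at the minimum: returned unchanged within tolerance
  pol2 <- cg_polish(model_eq, ds, ff, cfg, nuis_list = list(nuis))
  expect_equal(pol2$states[[1]]$xyz, model_eq$states[[1]]$xyz, tolerance = 1e-3)
})

test_that("short biased runs improve the fit on noiseless toy data", {
  study <- tiny_study(sigma = 0)
  start <- perturb_model(study$native, 0.3, seed = 4)
  r_start <- model_r_factors(start, study$datasets)
  cfg <- sampler_config(steps = 60, macro_cycle = 20, seed = 17,
                        n_trajectories = 1, w_xray = 1, cg_max_iter = 40)
  samp <- sampling_protocol(start, study$datasets, study$ff, cfg,
                            weights = study$native$weights)
  td <- tidy(samp)
  expect_lt(min(td$rwork_cond1), r_start$rwork[1])
  # protocol bookkeeping: records from every macro-cycle plus the polish
  expect_equal(sum(td$polished), 1)
  expect_equal(nrow(td), 4 + 1)
  # sample size scales with the sweep
  cfg2 <- sampler_config(steps = 20, macro_cycle = 20, seed = 17,
                         n_trajectories = 2, w_xray = c(1, 0.5),
                         cg_max_iter = 5)
  samp2 <- sampling_protocol(start, study$datasets, study$ff, cfg2,
                             weights = study$native$weights)
  expect_equal(max(tidy(samp2)$trajectory), 4)
  gl <- glance(samp2)
  expect_equal(gl$n_trajectories, 4)
})

test_that("sampler defaults follow the documented protocol constants", {
  cfg <- sampler_config()
  expect_equal(cfg$temperature, 5000)
  expect_equal(cfg$w_xray, c(1, 0.5, 0.25))
})
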