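# independent evaluation of log I0 through the integral representation
# I0(x) = (1/pi) * int_0^pi exp(x cos t) dt, evaluated in log space
log_i0_quad <- function(x) {
  f <- function(t) exp(x * (cos(t) - 1))
  log(stats::integrate(f, 0, pi, rel.tol = 1e-12)$value / pi) + x
}

test_that("amplitude log-likelihood matches closed forms and an independent oracle", {
  # Rayleigh limit: alpha * F_M = 0, eps*beta = 1, F_O = 1
  expect_equal(log_p_amplitude(1, 0, alpha = 1, beta = 1), log(2) - 1,
               tolerance = 1e-12)
  # acentric value against the quadrature-based Bessel oracle
  got <- log_p_amplitude(10, 9, alpha = 1, beta = 4, epsilon = 1)
  expected <- log(2 * 10 / 4) - (100 + 81) / 4 + log_i0_quad(2 * 10 * 9 / 4)
  expect_equal(got, expected, tolerance = 1e-9)
  # centric value against direct evaluation
  gotc <- log_p_amplitude(3, 2.5, alpha = 0.9, beta = 2, epsilon = 2,
                          centric = TRUE)
  eb <- 4
  expectedc <- 0.5 * log(2 / (pi * eb)) - (9 + 0.81 * 6.25) / (2 * eb) +
    log(cosh(0.9 * 3 * 2.5 / eb))
  expect_equal(gotc, expectedc, tolerance = 1e-12)
  expect_error(log_p_amplitude(1, 1, 1, beta = 0), "beta")
})

test_that("both likelihood branches are proper densities", {
  grid <- expand.grid(f_model = c(0, 1, 5, 20), alpha = c(0.8, 1),
                      beta = c(0.5, 4), epsilon = c(1, 2))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    for (cen in c(FALSE, TRUE)) {
      dens <- function(fo) vapply(fo, function(f)
        exp(log_p_amplitude(f, g$f_model, g$alpha, g$beta, g$epsilon, cen)), 0)
      # bounded domain: the density support is concentrated within a few
      # sigma of alpha*f_model, and integrate() misses narrow distant peaks
      # on an infinite range
      upper <- g$alpha * g$f_model + 30 * sqrt(g$epsilon * g$beta) + 5
      total <- stats::integrate(dens, 0, upper, rel.tol = 1e-9,
                                subdivisions = 400L)$value
      expect_equal(total, 1, tolerance = 1e-6,
                   info = paste(unlist(g), collapse = "/"))
    }
  }
})

test_that("likelihood evaluation is overflow-safe for huge Bessel arguments", {
  v <- log_p_amplitude(1e6, 1e6, alpha = 1, beta = 1, epsilon = 1)
  expect_true(is.finite(v))
  vc <- log_p_amplitude(1e6, 1e6, alpha = 1, beta = 1, centric = TRUE)
  expect_true(is.finite(vc))
})

test_that("gradient weights match finite differences and flip sign at the optimum", {
  grid <- expand.grid(f_obs = c(0.5, 3, 12), f_model = c(0.3, 2, 15),
                      centric = c(FALSE, TRUE))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    h <- 1e-5 * max(g$f_model, 1)
    fd <- -(log_p_amplitude(g$f_obs, g$f_model + h, 1, 2, 1, g$centric) -
            log_p_amplitude(g$f_obs, g$f_model - h, 1, 2, 1, g$centric)) / (2 * h)
    der <- msxtal:::neg_log_p_derivs(g$f_obs, g$f_model, 1, 2, 1, g$centric)
    expect_equal(der$gradient, fd, tolerance = 1e-6 * max(1, abs(fd)))
    fd2 <- -(log_p_amplitude(g$f_obs, g$f_model + h, 1, 2, 1, g$centric) -
             2 * log_p_amplitude(g$f_obs, g$f_model, 1, 2, 1, g$centric) +
             log_p_amplitude(g$f_obs, g$f_model - h, 1, 2, 1, g$centric)) / h^2
    expect_equal(der$curvature, fd2, tolerance = 1e-3 * max(1, abs(fd2)))
  }
  # unimodality in F_M: exactly one sign change of the derivative
  fm <- seq(0.01, 40, by = 0.01)
  gr <- msxtal:::neg_log_p_derivs(10, fm, 1, 0.5, 1, FALSE)$gradient
  expect_equal(sum(diff(sign(gr)) != 0), 1)
  # large-argument Rice limit: optimum approaches F_obs
  opt <- fm[which.min(abs(msxtal:::neg_log_p_derivs(10, fm, 1, 0.01, 1, FALSE)$gradient))]
  expect_equal(opt, 10, tolerance = 0.01)
})

test_that("dataset likelihood sums work reflections only and is additive", {
  study <- tiny_study(sigma = 0.05)
  refl <- study$datasets[[1]]
  msf <- model_structure_factors(study$native, refl, condition = 1)
  nll <- dataset_neg_log_likelihood(refl, msf)
  # manual summation oracle
  tab <- refl$data
  ab <- msxtal:::shell_alpha_beta(tab$d, msf$nuisance)
  manual <- 0
  for (i in which(!tab$free)) {
    manual <- manual - log_p_amplitude(tab$f_obs[i], msf$amp[i], ab$alpha[i],
                                       ab$beta[i], tab$epsilon[i], tab$centric[i])
  }
  expect_equal(nll, manual, tolerance = 1e-9)
  # additivity over a partition
  idx <- seq_len(nrow(tab)) %% 2 == 0
  r1 <- refl; r1$data <- tab[idx, ]
  r2 <- refl; r2$data <- tab[!idx, ]
  part <- dataset_neg_log_likelihood(r1, msf$amp[idx], msf$nuisance) +
    dataset_neg_log_likelihood(r2, msf$amp[!idx], msf$nuisance)
  expect_equal(part, dataset_neg_log_likelihood(refl, msf$amp, msf$nuisance),
               tolerance = 1e-9)

  r_empty <- refl; r_empty$data$free <- TRUE
  expect_error(dataset_neg_log_likelihood(r_empty, msf), "empty work set")

  # a single-reflection set reduces to one term
  r_one <- refl; r_one$data <- tab[1, ]; r_one$data$free <- FALSE
  expect_equal(dataset_neg_log_likelihood(r_one, msf$amp[1], msf$nuisance),
               -log_p_amplitude(tab$f_obs[1], msf$amp[1], ab$alpha[1],
                                ab$beta[1], tab$epsilon[1], tab$centric[1]))
})

test_that("joint likelihood uses one weight column per dataset", {
  study <- tiny_study(sigma = 0.05)
  model <- study$native
  jl <- joint_neg_log_likelihood(model, study$datasets)
  # componentwise oracle
  for (j in 1:2) {
    msf <- model_structure_factors(model, study$datasets[[j]], condition = j)
    expect_equal(unname(jl$per_dataset[j]),
                 dataset_neg_log_likelihood(study$datasets[[j]], msf),
                 tolerance = 1e-9)
  }
  expect_equal(jl$total, sum(jl$per_dataset))
  # duplicating a dataset doubles its contribution
  m3 <- multi_state_model(model$states,
                          weight_matrix(cbind(model$weights, model$weights[, 2])))
  jl3 <- joint_neg_log_likelihood(m3, c(study$datasets, study$datasets[2]))
  expect_equal(jl3$total, jl$total + jl$per_dataset[[2]], tolerance = 1e-9)
  expect_error(joint_neg_log_likelihood(model, study$datasets[1]),
               "does not match")
})

test_that("state relabeling leaves the joint likelihood unchanged", {
  study <- tiny_study(sigma = 0.05)
  model <- study$native
  perm <- multi_state_model(model$states[c(2, 1)],
                            weight_matrix(model$weights[c(2, 1), ]))
  jl <- joint_neg_log_likelihood(model, study$datasets)
  jlp <- joint_neg_log_likelihood(perm, study$datasets)
  expect_equal(jl$total, jlp$total, tolerance = 1e-9)
})

test_that("total score decomposes into likelihood and prior", {
  study <- tiny_study(sigma = 0.05)
  sb <- total_score(study$native, study$datasets, study$ff)
  jl <- joint_neg_log_likelihood(study$native, study$datasets)
  ep <- vapply(study$native$states, function(s)
    potential_energy(s, study$ff)$energy, 0)
  expect_equal(sb$total, jl$total + sum(ep), tolerance = 1e-9)
  # zero datasets: the score is the prior alone
  sb0 <- total_score(study$native, list(), study$ff)
  expect_equal(sb0$total, sum(ep))
  # relaxing a clash strictly lowers the score at fixed data terms
  clash <- study$native
  clash$states[[1]]$xyz[5, ] <- clash$states[[1]]$xyz[40, ] + c(0.8, 0, 0)
  e_clash <- total_score(clash, list(), study$ff)$total
  expect_gt(e_clash, sb0$total)
  td <- tidy(sb)
  expect_true(all(c("term", "value") %in% names(td)))
})
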