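KCAL_PER_MOL_TO_AKMA <- 4.184e-4  # (kcal/mol/A)/amu -> A/fs^2
KB_KCAL <- 0.0019872041           # kcal/mol/K

#' Sampler configuration
#'
#' Defaults follow the sampling protocol of the method: high-temperature
#' exploration at T = 5000 K with a likelihood down-weight sweep
#' `w_xray = {1.0, 0.5, 0.25}`, Langevin thermostat, nuisance/gradient
#' refresh every macro-cycle, and conjugate-gradient polishing of final
#' snapshots.
#'
#' @param temperature Sampling temperature in K (default 5000).
#' @param w_xray Likelihood down-weight value(s); the protocol sweeps them.
#' @param steps Dynamics steps per trajectory.
#' @param timestep Integration step in fs (default 1).
#' @param friction Langevin friction in 1/ps (default 1).
#' @param macro_cycle Steps between nuisance-parameter / quadratic-target /
#'   w_auto refreshes and snapshots (default 100).
#' @param n_trajectories Trajectories per w_xray value (default 4).
#' @param seed Base random seed.
#' @param state_seeds Optional per-state seeds for velocity/noise streams
#'   (default derived from `seed`); permuting them together with the states
#'   permutes the trajectory exactly.
#' @param resample_weights_every Macro-cycles between in-trajectory weight
#'   redraws, or NULL (default) to hold the weights drawn at trajectory start.
#' @param exact_gradient Use the exact likelihood derivative every step
#'   instead of the frozen per-reflection quadratic (testing aid).
#' @param solvent Include the bulk-solvent term.
#' @param n_shells Resolution shells for nuisance fitting.
#' @param cg_max_iter,cg_tol Conjugate-gradient polish iteration cap and
#'   gradient-RMS tolerance (kcal/mol/A equivalents).
#' @param wauto_max Clamp for w_auto when the likelihood gradient vanishes.
#' @return Object of class `sampler_config`.
#' @export
sampler_config <- function(temperature = 5000, w_xray = c(1, 0.5, 0.25),
                           steps = 500, timestep = 1, friction = 1,
                           macro_cycle = 100, n_trajectories = 4, seed = 1,
                           state_seeds = NULL, resample_weights_every = NULL,
                           exact_gradient = FALSE, solvent = FALSE,
                           n_shells = 10, cg_max_iter = 500, cg_tol = 1e-3,
                           wauto_max = 1e6) {
  stopifnot(temperature > 0, all(w_xray > 0), steps >= 0, timestep > 0,
            macro_cycle >= 1, n_trajectories >= 1)
  structure(list(temperature = temperature, w_xray = w_xray, steps = steps,
                 timestep = timestep, friction = friction,
                 macro_cycle = macro_cycle, n_trajectories = n_trajectories,
                 seed = seed, state_seeds = state_seeds,
                 resample_weights_every = resample_weights_every,
                 exact_gradient = exact_gradient, solvent = solvent,
                 n_shells = n_shells, cg_max_iter = cg_max_iter,
                 cg_tol = cg_tol, wauto_max = wauto_max),
            class = "sampler_config")
}

#' Automatic likelihood-gradient scale
#'
#' `w_auto` equalizes the average per-atom gradient magnitudes of the
#' likelihood and the prior: it is the ratio mean(|prior gradient|) /
#' mean(|likelihood gradient|) over all atoms of all states, so that after
#' scaling the two averages coincide.
#'
#' @param likelihood_grads,prior_grads Lists of n x 3 gradient matrices
#'   (one per state) over the same atoms.
#' @param wauto_max Clamp applied when the likelihood gradient vanishes.
#' @return Scalar `w_auto`.
#' @export
compute_wauto <- function(likelihood_grads, prior_grads, wauto_max = 1e6) {
  mag <- function(gl) mean(unlist(lapply(gl, function(g) sqrt(rowSums(g^2)))))
  ml <- mag(likelihood_grads); mp <- mag(prior_grads)
  if (!is.finite(ml) || ml <= 0) {
    warning("zero likelihood-gradient magnitude; w_auto clamped")
    return(wauto_max)
  }
  min(mp / ml, wauto_max)
}

#' Draw a random weight matrix from the uniform simplex
#'
#' Each column is an independent flat-Dirichlet draw: N exponential deviates
#' normalized to sum 1.
#'
#' @param n_states,n_conditions Matrix dimensions.
#' @return A [weight_matrix()].
#' @export
sample_weight_matrix <- function(n_states, n_conditions) {
  stopifnot(n_states >= 1, n_conditions >= 1)
  e <- matrix(-log(runif(n_states * n_conditions)), n_states, n_conditions)
  weight_matrix(sweep(e, 2, colSums(e), `/`))
}

# --- internal fast force machinery -----------------------------------------

# per-dataset precomputation reused across steps
make_sf_context <- function(refls) {
  H <- as.matrix(refls$data[, c("h", "k", "l")]); storage.mode(H) <- "double"
  Minv <- solve(orthogonalization_matrix(refls$cell))
  ops <- lapply(refls$ops, function(op) {
    HR <- H %*% op$R
    list(HR = HR, SR = HR %*% Minv, ph = exp(2i * pi * as.vector(H %*% op$t)))
  })
  list(H = H, Minv = Minv, ops = ops, tab = refls$data, refls = refls)
}

ctx_forward <- function(ctx, Xf, coef) {
  F <- complex(nrow(ctx$H))
  for (op in ctx$ops) F <- F + op$ph * sf_forward(op$HR, Xf, coef)
  F
}

ctx_gradient <- function(ctx, Xf, coef, pref) {
  G <- matrix(0, nrow(Xf), 3)
  for (op in ctx$ops) {
    p <- pref * op$ph
    G <- G + sf_gradient(op$HR, Xf, coef, Re(p), Im(p), op$SR)
  }
  G
}

# shared evaluation state for one model/datasets pairing during dynamics
make_eval_state <- function(model, datasets, cfg) {
  ctxs <- lapply(datasets, make_sf_context)
  sig <- vapply(ctxs, function(c) rlang::hash(c$H), "")
  ctx_of <- match(sig, sig)  # dataset -> index of first identical context
  coefs <- lapply(model$states, function(s) sf_coefficients(s, datasets[[1]]))
  list(ctxs = ctxs, ctx_of = ctx_of, coefs = coefs,
       f_bulk = vector("list", length(datasets)))
}

# forward amplitudes for all datasets given coordinates (list per state)
eval_forward <- function(es, model, xyz_list, nuis_list) {
  J <- length(es$ctxs)
  Fst <- vector("list", length(es$ctxs))  # per unique ctx: nrefl x N
  for (u in unique(es$ctx_of)) {
    ctx <- es$ctxs[[u]]
    Xf_u <- lapply(seq_along(xyz_list), function(i)
      xyz_list[[i]] %*% t(ctx$Minv))
    Fst[[u]] <- vapply(seq_along(xyz_list), function(i)
      ctx_forward(ctx, Xf_u[[i]], es$coefs[[i]]), complex(nrow(ctx$H)))
    Fst[[u]] <- matrix(Fst[[u]], ncol = length(xyz_list))
    attr(Fst[[u]], "Xf") <- Xf_u
  }
  out <- vector("list", J)
  for (j in seq_len(J)) {
    u <- es$ctx_of[j]
    fc <- as.vector(Fst[[u]] %*% model$weights[, j])
    tot <- total_amplitude(fc, es$f_bulk[[j]], nuis_list[[j]])
    out[[j]] <- list(f_states = Fst[[u]], f_calc = fc, amp = tot$amp,
                     phi = tot$phi, u = u)
  }
  out
}

# X-ray gradient per state given per-dataset dL/d|F_M|
eval_xray_gradient <- function(es, model, fw, dl_list, nuis_list) {
  N <- n_states(model)
  G <- vector("list", N)
  # combine datasets sharing a context: pref_i = sum_j w_ij prefbase_j
  prefbase <- lapply(seq_along(fw), function(j)
    dl_list[[j]] * nuis_list[[j]]$k_total * exp(-1i * fw[[j]]$phi))
  for (i in seq_len(N)) G[[i]] <- 0
  for (u in unique(es$ctx_of)) {
    js <- which(es$ctx_of == u)
    ctx <- es$ctxs[[u]]
    Xf_u <- attr(fw[[js[1]]]$f_states, "Xf")
    for (i in seq_len(N)) {
      pref_i <- Reduce(`+`, lapply(js, function(j)
        model$weights[i, j] * prefbase[[j]]))
      if (all(Mod(pref_i) == 0)) next
      G[[i]] <- G[[i]] + ctx_gradient(ctx, Xf_u[[i]], es$coefs[[i]], pref_i)
    }
  }
  n <- nrow(model$states[[1]]$xyz)
  lapply(G, function(g) if (is.matrix(g)) g else matrix(0, n, 3))
}

#' Biased force on every atom of every state
#'
#' `F = w_xray * w_auto * (-grad of the joint negative log-likelihood)
#'  + (-grad of the per-state prior energy)`. The X-ray term on state i sums
#' contributions from all datasets, each weighted by `w_ij`.
#'
#' @param model A [multi_state_model()].
#' @param datasets List of [reflection_set()]s (one per weight column).
#' @param prior A [forcefield_parameters()] object or resolved parameters.
#' @param w_xray,w_auto Gradient scaling factors.
#' @param solvent Include the bulk-solvent term.
#' @return List of n x 3 force matrices (kcal/mol/A), one per state.
#' @export
biased_force <- function(model, datasets, prior, w_xray = 1, w_auto = 1,
                         solvent = FALSE) {
  if (inherits(datasets, "reflection_set")) datasets <- list(datasets)
  jl <- joint_neg_log_likelihood(model, datasets, solvent = solvent)
  lik_grads <- prior_grads <- vector("list", n_states(model))
  for (i in seq_len(n_states(model))) lik_grads[[i]] <- 0
  for (j in seq_along(datasets)) {
    qw <- quadratic_gradient_weights(datasets[[j]], jl$msf[[j]])
    gj <- amplitude_coordinate_gradients(model, datasets[[j]], jl$msf[[j]],
                                         qw$gradient, condition = j)
    for (i in seq_len(n_states(model))) lik_grads[[i]] <- lik_grads[[i]] + gj[[i]]
  }
  rp <- if (inherits(prior, "forcefield_parameters"))
    resolve_forcefield(model$states[[1]]$topology, prior) else prior
  for (i in seq_len(n_states(model)))
    prior_grads[[i]] <- potential_energy(model$states[[i]], rp)$gradient
  lapply(seq_len(n_states(model)), function(i)
    -w_xray * w_auto * lik_grads[[i]] - prior_grads[[i]])
}

# R factors for current amplitudes
r_factors_from <- function(tab, amp) {
  tibble::tibble(
    rwork = r_factor(tab$f_obs[!tab$free], amp[!tab$free]),
    rfree = if (any(tab$free)) r_factor(tab$f_obs[tab$free], amp[tab$free]) else NA_real_)
}

#' Run one biased Langevin dynamics trajectory
#'
#' BAOAB Langevin integration at the configured temperature with the biased
#' force of the full score. Velocities are initialized from the
#' Maxwell-Boltzmann distribution; the weight matrix is drawn once at
#' trajectory start (flat Dirichlet) unless `weights` pins it. Nuisance
#' parameters, the frozen quadratic likelihood target and `w_auto` are
#' refreshed every macro-cycle, when a snapshot is also recorded. Identical
#' (seed, config, inputs) reproduce the trajectory bit-for-bit. Non-finite
#' coordinates truncate the trajectory with a `"blowup"` flag.
#'
#' @param start A [multi_state_model()] (parameterized by `prior`).
#' @param datasets List of [reflection_set()]s.
#' @param prior A [forcefield_parameters()] object.
#' @param cfg A [sampler_config()].
#' @param w_xray Single w_xray value for this trajectory (default first of
#'   the config sweep).
#' @param weights Optional fixed [weight_matrix()] overriding the random
#'   draw.
#' @param trajectory_id Identifier stored in the records.
#' @return Object of class `msx_trajectory`: list of snapshot records.
#' @export
run_trajectory <- function(start, datasets, prior, cfg, w_xray = cfg$w_xray[1],
                           weights = NULL, trajectory_id = 1L) {
  if (inherits(datasets, "reflection_set")) datasets <- list(datasets)
  stopifnot(inherits(start, "multi_state_model"))
  N <- n_states(start)
  J <- length(datasets)
  if (J != n_conditions(start)) stop("dataset count does not match weight columns")
  natom <- nrow(start$states[[1]]$xyz)
  rp <- resolve_forcefield(start$states[[1]]$topology, prior)
  set.seed(cfg$seed)
  model <- start
  if (is.null(weights)) model$weights <- sample_weight_matrix(N, J)
  else model$weights <- weight_matrix(weights)

  state_seeds <- cfg$state_seeds
  if (is.null(state_seeds)) state_seeds <- cfg$seed + 7919L * seq_len(N)
  mass <- element_mass(start$states[[1]]$element)
  dt <- cfg$timestep
  gam <- cfg$friction / 1000  # 1/ps -> 1/fs
  c1 <- exp(-gam * dt); c2 <- sqrt(1 - c1^2)
  sig_v <- sqrt(KB_KCAL * cfg$temperature / mass * KCAL_PER_MOL_TO_AKMA)
  vel <- noise <- vector("list", N)
  n_cycles <- if (cfg$steps == 0) 0 else ceiling(cfg$steps / cfg$macro_cycle)
  for (i in seq_len(N)) {
    set.seed(state_seeds[i] %% .Machine$integer.max)
    vel[[i]] <- matrix(rnorm(natom * 3), natom, 3) * sig_v
    noise[[i]] <- if (cfg$steps > 0)
      array(rnorm(cfg$steps * natom * 3), c(cfg$steps, natom, 3)) else NULL
  }
  set.seed(cfg$seed + 104729L)

  es <- make_eval_state(model, datasets, cfg)
  xyz <- lapply(model$states, `[[`, "xyz")
  records <- list()
  flags <- character()

  refresh <- function(xyz) {
    m <- set_coordinates(model, xyz)
    nuis_list <- vector("list", J); qw_list <- vector("list", J)
    for (j in seq_len(J)) {
      msf <- model_structure_factors(m, datasets[[j]], condition = j,
                                     solvent = cfg$solvent, n_shells = cfg$n_shells)
      nuis_list[[j]] <- msf$nuisance
      qw_list[[j]] <- quadratic_gradient_weights(datasets[[j]], msf)
      if (cfg$solvent) es$f_bulk[[j]] <<- msf$f_bulk
    }
    fw <- eval_forward(es, m, xyz, nuis_list)
    dl <- lapply(seq_len(J), function(j) qw_list[[j]]$gradient)
    lik_g <- eval_xray_gradient(es, m, fw, dl, nuis_list)
    pri_g <- lapply(seq_len(N), function(i) {
      s <- m$states[[i]]; s$xyz <- xyz[[i]]
      potential_energy(s, rp)$gradient
    })
    w_auto <- compute_wauto(lik_g, pri_g, cfg$wauto_max)
    list(nuis = nuis_list, qw = qw_list, w_auto = w_auto)
  }

  force_at <- function(xyz, rc) {
    fw <- eval_forward(es, model, xyz, rc$nuis)
    dl <- lapply(seq_len(J), function(j) {
      q <- rc$qw[[j]]
      if (cfg$exact_gradient) {
        ab <- shell_alpha_beta(datasets[[j]]$data$d, rc$nuis[[j]])
        tabj <- datasets[[j]]$data
        g <- neg_log_p_derivs(tabj$f_obs, fw[[j]]$amp, ab$alpha, ab$beta,
                              tabj$epsilon, tabj$centric)$gradient
        g[tabj$free] <- 0
        g
      } else q$gradient + q$curvature * (fw[[j]]$amp - q$amp_ref)
    })
    lik_g <- eval_xray_gradient(es, model, fw, dl, rc$nuis)
    pri_g <- lapply(seq_len(N), function(i) {
      s <- model$states[[i]]; s$xyz <- xyz[[i]]
      potential_energy(s, rp)$gradient
    })
    lapply(seq_len(N), function(i)
      -w_xray * rc$w_auto * lik_g[[i]] - pri_g[[i]])
  }

  snapshot <- function(xyz, step, rc, flag = character()) {
    m <- set_coordinates(model, xyz)
    fw <- eval_forward(es, m, xyz, rc$nuis)
    nll <- vapply(seq_len(J), function(j)
      dataset_neg_log_likelihood(datasets[[j]], fw[[j]]$amp, rc$nuis[[j]]), 0)
    names(nll) <- vapply(datasets, `[[`, "", "condition_id")
    epr <- vapply(seq_len(N), function(i) {
      s <- m$states[[i]]; potential_energy(s, rp)$energy
    }, 0)
    rf <- dplyr::bind_rows(lapply(seq_len(J), function(j)
      cbind(dataset = datasets[[j]]$condition_id,
            r_factors_from(datasets[[j]]$data, fw[[j]]$amp))))
    list(trajectory = trajectory_id, w_xray = w_xray, step = step,
         model = m, score = list(per_dataset_nll = nll, prior_energy = epr,
                                 total = sum(nll) + sum(epr)),
         r = tibble::as_tibble(rf), w_auto = rc$w_auto, flags = flag,
         polished = FALSE)
  }

  rc <- refresh(xyz)
  records[[1]] <- snapshot(xyz, 0L, rc)
  if (cfg$steps == 0) {
    return(structure(records, class = "msx_trajectory", seed = cfg$seed))
  }
  f <- force_at(xyz, rc)
  step <- 0L
  blown <- FALSE
  while (step < cfg$steps && !blown) {
    step <- step + 1L
    for (i in seq_len(N)) {
      acc <- f[[i]] / mass * KCAL_PER_MOL_TO_AKMA
      vel[[i]] <- vel[[i]] + 0.5 * dt * acc
      xyz[[i]] <- xyz[[i]] + 0.5 * dt * vel[[i]]
      vel[[i]] <- c1 * vel[[i]] + c2 * sig_v * noise[[i]][step, , ]
      xyz[[i]] <- xyz[[i]] + 0.5 * dt * vel[[i]]
    }
    if (any(!vapply(xyz, function(x) all(is.finite(x)), TRUE))) {
      blown <- TRUE
      flags <- c(flags, "blowup")
      break
    }
    end_cycle <- step %% cfg$macro_cycle == 0 || step == cfg$steps
    if (end_cycle) {
      model <- set_coordinates(model, xyz)
      if (!is.null(cfg$resample_weights_every) &&
          (step %/% cfg$macro_cycle) %% cfg$resample_weights_every == 0 &&
          step < cfg$steps) {
        model$weights <- sample_weight_matrix(N, J)
      }
      rc <- refresh(xyz)
      records[[length(records) + 1]] <- snapshot(xyz, step, rc)
    }
    f <- force_at(xyz, rc)
    for (i in seq_len(N)) {
      acc <- f[[i]] / mass * KCAL_PER_MOL_TO_AKMA
      vel[[i]] <- vel[[i]] + 0.5 * dt * acc
    }
  }
  if (blown && length(records)) {
    records[[length(records)]]$flags <- unique(c(records[[length(records)]]$flags, "blowup"))
  }
  structure(records, class = "msx_trajectory", seed = cfg$seed,
            truncated = blown)
}

#' Conjugate-gradient polish of a model
#'
#' Polak-Ribiere conjugate gradients with backtracking line search on the
#' score `S` at `w_xray = 1` (the likelihood term carries the `w_auto`
#' balance factor fixed at entry, and nuisance parameters are fixed during
#' the minimization). Stops when the gradient RMS falls below `cg_tol` or
#' after `cg_max_iter` iterations; the returned model never scores worse
#' than the input.
#'
#' @inheritParams run_trajectory
#' @param model A [multi_state_model()].
#' @param nuis_list Optional fixed [nuisance_parameters()] per dataset;
#'   fitted at the starting coordinates when NULL and then held fixed for
#'   the whole minimization.
#' @return The polished model, with attributes `score_trace` (per-iteration
#'   best score) and `flag` ("" or "line_search_failure").
#' @export
cg_polish <- function(model, datasets, prior, cfg = sampler_config(),
                      nuis_list = NULL) {
  if (inherits(datasets, "reflection_set")) datasets <- list(datasets)
  N <- n_states(model); J <- length(datasets)
  natom <- nrow(model$states[[1]]$xyz)
  rp <- resolve_forcefield(model$states[[1]]$topology, prior)
  es <- make_eval_state(model, datasets, cfg)
  if (is.null(nuis_list)) {
    nuis_list <- vector("list", J)
    for (j in seq_len(J)) {
      msf <- model_structure_factors(model, datasets[[j]], condition = j,
                                     solvent = cfg$solvent, n_shells = cfg$n_shells)
      nuis_list[[j]] <- msf$nuisance
      if (cfg$solvent) es$f_bulk[[j]] <- msf$f_bulk
    }
  }
  unpack <- function(p) {
    lapply(seq_len(N), function(i)
      matrix(p[((i - 1) * natom * 3 + 1):(i * natom * 3)], natom, 3))
  }
  pack <- function(xyz) unlist(xyz)

  obj <- function(p, w_auto) {
    xyz <- unpack(p)
    m <- set_coordinates(model, xyz)
    fw <- eval_forward(es, m, xyz, nuis_list)
    nll <- 0
    for (j in seq_len(J)) {
      tabj <- datasets[[j]]$data; work <- !tabj$free
      ab <- shell_alpha_beta(tabj$d, nuis_list[[j]])
      nll <- nll - sum(log_p_amplitude(tabj$f_obs[work], fw[[j]]$amp[work],
                                       ab$alpha[work], ab$beta[work],
                                       tabj$epsilon[work], tabj$centric[work]))
    }
    epr <- sum(vapply(seq_len(N), function(i) {
      s <- m$states[[i]]; potential_energy(s, rp)$energy
    }, 0))
    w_auto * nll + epr
  }
  grad <- function(p, w_auto) {
    xyz <- unpack(p)
    m <- set_coordinates(model, xyz)
    fw <- eval_forward(es, m, xyz, nuis_list)
    dl <- lapply(seq_len(J), function(j) {
      tabj <- datasets[[j]]$data
      ab <- shell_alpha_beta(tabj$d, nuis_list[[j]])
      g <- neg_log_p_derivs(tabj$f_obs, fw[[j]]$amp, ab$alpha, ab$beta,
                            tabj$epsilon, tabj$centric)$gradient
      g[tabj$free] <- 0
      g
    })
    lik_g <- eval_xray_gradient(es, m, fw, dl, nuis_list)
    pri_g <- lapply(seq_len(N), function(i) {
      s <- m$states[[i]]; s$xyz <- xyz[[i]]
      potential_energy(s, rp)$gradient
    })
    pack(lapply(seq_len(N), function(i) w_auto * lik_g[[i]] + pri_g[[i]]))
  }

  # balance factor fixed at entry
  p <- pack(lapply(model$states, `[[`, "xyz"))
  fw0 <- eval_forward(es, model, unpack(p), nuis_list)
  dl0 <- lapply(seq_len(J), function(j)
    quadratic_gradient_weights(datasets[[j]],
                               structure(list(amp = fw0[[j]]$amp,
                                              nuisance = nuis_list[[j]]),
                                         class = "model_sf"))$gradient)
  lik0 <- eval_xray_gradient(es, model, fw0, dl0, nuis_list)
  pri0 <- lapply(seq_len(N), function(i) potential_energy(model$states[[i]], rp)$gradient)
  w_auto <- compute_wauto(lik0, pri0, cfg$wauto_max)

  fcur <- obj(p, w_auto)
  g <- grad(p, w_auto)
  d <- -g
  trace <- fcur
  flag <- ""
  best_p <- p; best_f <- fcur
  for (it in seq_len(cfg$cg_max_iter)) {
    if (sqrt(mean(g^2)) < cfg$cg_tol) break
    # backtracking Armijo line search along d
    slope <- sum(g * d)
    if (slope >= 0) { d <- -g; slope <- sum(g * d) }
    alpha <- 1 / max(sqrt(sum(d^2) / length(d)), 1e-8) * 0.01
    ok <- FALSE
    for (ls in 1:30) {
      fnew <- obj(p + alpha * d, w_auto)
      if (is.finite(fnew) && fnew <= fcur + 1e-4 * alpha * slope) { ok <- TRUE; break }
      alpha <- alpha / 2
    }
    if (!ok) { flag <- "line_search_failure"; break }
    pnew <- p + alpha * d
    gnew <- grad(pnew, w_auto)
    beta <- max(0, sum(gnew * (gnew - g)) / max(sum(g * g), 1e-30))
    d <- -gnew + beta * d
    p <- pnew; fcur <- fnew; g <- gnew
    if (fcur < best_f) { best_f <- fcur; best_p <- p }
    trace <- c(trace, best_f)
  }
  out <- set_coordinates(model, unpack(best_p))
  attr(out, "score_trace") <- trace
  attr(out, "flag") <- flag
  attr(out, "w_auto") <- w_auto
  out
}

#' Full sampling protocol
#'
#' Runs `n_trajectories` biased-dynamics trajectories for every value in the
#' `w_xray` sweep (distinct seeds), polishes each trajectory's final
#' snapshot with [cg_polish()], and merges everything into one sample.
#'
#' @inheritParams run_trajectory
#' @param weights Optional fixed weight matrix applied to every trajectory
#'   (e.g. for single-state models).
#' @return Object of class `msx_sample`.
#' @export
sampling_protocol <- function(start, datasets, prior, cfg = sampler_config(),
                              weights = NULL) {
  if (inherits(datasets, "reflection_set")) datasets <- list(datasets)
  records <- list()
  tid <- 0L
  for (wx in cfg$w_xray) {
    for (k in seq_len(cfg$n_trajectories)) {
      tid <- tid + 1L
      tcfg <- cfg
      tcfg$seed <- cfg$seed + 1009L * tid
      tcfg$state_seeds <- NULL
      traj <- run_trajectory(start, datasets, prior, tcfg, w_xray = wx,
                             weights = weights, trajectory_id = tid)
      records <- c(records, unclass(traj))
      # polish the final snapshot
      last <- traj[[length(traj)]]
      pol <- cg_polish(last$model, datasets, prior, cfg)
      prec <- score_record(pol, datasets, prior,
                           trajectory = tid, w_xray = wx,
                           step = last$step, polished = TRUE,
                           flags = attr(pol, "flag"))
      records <- c(records, list(prec))
    }
  }
  structure(list(records = records,
                 meta = list(cfg = cfg, n_trajectories = tid)),
            class = "msx_sample")
}

# score an arbitrary model into a sample record
score_record <- function(model, datasets, prior, trajectory = NA_integer_,
                         w_xray = NA_real_, step = NA_integer_,
                         polished = FALSE, flags = character()) {
  if (inherits(datasets, "reflection_set")) datasets <- list(datasets)
  sb <- total_score(model, datasets, prior)
  rf <- dplyr::bind_rows(lapply(seq_along(datasets), function(j)
    cbind(dataset = datasets[[j]]$condition_id,
          r_factors_from(datasets[[j]]$data, sb$msf[[j]]$amp))))
  list(trajectory = trajectory, w_xray = w_xray, step = step, model = model,
       score = list(per_dataset_nll = sb$per_dataset_nll,
                    prior_energy = sb$prior_energy, total = sb$total),
       r = tibble::as_tibble(rf), w_auto = NA_real_,
       flags = flags[nzchar(flags)], polished = polished)
}

#' @export
print.msx_sample <- function(x, ...) {
  cat(sprintf("<sample> %d records from %d trajectories\n",
              length(x$records), x$meta$n_trajectories))
  invisible(x)
}

#' Tidy a sample into one row per snapshot record
#'
#' @param x An `msx_sample`.
#' @param ... Unused.
#' @return A tibble with trajectory, w_xray, step, polished flag, score
#'   components and per-dataset `rwork_*` / `rfree_*` columns.
#' @method tidy msx_sample
#' @export
tidy.msx_sample <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$records), function(k) {
    r <- x$records[[k]]
    row <- tibble::tibble(record = k, trajectory = r$trajectory,
                          w_xray = r$w_xray, step = r$step,
                          polished = r$polished, score = r$score$total,
                          nll = sum(r$score$per_dataset_nll),
                          prior = sum(r$score$prior_energy),
                          flagged = length(r$flags) > 0)
    for (j in seq_len(nrow(r$r))) {
      row[[paste0("rwork_", r$r$dataset[j])]] <- r$r$rwork[j]
      row[[paste0("rfree_", r$r$dataset[j])]] <- r$r$rfree[j]
    }
    row
  }))
}

#' One-row summary of a sample
#' @param x An `msx_sample`.
#' @param ... Unused.
#' @return A tibble with record counts and the best score and per-dataset
#'   Rfree over the sample.
#' @method glance msx_sample
#' @export
glance.msx_sample <- function(x, ...) {
  td <- tidy(x)
  out <- tibble::tibble(n_records = nrow(td),
                        n_trajectories = x$meta$n_trajectories,
                        best_score = min(td$score))
  for (cn in grep("^rfree_", names(td), value = TRUE))
    out[[paste0("best_", cn)]] <- min(td[[cn]], na.rm = TRUE)
  out
}
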