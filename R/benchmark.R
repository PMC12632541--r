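#' Toy two-state two-condition benchmark study
#'
#' Runs the full method on a self-contained synthetic study: a toy
#' two-state native with condition-dependent weights, simulated noisy
#' amplitude datasets with a shared free set, and sampling runs for four
#' model representations:
#'
#' * `m22` -- 2 states, both conditions jointly;
#' * `m21_d2` -- 2 states, condition 2 only;
#' * `m11_d1`, `m11_d2` -- 1 state, one condition each.
#'
#' Every run starts from the same perturbed copy of the native (the
#' single-state runs from its state 1) and uses the same trajectory budget
#' per w_xray value. Problem sizes default to a desk-scale study (16
#' residues per state, 2.5 Angstrom data, 5 percent noise, 8 trajectories
#' per w_xray value).
#'
#' @param seed Base seed for all randomness.
#' @param n_residues Chain length of the toy native.
#' @param d_min Resolution limit of the simulated data (Angstrom).
#' @param sigma Relative amplitude noise.
#' @param start_rms RMS perturbation of the starting model (Angstrom).
#' @param n_trajectories Trajectories per w_xray value.
#' @param w_xray The w_xray sweep.
#' @param steps,macro_cycle Dynamics length and refresh cadence.
#' @param cg_max_iter Conjugate-gradient polish iteration cap.
#' @param temperature Sampling temperature (K).
#' @return List with `native`, `datasets`, `start`, the four `msx_sample`
#'   objects, and `summary`: a tibble of best-by-Rfree results per run and
#'   dataset.
#' @export
run_toy_benchmark <- function(seed = 1, n_residues = 16, d_min = 2.5,
                              sigma = 0.05, start_rms = 0.4,
                              n_trajectories = 8, w_xray = c(1, 0.5, 0.25),
                              steps = 200, macro_cycle = 40,
                              cg_max_iter = 60, temperature = 5000) {
  ff <- toy_forcefield()
  native <- build_toy_native(n_residues = n_residues, seed = seed)
  datasets <- simulate_datasets(native, d_min = d_min, sigma = sigma,
                                free = free_set_spec(seed = seed + 1),
                                seed = seed + 2)
  start2 <- perturb_model(native, start_rms, seed = seed + 3)
  start1 <- multi_state_model(list(start2$states[[1]]), matrix(1, 1, 1))
  start1$cell <- native$cell; start1$ops <- native$ops
  start2_1c <- multi_state_model(start2$states, weight_matrix(c(0.5, 0.5)))
  start2_1c$cell <- native$cell; start2_1c$ops <- native$ops

  cfg <- function(k) sampler_config(
    temperature = temperature, w_xray = w_xray, steps = steps,
    macro_cycle = macro_cycle, n_trajectories = n_trajectories,
    cg_max_iter = cg_max_iter, seed = seed + 1000L * k)

  m22 <- sampling_protocol(start2, datasets, ff, cfg(1))
  m21_d2 <- sampling_protocol(start2_1c, datasets[2], ff, cfg(2))
  m11_d1 <- sampling_protocol(start1, datasets[1], ff, cfg(3),
                              weights = matrix(1, 1, 1))
  m11_d2 <- sampling_protocol(start1, datasets[2], ff, cfg(4),
                              weights = matrix(1, 1, 1))

  best_rfree <- function(sample, ds) {
    rec <- select_best(sample, ds$condition_id, "rfree")
    r <- rec$r[rec$r$dataset == ds$condition_id, ]
    tibble::tibble(states = n_states(rec$model),
                   conditions = n_conditions(rec$model),
                   dataset = ds$condition_id,
                   rwork = r$rwork, rfree = r$rfree)
  }
  summary <- dplyr::bind_rows(
    cbind(run = "m22", dplyr::bind_rows(best_rfree(m22, datasets[[1]]),
                                        best_rfree(m22, datasets[[2]]))),
    cbind(run = "m21_d2", best_rfree(m21_d2, datasets[[2]])),
    cbind(run = "m11_d1", best_rfree(m11_d1, datasets[[1]])),
    cbind(run = "m11_d2", best_rfree(m11_d2, datasets[[2]])))
  list(native = native, datasets = datasets, start = start2,
       m22 = m22, m21_d2 = m21_d2, m11_d1 = m11_d1, m11_d2 = m11_d2,
       summary = tibble::as_tibble(summary))
}

#' Weight recovery at fixed native conformations
#'
#' Draws `n` random weight matrices at the native conformations, scores
#' each against the datasets, and reports the best-scoring one together
#' with the L1 distance of each weight column from the native's.
#'
#' @param native The native [multi_state_model()].
#' @param datasets The simulated datasets.
#' @param n Number of random weight draws.
#' @param seed Seed.
#' @return List with `best_weights`, `native_weights`, `l1_per_column`,
#'   and the full `landscape` tibble.
#' @export
recover_weights <- function(native, datasets, n = 200, seed = 1) {
  decoys <- generate_decoys(native, datasets, n_decoys = n, mode = "weights",
                            seed = seed)
  land <- decoy_landscape(decoys, native, datasets)
  best <- which.min(land$score[!land$native])
  W <- decoys[[best]]$weights
  list(best_weights = W, native_weights = native$weights,
       l1_per_column = colSums(abs(W - native$weights)),
       landscape = land)
}
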