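# shared fixtures, built once per test run

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- build()
  fixture_env[[name]]
}

# small toy native (8 residues, 48 atoms/state) with noiseless and noisy
# 3 Angstrom datasets -- enough reflections to be informative, fast to score
tiny_study <- function(sigma = 0, seed = 11) {
  fixture(paste0("study_", sigma, "_", seed), function() {
    native <- build_toy_native(n_residues = 8, seed = 7)
    datasets <- simulate_datasets(native, d_min = 3.0, sigma = sigma,
                                  free = free_set_spec(0.05, 5, seed = 3),
                                  seed = seed)
    list(native = native, datasets = datasets, ff = toy_forcefield())
  })
}

# 6-atom single-residue-like state with all bonded term types
tiny_state <- function(jitter = 0.05, seed = 1) {
  topo <- topology(c("NB", "CA", "CC", "OC", "CB", "HB"),
                   bonds = rbind(c(1, 2), c(2, 3), c(3, 4), c(2, 5), c(5, 6)),
                   angles = rbind(c(1, 2, 3), c(2, 3, 4), c(1, 2, 5),
                                  c(3, 2, 5), c(2, 5, 6)),
                   dihedrals = rbind(c(1, 2, 3, 4), c(1, 2, 5, 6), c(3, 2, 5, 6)),
                   impropers = rbind(c(3, 2, 1, 4)))
  X <- rbind(c(0, 0, 0), c(1.4, 0.3, 0), c(2.1, 1.5, 0.4), c(3.3, 1.5, 0.6),
             c(1.2, 0.9, 1.5), c(1.8, 0.4, 2.4))
  set.seed(seed)
  X <- X + matrix(rnorm(18, 0, jitter), 6, 3)
  atomic_state(c("N", "C", "C", "O", "C", "H"), X, topology = topo)
}

# numeric gradient of a scalar function of an atomic state's coordinates
numeric_state_gradient <- function(fun, st, h = 1e-5) {
  X <- st$xyz
  G <- matrix(0, nrow(X), 3)
  for (i in seq_len(nrow(X))) for (d in 1:3) {
    sp <- st; sp$xyz[i, d] <- X[i, d] + h
    sm <- st; sm$xyz[i, d] <- X[i, d] - h
    G[i, d] <- (fun(sp) - fun(sm)) / (2 * h)
  }
  G
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)) / max(abs(expected), 1e-12), tol)
}
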