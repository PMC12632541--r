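#' Numerically stable log I0 and log cosh
#'
#' `log_i0` uses the (scaled) modified Bessel function for moderate
#' arguments and the asymptotic expansion `x - log(2 pi x)/2 + log(1 +
#' 1/(8x) + 9/(128 x^2))` beyond; no overflow for arguments up to 1e6 and
#' beyond.
#'
#' @param x Non-negative numeric vector.
#' @return Numeric vector.
#' @keywords internal
log_i0 <- function(x) {
  out <- numeric(length(x))
  lo <- x < 700
  if (any(lo)) out[lo] <- x[lo] + log(besselI(x[lo], 0, expon.scaled = TRUE))
  if (any(!lo)) {
    xb <- x[!lo]
    out[!lo] <- xb - 0.5 * log(2 * pi * xb) + log1p(1 / (8 * xb) + 9 / (128 * xb^2))
  }
  out
}

#' @rdname log_i0
#' @keywords internal
log_cosh <- function(x) {
  ax <- abs(x)
  ax + log1p(exp(-2 * ax)) - log(2)
}

# I1(x)/I0(x), stable for large x
i1_over_i0 <- function(x) {
  out <- numeric(length(x))
  lo <- x < 700
  if (any(lo)) out[lo] <- besselI(x[lo], 1, expon.scaled = TRUE) /
      besselI(x[lo], 0, expon.scaled = TRUE)
  if (any(!lo)) {
    xb <- x[!lo]
    out[!lo] <- 1 - 1 / (2 * xb) - 1 / (8 * xb^2) - 1 / (8 * xb^3)
  }
  out
}

#' Amplitude log-likelihood (Rice / Woolfson noise model)
#'
#' Log density of observing amplitude `F_O` given model amplitude `F_M`,
#' under the two-dimensional Gaussian structure-factor error model with
#' variance `epsilon * beta` and scale `alpha`. Acentric reflections follow
#' the Rice density, centric reflections the folded (Woolfson) density:
#'
#' acentric: `log(2 F_O/(eb)) - (F_O^2 + a^2 F_M^2)/(eb) + log I0(2 a F_O F_M/(eb))`
#'
#' centric:  `log(2/(pi eb))/2 - (F_O^2 + a^2 F_M^2)/(2 eb) + log cosh(a F_O F_M/(eb))`
#'
#' with `eb = epsilon * beta`. Both branches are proper densities in `F_O`
#' over `[0, Inf)` and are evaluated in log space with asymptotic
#' expansions for large Bessel/cosh arguments.
#'
#' @param f_obs Observed amplitudes (>= 0).
#' @param f_model Model amplitudes `|F_M|` (>= 0).
#' @param alpha,beta Likelihood scale parameters (`beta > 0`).
#' @param epsilon Symmetry multiplicity factors (>= 1).
#' @param centric Logical vector selecting the centric branch.
#' @return Log-density per reflection.
#' @export
log_p_amplitude <- function(f_obs, f_model, alpha, beta, epsilon = 1,
                            centric = FALSE) {
  if (any(beta <= 0)) stop("beta must be > 0")
  if (any(f_obs < 0)) stop("f_obs must be >= 0")
  if (any(epsilon < 1)) stop("epsilon must be >= 1")
  n <- max(length(f_obs), length(f_model), length(alpha), length(beta),
           length(epsilon), length(centric))
  f_obs <- rep_len(f_obs, n); f_model <- rep_len(f_model, n)
  alpha <- rep_len(alpha, n); beta <- rep_len(beta, n)
  epsilon <- rep_len(epsilon, n); centric <- rep_len(centric, n)
  eb <- epsilon * beta
  out <- numeric(n)
  a <- !centric
  if (any(a)) {
    out[a] <- log(2 * f_obs[a] / eb[a]) -
      (f_obs[a]^2 + alpha[a]^2 * f_model[a]^2) / eb[a] +
      log_i0(2 * alpha[a] * f_obs[a] * f_model[a] / eb[a])
  }
  if (any(centric)) {
    cc <- centric
    out[cc] <- 0.5 * log(2 / (pi * eb[cc])) -
      (f_obs[cc]^2 + alpha[cc]^2 * f_model[cc]^2) / (2 * eb[cc]) +
      log_cosh(alpha[cc] * f_obs[cc] * f_model[cc] / eb[cc])
  }
  out
}

# first and second derivatives of -log p with respect to f_model
neg_log_p_derivs <- function(f_obs, f_model, alpha, beta, epsilon = 1,
                             centric = FALSE) {
  n <- max(length(f_obs), length(f_model), length(alpha), length(beta),
           length(epsilon), length(centric))
  f_obs <- rep_len(f_obs, n); f_model <- rep_len(f_model, n)
  alpha <- rep_len(alpha, n); beta <- rep_len(beta, n)
  epsilon <- rep_len(epsilon, n); centric <- rep_len(centric, n)
  eb <- epsilon * beta
  g <- numeric(n); h <- numeric(n)
  a <- !centric
  if (any(a)) {
    u <- 2 * alpha[a] * f_obs[a] * f_model[a] / eb[a]
    r <- i1_over_i0(u)
    rp <- ifelse(u > 0, 1 - r / u - r^2, 0.5)
    du <- 2 * alpha[a] * f_obs[a] / eb[a]
    g[a] <- 2 * alpha[a]^2 * f_model[a] / eb[a] - du * r
    h[a] <- 2 * alpha[a]^2 / eb[a] - du^2 * rp
  }
  if (any(centric)) {
    cc <- centric
    u <- alpha[cc] * f_obs[cc] * f_model[cc] / eb[cc]
    du <- alpha[cc] * f_obs[cc] / eb[cc]
    g[cc] <- alpha[cc]^2 * f_model[cc] / eb[cc] - du * tanh(u)
    h[cc] <- alpha[cc]^2 / eb[cc] - du^2 / cosh(u)^2
  }
  list(gradient = g, curvature = h)
}

#' Per-dataset negative log-likelihood
#'
#' Minus the sum of [log_p_amplitude()] over the WORK reflections of one
#' dataset; free reflections are excluded from the refinement target and
#' only enter Rfree reporting.
#'
#' @param refls A [reflection_set()].
#' @param msf A `model_sf` from [model_structure_factors()], or a numeric
#'   vector of model amplitudes `|F_M|`.
#' @param nuis A [nuisance_parameters()] object; defaults to the one stored
#'   in `msf`.
#' @return Scalar negative log-likelihood.
#' @export
dataset_neg_log_likelihood <- function(refls, msf, nuis = NULL) {
  tab <- refls$data
  amp <- if (is.numeric(msf)) msf else msf$amp
  if (is.null(nuis)) {
    if (is.numeric(msf)) stop("nuis required when msf is a plain amplitude vector")
    nuis <- msf$nuisance
  }
  work <- !tab$free
  if (!any(work)) stop("empty work set")
  ab <- shell_alpha_beta(tab$d, nuis)
  -sum(log_p_amplitude(tab$f_obs[work], amp[work], ab$alpha[work],
                       ab$beta[work], tab$epsilon[work], tab$centric[work]))
}

#' Joint multi-condition negative log-likelihood
#'
#' Evaluates the forward model for each dataset with the matching weight
#' column (column j for dataset j) and sums the per-dataset negative
#' log-likelihoods.
#'
#' @param model A [multi_state_model()] with as many weight columns as there
#'   are datasets.
#' @param datasets List of [reflection_set()]s.
#' @param solvent Logical, include the bulk-solvent term.
#' @param nuis_list Optional list of fixed [nuisance_parameters()] (one per
#'   dataset); fitted from the work reflections when NULL.
#' @return List with `per_dataset` (named numeric), `total`, and `msf`
#'   (the per-dataset `model_sf` objects).
#' @export
joint_neg_log_likelihood <- function(model, datasets, solvent = FALSE,
                                     nuis_list = NULL) {
  if (inherits(datasets, "reflection_set")) datasets <- list(datasets)
  J <- length(datasets)
  if (J != n_conditions(model))
    stop("dataset count (", J, ") does not match weight columns (",
         n_conditions(model), ")")
  msf <- vector("list", J)
  nll <- numeric(J)
  for (j in seq_len(J)) {
    nj <- if (is.null(nuis_list)) NULL else nuis_list[[j]]
    msf[[j]] <- model_structure_factors(model, datasets[[j]], condition = j,
                                        nuis = nj, solvent = solvent)
    nll[j] <- dataset_neg_log_likelihood(datasets[[j]], msf[[j]])
  }
  names(nll) <- vapply(datasets, `[[`, "", "condition_id")
  list(per_dataset = nll, total = sum(nll), msf = msf)
}

#' Per-reflection likelihood gradient weights
#'
#' First derivative of minus the amplitude log-likelihood with respect to
#' `|F_M|`, per reflection, together with the curvature used to freeze a
#' local quadratic approximation of the target between refreshes. Free
#' reflections receive 0 (they are not part of the target). The derivative
#' is positive when `|F_M|` exceeds the per-reflection optimum.
#'
#' @inheritParams dataset_neg_log_likelihood
#' @return List with numeric vectors `gradient`, `curvature` and `amp_ref`
#'   (the expansion point).
#' @export
quadratic_gradient_weights <- function(refls, msf, nuis = NULL) {
  tab <- refls$data
  amp <- if (is.numeric(msf)) msf else msf$amp
  if (is.null(nuis)) nuis <- msf$nuisance
  ab <- shell_alpha_beta(tab$d, nuis)
  der <- neg_log_p_derivs(tab$f_obs, amp, ab$alpha, ab$beta,
                          tab$epsilon, tab$centric)
  der$gradient[tab$free] <- 0
  der$curvature[tab$free] <- 0
  list(gradient = der$gradient, curvature = der$curvature, amp_ref = amp)
}

#' Total posterior score
#'
#' The negative log posterior up to additive constants:
#' `S = sum_j (-log L_j) + sum_i E_prior(state i)`, with the partition
#' function and normalization constants dropped.
#'
#' @param model A [multi_state_model()].
#' @param datasets List of [reflection_set()]s (may be empty).
#' @param prior A [forcefield_parameters()] object, or NULL to skip the
#'   prior term.
#' @param solvent Logical, include the bulk-solvent term.
#' @param nuis_list Optional fixed nuisance parameters per dataset.
#' @return Object of class `score_breakdown`: list with `per_dataset_nll`,
#'   `prior_energy` (per state), `total`, and `msf`.
#' @export
total_score <- function(model, datasets, prior = NULL, solvent = FALSE,
                        nuis_list = NULL) {
  if (inherits(datasets, "reflection_set")) datasets <- list(datasets)
  if (length(datasets)) {
    jl <- joint_neg_log_likelihood(model, datasets, solvent, nuis_list)
    nll <- jl$per_dataset; msf <- jl$msf
  } else {
    nll <- numeric(0); msf <- list()
  }
  eprior <- rep(0, n_states(model))
  if (!is.null(prior)) {
    eprior <- vapply(model$states, function(s)
      potential_energy(s, prior)$energy, 0)
  }
  out <- list(per_dataset_nll = nll, prior_energy = eprior,
              total = sum(nll) + sum(eprior), msf = msf)
  structure(out, class = "score_breakdown")
}

#' @export
print.score_breakdown <- function(x, ...) {
  cat(sprintf("<score> S = %.4f  (-logL: %s; prior: %s)\n", x$total,
              paste(sprintf("%.3f", x$per_dataset_nll), collapse = ", "),
              paste(sprintf("%.3f", x$prior_energy), collapse = ", ")))
  invisible(x)
}

#' @method tidy score_breakdown
#' @export
tidy.score_breakdown <- function(x, ...) {
  tibble::tibble(
    term = c(paste0("nll_", seq_along(x$per_dataset_nll)),
             paste0("prior_state_", seq_along(x$prior_energy)), "total"),
    value = c(unname(x$per_dataset_nll), x$prior_energy, x$total))
}
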