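#' Free-set specification
#'
#' @param fraction Fraction of reflections withheld for cross-validation,
#'   in [0, 0.5); default 0.05.
#' @param n_bins Number of resolution bins within which the fraction is
#'   maintained; default 10.
#' @param seed Seed for the random draw.
#' @return Object of class `free_set_spec`.
#' @export
free_set_spec <- function(fraction = 0.05, n_bins = 10, seed = 1) {
  stopifnot(fraction >= 0, fraction < 0.5, n_bins >= 1)
  structure(list(fraction = fraction, n_bins = n_bins, seed = seed),
            class = "free_set_spec")
}

#' Assign a shared free set across datasets
#'
#' Highly correlated datasets must withhold the SAME reflections, otherwise
#' information leaks between one dataset's work set and another's free set.
#' Within each resolution bin of the joint hkl universe,
#' `round(fraction * n_bin)` reflections are drawn uniformly at random
#' (seeded) and flagged free in every dataset.
#'
#' @param refl_list List of [reflection_set()]s sharing an hkl universe
#'   (flags are defined on the union).
#' @param spec A [free_set_spec()].
#' @return The list with updated `free` columns (identical elementwise
#'   across datasets).
#' @export
assign_free_flags <- function(refl_list, spec = free_set_spec()) {
  single <- inherits(refl_list, "reflection_set")
  if (single) refl_list <- list(refl_list)
  keys <- lapply(refl_list, function(r) paste(r$data$h, r$data$k, r$data$l))
  univ <- unique(unlist(keys))
  d_univ <- numeric(length(univ))
  for (r in refl_list) {
    k <- paste(r$data$h, r$data$k, r$data$l)
    d_univ[match(k, univ)] <- r$data$d
  }
  edges <- stats::quantile(d_univ, probs = seq(0, 1, length.out = spec$n_bins + 1),
                           names = FALSE)
  bin <- findInterval(d_univ, edges, rightmost.closed = TRUE, all.inside = TRUE)
  set.seed(spec$seed)
  free_univ <- logical(length(univ))
  n_free_total <- 0L
  for (b in seq_len(spec$n_bins)) {
    idx <- which(bin == b)
    nf <- round(spec$fraction * length(idx))
    if (nf > 0) {
      free_univ[sample(idx, nf)] <- TRUE
      n_free_total <- n_free_total + nf
    }
  }
  if (spec$fraction > 0 && n_free_total == 0L)
    warning("free fraction too small for every bin; zero free set assigned")
  lapply2 <- function(r, k) {
    r$data$free <- free_univ[match(k, univ)]
    r
  }
  out <- Map(lapply2, refl_list, keys)
  if (single) out[[1]] else out
}

#' Crystallographic R factor
#'
#' `R = sum |F_obs - |F_M|| / sum F_obs` over the given reflections
#' (amplitudes are expected to be on a common scale, i.e. after nuisance
#' scaling).
#'
#' @param f_obs Observed amplitudes of the subset.
#' @param f_model Model amplitudes `|F_M|` of the subset.
#' @return Scalar R.
#' @export
r_factor <- function(f_obs, f_model) {
  if (!length(f_obs)) stop("empty reflection subset")
  sum(abs(f_obs - f_model)) / sum(f_obs)
}

#' R factors of a model against datasets
#'
#' Convenience wrapper: evaluates the forward model (with nuisance refit on
#' the work set) for each dataset and reports Rwork/Rfree.
#'
#' @param model A [multi_state_model()].
#' @param datasets List of [reflection_set()]s (one per weight column).
#' @param solvent Include the bulk-solvent term.
#' @return Tibble with columns `dataset, rwork, rfree, n_work, n_free`.
#' @export
model_r_factors <- function(model, datasets, solvent = FALSE) {
  if (inherits(datasets, "reflection_set")) datasets <- list(datasets)
  dplyr::bind_rows(lapply(seq_along(datasets), function(j) {
    msf <- model_structure_factors(model, datasets[[j]], condition = j,
                                   solvent = solvent)
    tab <- datasets[[j]]$data
    tibble::tibble(
      dataset = datasets[[j]]$condition_id,
      rwork = r_factor(tab$f_obs[!tab$free], msf$amp[!tab$free]),
      rfree = if (any(tab$free)) r_factor(tab$f_obs[tab$free], msf$amp[tab$free])
              else NA_real_,
      n_work = sum(!tab$free), n_free = sum(tab$free))
  }))
}

#' Weighted-average model difference (RMSD*)
#'
#' For each condition j, both models are collapsed to their weighted-average
#' structure (atom k at `sum_i w_ij x_ik`); the RMSD between the two
#' averages is computed on raw coordinates in the crystal frame (no
#' superposition by default) and averaged over conditions. The state counts
#' of A and B may differ; compositions must match. Zero if and only if the
#' weighted averages coincide under every condition; invariant to state
#' re-indexing and to the forward model's state-mixing degeneracy.
#'
#' @param a,b [multi_state_model()]s with identical atom composition and the
#'   same number of conditions.
#' @param superpose Optionally least-squares superpose the averages before
#'   the RMSD (not the default; the metric is defined in the crystal frame).
#' @return RMSD* in Angstrom.
#' @export
rmsd_star <- function(a, b, superpose = FALSE) {
  if (!identical(a$states[[1]]$element, b$states[[1]]$element))
    stop("models differ in atom composition")
  J <- n_conditions(a)
  if (J != n_conditions(b)) stop("models differ in condition count")
  avg <- function(m, j) {
    Reduce(`+`, Map(function(s, w) w * s$xyz, m$states, m$weights[, j]))
  }
  mean(vapply(seq_len(J), function(j) {
    xa <- avg(a, j); xb <- avg(b, j)
    if (superpose) xb <- kabsch_superpose(xb, xa)
    sqrt(mean(rowSums((xa - xb)^2)))
  }, 0))
}

# least-squares superposition of x onto target (rotation + translation)
kabsch_superpose <- function(x, target) {
  cx <- colMeans(x); ct <- colMeans(target)
  xc <- sweep(x, 2, cx); tc <- sweep(target, 2, ct)
  s <- svd(crossprod(xc, tc))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(xc %*% t(R), 2, ct, `+`)
}

#' Select the best-scoring record of a sample
#'
#' @param sample An `msx_sample` from [sampling_protocol()].
#' @param dataset_id Condition label whose Rfree is minimized (ignored for
#'   `criterion = "score"`).
#' @param criterion `"rfree"` (default) or `"score"` (total posterior
#'   score). Ties break by lower total score, then earlier trajectory.
#' @return The winning sample record.
#' @export
select_best <- function(sample, dataset_id = NULL, criterion = c("rfree", "score")) {
  criterion <- match.arg(criterion)
  recs <- sample$records
  if (!length(recs)) stop("empty sample")
  key <- vapply(recs, function(r) {
    if (criterion == "score") r$score$total
    else {
      if (is.null(dataset_id)) stop("dataset_id required for rfree criterion")
      v <- r$r$rfree[r$r$dataset == dataset_id]
      if (!length(v)) stop("dataset '", dataset_id, "' not in sample records")
      v
    }
  }, 0)
  score <- vapply(recs, function(r) r$score$total, 0)
  traj <- vapply(recs, function(r) as.numeric(r$trajectory), 0)
  ord <- order(key, score, traj)
  recs[[ord[1]]]
}

#' Sampling convergence curve
#'
#' For each subsample size s, draws `n_resamples` random subsets of s
#' trajectories and records the best criterion value within each subset;
#' reports mean and standard deviation per size. With the criterion being a
#' minimum, the mean best value is non-increasing in s for nested draws.
#'
#' @param sample An `msx_sample`.
#' @param subsample_sizes Integer vector of trajectory-subset sizes.
#' @param n_resamples Random subsets per size (default 1000).
#' @param seed Seed for the resampling.
#' @param criterion `"score"` (best total score) or `"accuracy"` (best
#'   RMSD* against `native`).
#' @param native Reference [multi_state_model()] for the accuracy criterion.
#' @return Tibble `size, mean, sd` of class `convergence_curve`.
#' @export
convergence_curve <- function(sample, subsample_sizes, n_resamples = 1000,
                              seed = 1, criterion = c("score", "accuracy"),
                              native = NULL) {
  criterion <- match.arg(criterion)
  recs <- sample$records
  tids <- vapply(recs, function(r) as.integer(r$trajectory), 0L)
  utids <- sort(unique(tids))
  if (any(subsample_sizes > length(utids)))
    stop("subsample size exceeds trajectory count (", length(utids), ")")
  val <- switch(criterion,
    score = vapply(recs, function(r) r$score$total, 0),
    accuracy = {
      if (is.null(native)) stop("native model required for accuracy criterion")
      vapply(recs, function(r) rmsd_star(r$model, native), 0)
    })
  per_traj_best <- vapply(utids, function(t) min(val[tids == t]), 0)
  set.seed(seed)
  out <- lapply(subsample_sizes, function(s) {
    if (s == length(utids)) {
      best <- rep(min(per_traj_best), n_resamples)
    } else {
      best <- vapply(seq_len(n_resamples), function(k)
        min(per_traj_best[sample.int(length(utids), s)]), 0)
    }
    tibble::tibble(size = s, mean = mean(best), sd = stats::sd(best))
  })
  structure(dplyr::bind_rows(out),
            class = c("convergence_curve", "tbl_df", "tbl", "data.frame"),
            criterion = criterion)
}

#' Decoy score/accuracy landscape
#'
#' Scores every decoy (joint negative log-likelihood across all datasets,
#' with per-decoy nuisance refit) and pairs it with its accuracy, the RMSD*
#' to the native. Reports how many decoys score better than the native.
#'
#' @param decoys List of [multi_state_model()]s sharing the native's
#'   composition.
#' @param native The reference [multi_state_model()].
#' @param datasets List of [reflection_set()]s.
#' @return Tibble of class `decoy_landscape` with columns
#'   `model, accuracy, score, native` (the native is the last row);
#'   attribute `n_better` counts decoys scoring below the native.
#' @export
decoy_landscape <- function(decoys, native, datasets) {
  if (inherits(datasets, "reflection_set")) datasets <- list(datasets)
  score_of <- function(m) joint_neg_log_likelihood(m, datasets)$total
  rows <- lapply(seq_along(decoys), function(k) {
    tibble::tibble(model = k, accuracy = rmsd_star(decoys[[k]], native),
                   score = score_of(decoys[[k]]), native = FALSE)
  })
  nat <- tibble::tibble(model = NA_integer_, accuracy = 0,
                        score = score_of(native), native = TRUE)
  out <- dplyr::bind_rows(c(rows, list(nat)))
  structure(out, class = c("decoy_landscape", class(out)),
            n_better = sum(out$score[!out$native] < nat$score))
}

#' Benchmark-style summary table of best models
#'
#' The per-dataset best-by-Rfree record of a sample, with both Rwork and
#' Rfree reported.
#'
#' @param sample An `msx_sample`.
#' @param datasets The datasets the sample was computed against.
#' @return Tibble `dataset, states, conditions, rwork, rfree`.
#' @export
summarize_best_models <- function(sample, datasets) {
  if (inherits(datasets, "reflection_set")) datasets <- list(datasets)
  dplyr::bind_rows(lapply(datasets, function(ds) {
    best <- select_best(sample, ds$condition_id, "rfree")
    rrow <- best$r[best$r$dataset == ds$condition_id, ]
    tibble::tibble(dataset = ds$condition_id,
                   states = n_states(best$model),
                   conditions = n_conditions(best$model),
                   rwork = rrow$rwork, rfree = rrow$rfree)
  }))
}
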