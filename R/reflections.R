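#' Reflection sets
#'
#' A reflection set holds symmetry-unique Miller indices with their observed
#' amplitudes, uncertainties and cross-validation flags for one experimental
#' condition, together with the unit cell and symmetry used to annotate them.
#' The tabular part is a tibble with columns
#' `h, k, l, d, centric, epsilon, f_obs, sigma, free`.
#'
#' Incoming indices are reduced to a canonical asymmetric-unit representative
#' (lexicographically largest symmetry/Friedel equivalent); duplicates after
#' reduction with conflicting amplitudes are an error, consistent duplicates
#' are merged. Systematically absent reflections are rejected.
#'
#' @param data A data frame with columns `h,k,l,f_obs` and optionally
#'   `sigma` (default 0) and `free` (default FALSE).
#' @param cell An [unit_cell()].
#' @param ops An [symmetry_ops()] set.
#' @param condition_id Label for the experimental condition (e.g. a
#'   temperature); defaults to `"cond1"`.
#' @return An object of class `reflection_set`.
#' @export
reflection_set <- function(data, cell, ops = symmetry_ops("P1"),
                           condition_id = "cond1") {
  stopifnot(is.data.frame(data), inherits(cell, "xtal_cell"),
            inherits(ops, "xtal_symops"))
  need <- c("h", "k", "l", "f_obs")
  if (!all(need %in% names(data)))
    stop("reflection data must have columns h, k, l, f_obs")
  if (!"sigma" %in% names(data)) {
    warning("missing sigma column; sigmas set to 0")
    data$sigma <- 0
  }
  if (!"free" %in% names(data)) data$free <- FALSE
  if (any(data$f_obs < 0)) stop("negative observed amplitudes")

  H <- asu_reduce(as.matrix(data[, c("h", "k", "l")]), ops)
  key <- paste(H[, 1], H[, 2], H[, 3])
  if (anyDuplicated(key)) {
    split_f <- split(data$f_obs, key)
    bad <- names(split_f)[vapply(split_f, function(f) diff(range(f)) > 1e-6 * max(f, 1), TRUE)]
    if (length(bad))
      stop("duplicate hkl after symmetry reduction with conflicting f_obs: ", bad[[1]])
    keep <- !duplicated(key)
    data <- data[keep, , drop = FALSE]; H <- H[keep, , drop = FALSE]
  }
  cls <- classify_reflection(H, ops)
  if (any(cls$absent))
    stop("systematically absent reflection in data: (",
         paste(H[which(cls$absent)[1], ], collapse = " "), ")")
  tab <- tibble::tibble(
    h = H[, 1], k = H[, 2], l = H[, 3],
    d = resolution_of(H, cell),
    centric = cls$centric, epsilon = cls$epsilon,
    f_obs = as.numeric(data$f_obs), sigma = as.numeric(data$sigma),
    free = as.logical(data$free))
  structure(list(cell = cell, ops = ops, data = tab, condition_id = condition_id),
            class = "reflection_set")
}

#' @export
print.reflection_set <- function(x, ...) {
  cat(sprintf("<reflection set> '%s': %d unique reflections, %.2f-%.2f A, %d free\n",
              x$condition_id, nrow(x$data), max(x$data$d), min(x$data$d),
              sum(x$data$free)))
  invisible(x)
}

#' @method as_tibble reflection_set
#' @export
as_tibble.reflection_set <- function(x, ...) x$data

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Enumerate a complete unique reflection list to a resolution limit
#'
#' All symmetry-unique, non-absent Miller indices with `d >= d_min`
#' (excluding (0,0,0)).
#'
#' @param cell An [unit_cell()].
#' @param ops An [symmetry_ops()] set.
#' @param d_min Resolution limit in Angstrom.
#' @return Integer matrix (n x 3) of unique Miller indices.
#' @export
generate_hkl <- function(cell, ops, d_min) {
  stopifnot(d_min > 0)
  hmax <- ceiling(cell$a / d_min); kmax <- ceiling(cell$b / d_min)
  lmax <- ceiling(cell$c / d_min)
  grid <- as.matrix(expand.grid(h = -hmax:hmax, k = -kmax:kmax, l = -lmax:lmax))
  grid <- grid[rowSums(grid != 0) > 0, , drop = FALSE]
  d <- resolution_of(grid, cell)
  grid <- grid[d >= d_min, , drop = FALSE]
  red <- asu_reduce(grid, ops)
  red <- red[!duplicated(paste(red[, 1], red[, 2], red[, 3])), , drop = FALSE]
  cls <- classify_reflection(red, ops)
  red <- red[!cls$absent, , drop = FALSE]
  storage.mode(red) <- "integer"
  dimnames(red) <- list(NULL, c("h", "k", "l"))
  red
}
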