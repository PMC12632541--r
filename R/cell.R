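#' Unit cell
#'
#' Construct a crystallographic unit cell from lengths (Angstrom) and angles
#' (degrees). The cell must have positive volume (non-degenerate metric).
#'
#' @param a,b,c Cell edge lengths in Angstrom, all > 0.
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180).
#' @return An object of class `xtal_cell` with fields `a,b,c,alpha,beta,gamma`
#'   and cached `volume` (Angstrom^3).
#' @examples
#' unit_cell(10, 10, 10)
#' unit_cell(7, 9, 11, 80, 95, 103)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  len <- c(a, b, c); ang <- c(alpha, beta, gamma)
  if (!all(is.finite(len)) || any(len <= 0))
    stop("unit cell lengths must be positive and finite")
  if (!all(is.finite(ang)) || any(ang <= 0) || any(ang >= 180))
    stop("unit cell angles must lie in (0, 180) degrees")
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180); cg <- cos(gamma * pi / 180)
  det_metric <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (det_metric <= 0) stop("degenerate unit cell: metric tensor determinant <= 0")
  cell <- list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma,
               volume = a * b * c * sqrt(det_metric))
  structure(cell, class = "xtal_cell")
}

#' @export
print.xtal_cell <- function(x, ...) {
  cat(sprintf("<unit cell> a=%.3f b=%.3f c=%.3f  alpha=%.2f beta=%.2f gamma=%.2f  V=%.1f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}

#' Fractional-to-Cartesian orthogonalization matrix
#'
#' Standard crystallographic convention: `a` along x, `b` in the xy plane.
#' Cartesian coordinates are `M %*% x_frac` (Angstrom).
#'
#' @param cell An [unit_cell()].
#' @return A 3x3 numeric matrix `M`; `solve(M)` fractionalizes.
#' @export
orthogonalization_matrix <- function(cell) {
  stopifnot(inherits(cell, "xtal_cell"))
  ca <- cos(cell$alpha * pi / 180); cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180); sg <- sin(cell$gamma * pi / 180)
  v <- cell$volume / (cell$a * cell$b * cell$c)
  matrix(c(cell$a, cell$b * cg, cell$c * cb,
           0,      cell$b * sg, cell$c * (ca - cb * cg) / sg,
           0,      0,           cell$c * v / sg),
         nrow = 3, byrow = TRUE)
}

#' Resolution of reflections
#'
#' d-spacing of Miller indices from the reciprocal metric of the cell,
#' `d = 1 / |t(solve(M)) %*% h|`.
#'
#' @param hkl Integer vector of length 3 or an n x 3 matrix of Miller indices.
#' @param cell An [unit_cell()].
#' @return Resolution(s) in Angstrom.
#' @export
resolution_of <- function(hkl, cell) {
  H <- rbind(hkl)
  storage.mode(H) <- "double"
  if (ncol(H) != 3) stop("hkl must have 3 columns")
  if (any(rowSums(H != 0) == 0)) stop("undefined resolution: hkl = (0,0,0)")
  S <- H %*% solve(orthogonalization_matrix(cell))   # scattering vectors, A^-1
  d <- 1 / sqrt(rowSums(S^2))
  if (is.vector(hkl)) d[[1]] else d
}

#' Scattering vectors in Cartesian reciprocal space
#'
#' @param hkl n x 3 matrix of Miller indices.
#' @param cell An [unit_cell()].
#' @return n x 3 matrix of reciprocal vectors (A^-1); row norms are `1/d`.
#' @keywords internal
scattering_vectors <- function(hkl, cell) {
  H <- rbind(hkl); storage.mode(H) <- "double"
  H %*% solve(orthogonalization_matrix(cell))
}
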