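#' Atomic scattering factors
#'
#' Isolated-atom X-ray scattering factors in the standard 4-Gaussian +
#' constant parameterization, `f(s) = sum_i a_i exp(-b_i s^2) + c` with
#' `s = sin(theta)/lambda` in 1/Angstrom. Coefficients for the elements
#' common in proteins (H, C, N, O, S, P, Zn) are embedded (International
#' Tables values); other elements can be supplied with
#' [load_form_factor_table()].
#'
#' @format Internal data frame, one row per element.
#' @name form-factors
NULL

.builtin_form_factors <- local({
  m <- rbind(
    H  = c(0.493002, 0.322912, 0.140191, 0.040810, 10.5109, 26.1257, 3.14236, 57.7997, 0.003038),
    C  = c(2.31000, 1.02000, 1.58860, 0.86500, 20.8439, 10.2075, 0.56870, 51.6512, 0.21560),
    N  = c(12.2126, 3.13220, 2.01250, 1.16630, 0.00570, 9.89330, 28.9975, 0.58260, -11.5290),
    O  = c(3.04850, 2.28680, 1.54630, 0.86700, 13.2771, 5.70110, 0.32390, 32.9089, 0.25080),
    P  = c(6.43450, 4.17910, 1.78000, 1.49080, 1.90670, 27.1570, 0.52600, 68.1645, 1.11490),
    S  = c(6.90530, 5.20340, 1.43790, 1.58630, 1.46790, 22.2151, 0.25360, 56.1720, 0.86690),
    Zn = c(14.0743, 7.03180, 5.16520, 2.41000, 3.26550, 0.23330, 10.3163, 58.7097, 1.30410))
  colnames(m) <- c(paste0("a", 1:4), paste0("b", 1:4), "c")
  m
})

form_factor_env <- new.env(parent = emptyenv())
form_factor_env$table <- .builtin_form_factors

#' Load extra scattering-factor coefficients from a table file
#'
#' The file is whitespace- or comma-separated plain text with columns
#' `element a1 a2 a3 a4 b1 b2 b3 b4 c` (header optional). Loaded entries
#' extend or override the built-in table for the rest of the session.
#'
#' @param path Path to the coefficient file.
#' @return Invisibly, the updated coefficient matrix.
#' @export
load_form_factor_table <- function(path) {
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#", sep = "")
  if (is.character(raw[1, 2])) raw <- utils::read.table(path, header = TRUE)
  if (ncol(raw) != 10) stop("form-factor table must have 10 columns: element a1..a4 b1..b4 c")
  m <- as.matrix(raw[, -1]); rownames(m) <- raw[, 1]
  colnames(m) <- colnames(.builtin_form_factors)
  tab <- form_factor_env$table
  tab <- rbind(tab[!rownames(tab) %in% rownames(m), , drop = FALSE], m)
  form_factor_env$table <- tab
  invisible(tab)
}

#' Evaluate atomic scattering factors
#'
#' @param element Element symbol(s).
#' @param stol `sin(theta)/lambda` in 1/Angstrom (vector); equals `1/(2 d)`.
#' @return If both arguments have length 1, a scalar; if one element and
#'   many stol, a vector; otherwise a `length(stol) x length(element)` matrix.
#' @examples
#' form_factor("C", 0)      # ~ 6 electrons
#' form_factor("O", 0.25)
#' @export
form_factor <- function(element, stol) {
  stopifnot(all(stol >= 0))
  tab <- form_factor_env$table
  unknown <- setdiff(unique(element), rownames(tab))
  if (length(unknown))
    stop("unknown element(s) in form-factor table: ", paste(unknown, collapse = ", "))
  s2 <- stol^2
  f <- vapply(element, function(el) {
    p <- tab[el, ]
    p[["a1"]] * exp(-p[["b1"]] * s2) + p[["a2"]] * exp(-p[["b2"]] * s2) +
      p[["a3"]] * exp(-p[["b3"]] * s2) + p[["a4"]] * exp(-p[["b4"]] * s2) + p[["c"]]
  }, numeric(length(s2)))
  if (length(element) == 1L) as.vector(f) else f
}

#' Atomic masses (amu) for the shipped elements
#' @param element Element symbol(s).
#' @return Numeric vector of masses.
#' @export
element_mass <- function(element) {
  masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
              P = 30.974, S = 32.06, Zn = 65.38)
  unknown <- setdiff(unique(element), names(masses))
  if (length(unknown)) stop("unknown element(s): ", paste(unknown, collapse = ", "))
  unname(masses[element])
}
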