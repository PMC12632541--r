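#' Symmetry operator sets
#'
#' A space group is supplied as an explicit list of (rotation, translation)
#' pairs acting on fractional coordinates, `x' = R x + t`. A small built-in
#' table covers the groups used by the toy benchmarks: `"P1"`, `"P-1"`, `"P2"`
#' (unique axis b), `"P212121"` and `"C2"`. No general space-group symbol
#' parser is provided.
#'
#' On construction the set is validated: it must contain the identity and be
#' closed under composition (translations compared modulo 1).
#'
#' @param group Either a built-in symbol (character) or a list of operators,
#'   each a `list(R = <3x3 integer matrix>, t = <length-3 fractional shift>)`.
#' @return An object of class `xtal_symops`: a list of operators with a
#'   `name` attribute.
#' @examples
#' symmetry_ops("P212121")
#' @export
symmetry_ops <- function(group = "P1") {
  if (is.character(group)) {
    ops <- builtin_symmetry_table()[[group]]
    if (is.null(ops)) {
      stop("unknown built-in symmetry group '", group, "'; available: ",
           paste(names(builtin_symmetry_table()), collapse = ", "))
    }
    name <- group
  } else {
    ops <- lapply(group, function(op) {
      R <- matrix(as.integer(op$R), 3, 3)
      list(R = R, t = as.numeric(op$t) %% 1)
    })
    name <- "custom"
  }
  validate_symops(ops)
  structure(ops, class = "xtal_symops", name = name)
}

#' @export
print.xtal_symops <- function(x, ...) {
  cat(sprintf("<symmetry ops> %s (%d operators)\n", attr(x, "name"), length(x)))
  invisible(x)
}

op_xyz <- function(R, t) list(R = matrix(as.integer(R), 3, 3, byrow = TRUE), t = t)

builtin_symmetry_table <- function() {
  I3 <- diag(3)
  list(
    "P1" = list(op_xyz(I3, c(0, 0, 0))),
    "P-1" = list(op_xyz(I3, c(0, 0, 0)), op_xyz(-I3, c(0, 0, 0))),
    "P2" = list(op_xyz(I3, c(0, 0, 0)),
                op_xyz(diag(c(-1, 1, -1)), c(0, 0, 0))),
    "P212121" = list(op_xyz(I3, c(0, 0, 0)),
                     op_xyz(diag(c(-1, -1, 1)), c(0.5, 0, 0.5)),
                     op_xyz(diag(c(-1, 1, -1)), c(0, 0.5, 0.5)),
                     op_xyz(diag(c(1, -1, -1)), c(0.5, 0.5, 0))),
    "C2" = list(op_xyz(I3, c(0, 0, 0)),
                op_xyz(diag(c(-1, 1, -1)), c(0, 0, 0)),
                op_xyz(I3, c(0.5, 0.5, 0)),
                op_xyz(diag(c(-1, 1, -1)), c(0.5, 0.5, 0)))
  )
}

validate_symops <- function(ops) {
  key <- function(R, t) paste(c(as.integer(R), round(as.numeric(t) %% 1, 9)), collapse = ",")
  keys <- vapply(ops, function(op) key(op$R, op$t), "")
  if (!key(diag(3), c(0, 0, 0)) %in% keys)
    stop("symmetry operator list does not contain the identity")
  if (anyDuplicated(keys)) stop("duplicate symmetry operators")
  for (a in ops) for (b in ops) {
    Rab <- a$R %*% b$R
    tab <- (as.numeric(a$R %*% b$t) + a$t) %% 1
    if (!key(Rab, tab) %in% keys)
      stop("symmetry operator list is not closed under composition")
  }
  invisible(TRUE)
}

#' Centric/epsilon classification of reflections
#'
#' A reflection h is centric if some rotation R of the group satisfies
#' `h R = -h` (its phase is symmetry-restricted). The intensity-enhancement
#' factor epsilon is `|sum over ops with h R = h of exp(2 pi i h.t)|`: the
#' count of phase-consistent operators fixing h. A value of 0 marks a
#' systematic absence (`absent = TRUE`, epsilon reported as 0).
#'
#' @param hkl Length-3 integer vector or n x 3 matrix of Miller indices.
#' @param ops An [symmetry_ops()] set.
#' @return A tibble with columns `h,k,l,centric,epsilon,absent` (single rows
#'   are still returned as a tibble).
#' @export
classify_reflection <- function(hkl, ops) {
  stopifnot(inherits(ops, "xtal_symops"))
  H <- rbind(hkl); storage.mode(H) <- "integer"
  n <- nrow(H)
  centric <- logical(n); eps <- integer(n); absent <- logical(n)
  Rs <- lapply(ops, `[[`, "R"); ts <- lapply(ops, `[[`, "t")
  for (i in seq_len(n)) {
    h <- H[i, ]
    s <- 0 + 0i; cen <- FALSE
    for (k in seq_along(Rs)) {
      hR <- as.integer(h %*% Rs[[k]])
      if (all(hR == h)) s <- s + exp(2i * pi * sum(h * ts[[k]]))
      if (all(hR == -h)) cen <- TRUE
    }
    m <- Mod(s)
    centric[i] <- cen
    absent[i] <- m < 1e-9
    eps[i] <- as.integer(round(m))
  }
  tibble::tibble(h = H[, 1], k = H[, 2], l = H[, 3],
                 centric = centric, epsilon = eps, absent = absent)
}

#' Reduce Miller indices to a canonical asymmetric-unit representative
#'
#' The orbit of h under all rotations and Friedel inversion is enumerated and
#' the lexicographically largest (h, k, l) member is kept.
#'
#' @param hkl n x 3 matrix of Miller indices.
#' @param ops An [symmetry_ops()] set.
#' @return n x 3 integer matrix of canonical representatives.
#' @export
asu_reduce <- function(hkl, ops) {
  H <- rbind(hkl); storage.mode(H) <- "integer"
  Rs <- lapply(ops, `[[`, "R")
  out <- H
  for (i in seq_len(nrow(H))) {
    h <- H[i, ]
    best <- NULL
    for (R in Rs) {
      for (sgn in c(1L, -1L)) {
        cand <- as.integer(sgn * (h %*% R))
        if (is.null(best) || lex_gt(cand, best)) best <- cand
      }
    }
    out[i, ] <- best
  }
  out
}

lex_gt <- function(a, b) {
  for (i in 1:3) {
    if (a[i] > b[i]) return(TRUE)
    if (a[i] < b[i]) return(FALSE)
  }
  FALSE
}
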