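#' Force-field parameters
#'
#' Parameter tables for the simplified molecular-mechanics prior: harmonic
#' bonds and angles, periodic dihedrals, harmonic impropers, and
#' Lennard-Jones nonbonded terms (CHARMM `eps, Rmin/2` convention with
#' geometric/arithmetic combining). Electrostatics are deliberately absent.
#' Units: kcal/mol, Angstrom, degrees in the tables (radians internally).
#'
#' @param bonds Tibble `t1,t2,k,b0` (k in kcal/mol/A^2, b0 in A).
#' @param angles Tibble `t1,t2,t3,k,theta0` (k in kcal/mol/rad^2, theta0 deg).
#' @param dihedrals Tibble `t1,t2,t3,t4,k,n,delta` (delta in degrees; type
#'   "X" is a wildcard for the outer atoms).
#' @param impropers Tibble `t1,t2,t3,t4,k,omega0` (omega0 in degrees).
#' @param nonbonded Tibble `type,eps,rmin_half` (eps > 0 in kcal/mol,
#'   Rmin/2 in A).
#' @return Object of class `forcefield_parameters`.
#' @export
forcefield_parameters <- function(bonds, angles, dihedrals, impropers, nonbonded) {
  ff <- list(bonds = tibble::as_tibble(bonds), angles = tibble::as_tibble(angles),
             dihedrals = tibble::as_tibble(dihedrals),
             impropers = tibble::as_tibble(impropers),
             nonbonded = tibble::as_tibble(nonbonded))
  for (nm in c("bonds", "angles", "dihedrals", "impropers"))
    if (nrow(ff[[nm]]) && any(ff[[nm]]$k < 0))
      stop("negative force constant in ", nm)
  if (any(ff$nonbonded$rmin_half <= 0)) stop("Rmin/2 must be positive")
  structure(ff, class = "forcefield_parameters")
}

#' @export
print.forcefield_parameters <- function(x, ...) {
  cat(sprintf("<force field> %d bond, %d angle, %d dihedral, %d improper, %d atom types\n",
              nrow(x$bonds), nrow(x$angles), nrow(x$dihedrals),
              nrow(x$impropers), nrow(x$nonbonded)))
  invisible(x)
}

#' Read force-field parameters from a sectioned text file
#'
#' The dialect mirrors the CHARMM parameter-file layout for the sections
#' used here: lines under `BONDS` (`t1 t2 k b0`), `ANGLES`
#' (`t1 t2 t3 k theta0`), `DIHEDRALS` (`t1 t2 t3 t4 k n delta`),
#' `IMPROPERS` (`t1 t2 t3 t4 k omega0`) and `NONBONDED`
#' (`type eps rmin_half`). `!` and `#` start comments.
#'
#' @param path Path to the parameter file.
#' @return A [forcefield_parameters()] object.
#' @export
load_forcefield <- function(path) {
  lines <- readLines(path)
  lines <- sub("[!#].*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  secs <- c("BONDS", "ANGLES", "DIHEDRALS", "IMPROPERS", "NONBONDED")
  cur <- NULL
  store <- setNames(vector("list", length(secs)), secs)
  for (ln in lines) {
    up <- toupper(ln)
    if (up %in% secs) { cur <- up; next }
    if (is.null(cur)) stop("parameter line before any section header: ", ln)
    store[[cur]] <- c(store[[cur]], list(strsplit(ln, "[[:space:]]+")[[1]]))
  }
  parse_sec <- function(rows, n_str, cols) {
    if (!length(rows)) {
      out <- lapply(seq_along(cols), function(i) if (i <= n_str) character() else numeric())
      names(out) <- cols
      return(tibble::as_tibble(out))
    }
    m <- do.call(rbind, rows)
    if (ncol(m) != length(cols)) stop("malformed parameter line: ", paste(rows[[1]], collapse = " "))
    out <- as.data.frame(m, stringsAsFactors = FALSE)
    names(out) <- cols
    for (i in seq_along(cols)[-seq_len(n_str)]) out[[i]] <- as.numeric(out[[i]])
    tibble::as_tibble(out)
  }
  forcefield_parameters(
    bonds = parse_sec(store$BONDS, 2, c("t1", "t2", "k", "b0")),
    angles = parse_sec(store$ANGLES, 3, c("t1", "t2", "t3", "k", "theta0")),
    dihedrals = parse_sec(store$DIHEDRALS, 4, c("t1", "t2", "t3", "t4", "k", "n", "delta")),
    impropers = parse_sec(store$IMPROPERS, 4, c("t1", "t2", "t3", "t4", "k", "omega0")),
    nonbonded = parse_sec(store$NONBONDED, 1, c("type", "eps", "rmin_half")))
}

#' Write force-field parameters to the sectioned text dialect
#'
#' Round-trips bit-exactly with [load_forcefield()] (full-precision
#' coefficients).
#'
#' @param params A [forcefield_parameters()] object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_forcefield <- function(params, path) {
  fmt_row <- function(row) paste(vapply(row, function(v) {
    if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
  }, ""), collapse = " ")
  out <- character()
  for (sec in c("bonds", "angles", "dihedrals", "impropers", "nonbonded")) {
    out <- c(out, toupper(sec))
    tab <- params[[sec]]
    for (r in seq_len(nrow(tab))) out <- c(out, fmt_row(as.list(tab[r, ])))
  }
  writeLines(out, path)
  invisible(path)
}

#' Built-in minimal force field for the toy systems
#'
#' Alanine-like backbone and side-chain types sufficient to parameterize the
#' synthetic peptide-like chains: types `NB` (backbone amide N), `CA`
#' (alpha carbon), `CC` (carbonyl C), `OC` (carbonyl O), `CB` (side-chain
#' carbon), `HB` (side-chain hydrogen). Values are in the range of the
#' CHARMM22 protein parameter set.
#'
#' @return A [forcefield_parameters()] object.
#' @export
toy_forcefield <- function() {
  forcefield_parameters(
    bonds = tibble::tribble(
      ~t1, ~t2, ~k, ~b0,
      "NB", "CA", 320.0, 1.455,
      "CA", "CC", 250.0, 1.522,
      "CC", "OC", 620.0, 1.230,
      "CC", "NB", 370.0, 1.345,
      "CA", "CB", 222.5, 1.538,
      "CB", "HB", 322.0, 1.111),
    angles = tibble::tribble(
      ~t1, ~t2, ~t3, ~k, ~theta0,
      "NB", "CA", "CC", 50.0, 107.0,
      "CA", "CC", "OC", 80.0, 121.0,
      "CA", "CC", "NB", 80.0, 116.5,
      "OC", "CC", "NB", 80.0, 122.5,
      "CC", "NB", "CA", 50.0, 120.0,
      "NB", "CA", "CB", 70.0, 110.0,
      "CC", "CA", "CB", 52.0, 108.0,
      "CA", "CB", "HB", 33.4, 110.1,
      "HB", "CB", "HB", 35.5, 108.4),
    dihedrals = tibble::tribble(
      ~t1, ~t2, ~t3, ~t4, ~k, ~n, ~delta,
      "X", "CA", "CC", "X", 0.20, 3, 0,
      "X", "NB", "CA", "X", 0.30, 3, 0,
      "X", "CC", "NB", "X", 1.60, 2, 180,
      "X", "CA", "CB", "X", 0.16, 3, 0),
    impropers = tibble::tribble(
      ~t1, ~t2, ~t3, ~t4, ~k, ~omega0,
      "CC", "CA", "NB", "OC", 120.0, 0),
    nonbonded = tibble::tribble(
      ~type, ~eps, ~rmin_half,
      "NB", 0.20, 1.85,
      "CA", 0.02, 2.275,
      "CC", 0.11, 2.00,
      "OC", 0.12, 1.70,
      "CB", 0.08, 2.06,
      "HB", 0.022, 1.32))
}
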