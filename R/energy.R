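#' Resolve a topology against force-field parameters
#'
#' Looks up every bonded term and builds the nonbonded pair list (all pairs
#' minus 1-2 and 1-3 exclusions; 1-4 pairs carry a configurable scale).
#' A missing parameter is an error naming the offending type tuple.
#'
#' @param topo A [topology()].
#' @param params A [forcefield_parameters()] object.
#' @param scale_14 Scale factor applied to 1-4 Lennard-Jones pairs
#'   (default 1).
#' @return An internal resolved-parameter list, reusable across calls to
#'   [potential_energy()] for states sharing this topology.
#' @export
resolve_forcefield <- function(topo, params, scale_14 = 1) {
  ty <- topo$types
  key2 <- function(a, b) paste(pmin(a, b), pmax(a, b))
  bonds <- topo$bonds
  bk <- key2(ty[bonds[, 1]], ty[bonds[, 2]])
  pk <- key2(params$bonds$t1, params$bonds$t2)
  m <- match(bk, pk)
  if (anyNA(m) && nrow(bonds))
    stop("missing bond parameter for type pair: ", bk[which(is.na(m))[1]])
  bond_k <- params$bonds$k[m]; bond_b0 <- params$bonds$b0[m]

  ang <- topo$angles
  ak <- paste(pmin(ty[ang[, 1]], ty[ang[, 3]]), ty[ang[, 2]],
              pmax(ty[ang[, 1]], ty[ang[, 3]]))
  apk <- paste(pmin(params$angles$t1, params$angles$t3), params$angles$t2,
               pmax(params$angles$t1, params$angles$t3))
  m <- match(ak, apk)
  if (anyNA(m) && nrow(ang))
    stop("missing angle parameter for type triple: ", ak[which(is.na(m))[1]])
  ang_k <- params$angles$k[m]; ang_t0 <- params$angles$theta0[m] * pi / 180

  dih <- topo$dihedrals
  lookup_4 <- function(tab, t1, t2, t3, t4, wildcard = TRUE) {
    keyf <- paste(tab$t1, tab$t2, tab$t3, tab$t4)
    cand <- c(paste(t1, t2, t3, t4), paste(t4, t3, t2, t1))
    if (wildcard) cand <- c(cand, paste("X", t2, t3, "X"), paste("X", t3, t2, "X"))
    for (k in cand) {
      i <- match(k, keyf)
      if (!is.na(i)) return(i)
    }
    NA_integer_
  }
  dm <- integer(nrow(dih))
  for (i in seq_len(nrow(dih))) {
    dm[i] <- lookup_4(params$dihedrals, ty[dih[i, 1]], ty[dih[i, 2]],
                      ty[dih[i, 3]], ty[dih[i, 4]])
    if (is.na(dm[i]))
      stop("missing dihedral parameter for type quadruple: ",
           paste(ty[dih[i, ]], collapse = " "))
  }
  dih_k <- params$dihedrals$k[dm]; dih_n <- params$dihedrals$n[dm]
  dih_d <- params$dihedrals$delta[dm] * pi / 180

  imp <- topo$impropers
  im <- integer(nrow(imp))
  for (i in seq_len(nrow(imp))) {
    im[i] <- lookup_4(params$impropers, ty[imp[i, 1]], ty[imp[i, 2]],
                      ty[imp[i, 3]], ty[imp[i, 4]], wildcard = FALSE)
    if (is.na(im[i]))
      stop("missing improper parameter for type quadruple: ",
           paste(ty[imp[i, ]], collapse = " "))
  }
  imp_k <- params$impropers$k[im]; imp_w0 <- params$impropers$omega0[im] * pi / 180

  nb <- params$nonbonded
  tm <- match(ty, nb$type)
  if (anyNA(tm))
    stop("missing nonbonded parameter for atom type: ", ty[which(is.na(tm))[1]])
  n <- length(ty)
  # exclusion bookkeeping: bonded graph distances 1 (1-2), 2 (1-3), 3 (1-4)
  adj <- lapply(seq_len(n), function(i) integer())
  for (r in seq_len(nrow(bonds))) {
    i <- bonds[r, 1]; j <- bonds[r, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  excl12 <- paste(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
  excl13 <- character(); pair14 <- character()
  for (i in seq_len(n)) {
    for (j in adj[[i]]) for (k in adj[[j]]) if (k != i)
      excl13 <- c(excl13, paste(min(i, k), max(i, k)))
  }
  for (r in seq_len(nrow(bonds))) {
    j <- bonds[r, 1]; k <- bonds[r, 2]
    for (i in setdiff(adj[[j]], k)) for (l in setdiff(adj[[k]], j))
      if (i != l) pair14 <- c(pair14, paste(min(i, l), max(i, l)))
  }
  allp <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pkey <- paste(allp[, 1], allp[, 2])
  keep <- !(pkey %in% c(excl12, excl13))
  pairs <- allp[keep, , drop = FALSE]
  pkey <- pkey[keep]
  scale <- ifelse(pkey %in% pair14, scale_14, 1)
  eps_i <- nb$eps[tm]; rh_i <- nb$rmin_half[tm]
  list(bonds = bonds, bond_k = bond_k, bond_b0 = bond_b0,
       angles = ang, ang_k = ang_k, ang_t0 = ang_t0,
       dihedrals = dih, dih_k = dih_k, dih_n = dih_n, dih_d = dih_d,
       impropers = imp, imp_k = imp_k, imp_w0 = imp_w0,
       pairs = pairs,
       pair_eps = sqrt(eps_i[pairs[, 1]] * eps_i[pairs[, 2]]),
       pair_rmin = rh_i[pairs[, 1]] + rh_i[pairs[, 2]],
       pair_scale = scale)
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}
rownorm <- function(a) sqrt(rowSums(a^2))
add_rows <- function(G, idx, val) {
  agg <- rowsum(val, idx)
  ridx <- as.integer(rownames(agg))
  G[ridx, ] <- G[ridx, ] + agg
  G
}

# signed dihedral angle and its gradient for atom quadruples (vectorized)
dihedral_angle_grad <- function(X, quad) {
  b1 <- X[quad[, 2], , drop = FALSE] - X[quad[, 1], , drop = FALSE]
  b2 <- X[quad[, 3], , drop = FALSE] - X[quad[, 2], , drop = FALSE]
  b3 <- X[quad[, 4], , drop = FALSE] - X[quad[, 3], , drop = FALSE]
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  nb2 <- rownorm(b2)
  phi <- atan2(rowSums(cross3(n1, n2) * b2) / pmax(nb2, 1e-12),
               rowSums(n1 * n2))
  n1sq <- pmax(rowSums(n1^2), 1e-12); n2sq <- pmax(rowSums(n2^2), 1e-12)
  dphi_d1 <- -n1 * (nb2 / n1sq)
  dphi_d4 <- n2 * (nb2 / n2sq)
  c12 <- rowSums(b1 * b2) / pmax(nb2^2, 1e-12)
  c32 <- rowSums(b3 * b2) / pmax(nb2^2, 1e-12)
  dphi_d2 <- -dphi_d1 * (1 + c12) + dphi_d4 * c32
  dphi_d3 <- dphi_d1 * c12 - dphi_d4 * (1 + c32)
  list(phi = phi, d1 = dphi_d1, d2 = dphi_d2, d3 = dphi_d3, d4 = dphi_d4)
}

#' Molecular-mechanics potential energy and gradient
#'
#' `E = sum_bond k (b - b0)^2 + sum_ang k (theta - theta0)^2 +
#'  sum_dih k (1 + cos(n phi - delta)) + sum_imp k (omega - omega0)^2 +
#'  sum_nb eps ((Rmin/r)^12 - 2 (Rmin/r)^6)`
#'
#' with analytic Cartesian gradients. Nonbonded pairs exclude 1-2 and 1-3
#' neighbours, scale 1-4 pairs, and use a switched cutoff. States are
#' treated as isolated molecules (no periodic images).
#'
#' @param state An [atomic_state()] carrying a [topology()].
#' @param params A [forcefield_parameters()] object, or a pre-resolved list
#'   from [resolve_forcefield()].
#' @param cutoff,switch_on Nonbonded cutoff and switching onset (Angstrom).
#' @param scale_14 1-4 Lennard-Jones scale (used only when `params` is not
#'   already resolved).
#' @return List with `energy` (kcal/mol), `gradient` (n x 3, kcal/mol/A)
#'   and a named `terms` breakdown.
#' @export
potential_energy <- function(state, params, cutoff = 9, switch_on = 7.5,
                             scale_14 = 1) {
  if (inherits(params, "forcefield_parameters")) {
    if (is.null(state$topology)) stop("state carries no topology")
    rp <- resolve_forcefield(state$topology, params, scale_14)
  } else rp <- params
  X <- state$xyz
  n <- nrow(X)
  G <- matrix(0, n, 3)
  terms <- c(bond = 0, angle = 0, dihedral = 0, improper = 0, lj = 0)

  if (nrow(rp$bonds)) {
    d <- X[rp$bonds[, 1], , drop = FALSE] - X[rp$bonds[, 2], , drop = FALSE]
    r <- rownorm(d)
    dev <- r - rp$bond_b0
    terms[["bond"]] <- sum(rp$bond_k * dev^2)
    f <- 2 * rp$bond_k * dev / pmax(r, 1e-12)
    G <- add_rows(G, rp$bonds[, 1], f * d)
    G <- add_rows(G, rp$bonds[, 2], -f * d)
  }
  if (nrow(rp$angles)) {
    i <- rp$angles[, 1]; j <- rp$angles[, 2]; k <- rp$angles[, 3]
    u <- X[i, , drop = FALSE] - X[j, , drop = FALSE]
    v <- X[k, , drop = FALSE] - X[j, , drop = FALSE]
    nu <- rownorm(u); nv <- rownorm(v)
    ct <- pmin(pmax(rowSums(u * v) / (nu * nv), -1), 1)
    th <- acos(ct)
    st <- pmax(sqrt(1 - ct^2), 1e-8)
    dev <- th - rp$ang_t0
    terms[["angle"]] <- sum(rp$ang_k * dev^2)
    dEdth <- 2 * rp$ang_k * dev
    uh <- u / nu; vh <- v / nv
    dth_di <- (ct * uh - vh) / (nu * st)
    dth_dk <- (ct * vh - uh) / (nv * st)
    G <- add_rows(G, i, dEdth * dth_di)
    G <- add_rows(G, k, dEdth * dth_dk)
    G <- add_rows(G, j, -dEdth * (dth_di + dth_dk))
  }
  if (nrow(rp$dihedrals)) {
    dg <- dihedral_angle_grad(X, rp$dihedrals)
    terms[["dihedral"]] <- sum(rp$dih_k * (1 + cos(rp$dih_n * dg$phi - rp$dih_d)))
    dEdphi <- -rp$dih_k * rp$dih_n * sin(rp$dih_n * dg$phi - rp$dih_d)
    G <- add_rows(G, rp$dihedrals[, 1], dEdphi * dg$d1)
    G <- add_rows(G, rp$dihedrals[, 2], dEdphi * dg$d2)
    G <- add_rows(G, rp$dihedrals[, 3], dEdphi * dg$d3)
    G <- add_rows(G, rp$dihedrals[, 4], dEdphi * dg$d4)
  }
  if (nrow(rp$impropers)) {
    dg <- dihedral_angle_grad(X, rp$impropers)
    dev <- dg$phi - rp$imp_w0
    dev <- dev - 2 * pi * round(dev / (2 * pi))
    terms[["improper"]] <- sum(rp$imp_k * dev^2)
    dEdphi <- 2 * rp$imp_k * dev
    G <- add_rows(G, rp$impropers[, 1], dEdphi * dg$d1)
    G <- add_rows(G, rp$impropers[, 2], dEdphi * dg$d2)
    G <- add_rows(G, rp$impropers[, 3], dEdphi * dg$d3)
    G <- add_rows(G, rp$impropers[, 4], dEdphi * dg$d4)
  }
  if (nrow(rp$pairs)) {
    lj <- lj_pairs(X, rp$pairs, rp$pair_eps, rp$pair_rmin, rp$pair_scale,
                   switch_on, cutoff)
    terms[["lj"]] <- lj$energy
    G <- G + lj$grad
  }
  list(energy = sum(terms), gradient = G, terms = terms)
}
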