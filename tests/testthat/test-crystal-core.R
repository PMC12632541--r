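crossprod_vec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

test_that("resolution follows the reciprocal metric", {
  cubic <- unit_cell(10, 10, 10)
  expect_equal(resolution_of(c(1, 0, 0), cubic), 10)
  expect_equal(resolution_of(c(2, 0, 0), cubic), 5)

  # triclinic oracle: build the reciprocal basis from explicit real-space
  # vectors and compute |h a* + k b* + l c*| independently
  cell <- unit_cell(7, 9, 11, 80, 95, 103)
  deg <- pi / 180
  ca <- cos(80 * deg); cb <- cos(95 * deg); cg <- cos(103 * deg); sg <- sin(103 * deg)
  av <- c(7, 0, 0)
  bv <- 9 * c(cg, sg, 0)
  cv <- 11 * c(cb, (ca - cb * cg) / sg,
               sqrt(1 - cb^2 - ((ca - cb * cg) / sg)^2))
  V <- sum(av * crossprod_vec(bv, cv))
  astar <- crossprod_vec(bv, cv) / V
  bstar <- crossprod_vec(cv, av) / V
  cstar <- crossprod_vec(av, bv) / V
  s <- 1 * astar + 2 * bstar + 3 * cstar
  expect_equal(resolution_of(c(1, 2, 3), cell), 1 / sqrt(sum(s^2)),
               tolerance = 1e-12)

  expect_error(resolution_of(c(0, 0, 0), cubic), "undefined resolution")
})

test_that("unit cell validation rejects degenerate metrics", {
  expect_error(unit_cell(-1, 10, 10), "positive")
  expect_error(unit_cell(10, 10, 10, 0, 90, 90), "angles")
  expect_error(unit_cell(10, 10, 10, 10, 10, 170), "degenerate")
})

test_that("orthogonalization matrix follows the standard convention", {
  expect_equal(orthogonalization_matrix(unit_cell(10, 10, 10)),
               diag(c(10, 10, 10)))
  # monoclinic: independent symbolic evaluation of the convention
  cell <- unit_cell(10, 12, 14, 90, 100, 90)
  cb <- cos(100 * pi / 180)
  M_expected <- rbind(c(10, 0, 14 * cb),
                      c(0, 12, 0),
                      c(0, 0, 14 * sqrt(1 - cb^2)))
  expect_equal(orthogonalization_matrix(cell), M_expected, tolerance = 1e-12)
  # round trip fractional -> Cartesian -> fractional
  for (cl in list(cell, unit_cell(7, 9, 11, 80, 95, 103))) {
    M <- orthogonalization_matrix(cl)
    expect_equal(M %*% solve(M), diag(3), tolerance = 1e-12)
  }
})

test_that("centric/epsilon classification matches group structure", {
  p1 <- classify_reflection(rbind(c(1, 2, 3), c(-4, 0, 2)), symmetry_ops("P1"))
  expect_false(any(p1$centric))
  expect_true(all(p1$epsilon == 1))

  pbar <- classify_reflection(rbind(c(1, 2, 3), c(0, 0, 5)), symmetry_ops("P-1"))
  expect_true(all(pbar$centric))
  expect_true(all(pbar$epsilon == 1))

  # P2 along b: exhaustive enumeration of the two rotations
  p2 <- classify_reflection(rbind(c(0, 3, 0), c(2, 0, 1)), symmetry_ops("P2"))
  expect_equal(p2$centric, c(FALSE, TRUE))
  expect_equal(p2$epsilon, c(2L, 1L))
})

test_that("classification agrees with brute-force orbit enumeration", {
  rng <- -4:4
  hkl <- as.matrix(expand.grid(h = rng, k = rng, l = rng))
  hkl <- hkl[rowSums(hkl != 0) > 0, ]
  for (grp in c("P1", "P-1", "P2", "P212121", "C2")) {
    ops <- symmetry_ops(grp)
    got <- classify_reflection(hkl, ops)
    Rs <- lapply(ops, `[[`, "R"); ts <- lapply(ops, `[[`, "t")
    for (i in sample(nrow(hkl), 60)) {
      h <- hkl[i, ]
      imgs <- t(vapply(Rs, function(R) as.integer(h %*% R), integer(3)))
      expect_equal(got$centric[i],
                   any(apply(imgs, 1, function(v) all(v == -h))),
                   info = paste(grp, paste(h, collapse = ",")))
      fix <- apply(imgs, 1, function(v) all(v == h))
      phase_sum <- sum(vapply(which(fix), function(k)
        exp(2i * pi * sum(h * ts[[k]])), complex(1)))
      expect_equal(got$epsilon[i], as.integer(round(Mod(phase_sum))))
      if (!got$absent[i]) {
        expect_true(got$epsilon[i] >= 1)
        expect_equal(length(ops) %% got$epsilon[i], 0)
      }
    }
  }
})

test_that("symmetry-equivalent reflections share annotation and the ASU representative", {
  ops <- symmetry_ops("P212121")
  cell <- unit_cell(10, 12, 14)
  h <- c(1, 2, 3)
  for (op in ops) {
    h2 <- as.integer(h %*% op$R)
    expect_equal(asu_reduce(h, ops), asu_reduce(h2, ops))
    expect_equal(asu_reduce(h, ops), asu_reduce(-h2, ops))
    a <- classify_reflection(h, ops); b <- classify_reflection(h2, ops)
    expect_equal(a$centric, b$centric)
    expect_equal(a$epsilon, b$epsilon)
    expect_equal(resolution_of(h, cell), resolution_of(h2, cell))
  }
})

test_that("symmetry operator sets are validated", {
  expect_error(symmetry_ops("P6122"), "unknown built-in")
  # not closed: a fourfold without its square
  bad <- list(list(R = diag(3), t = c(0, 0, 0)),
              list(R = matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3),
                   t = c(0, 0, 0)))
  expect_error(symmetry_ops(bad), "not closed")
  expect_error(symmetry_ops(list(list(R = diag(c(-1, 1, -1)), t = c(0, 0, 0)))),
               "identity")
})

test_that("weight matrices are validated and preserved", {
  expect_error(weight_matrix(c(0.5, 0.6)), "sum to 1")
  expect_error(weight_matrix(c(1.4, -0.4)), "0, 1")
  W <- weight_matrix(matrix(c(0.8, 0.2, 0.3, 0.7), 2, 2))
  expect_equal(colSums(W), c(1, 1))
  set.seed(1)
  for (k in 1:20) {
    Wk <- sample_weight_matrix(sample(1:4, 1), sample(1:3, 1))
    expect_true(all(Wk >= 0))
    expect_true(all(abs(colSums(Wk) - 1) < 1e-12))
  }
})

test_that("multi-state models demand identical composition", {
  s1 <- atomic_state(c("C", "N"), rbind(c(0, 0, 0), c(1.5, 0, 0)))
  s2 <- atomic_state(c("C", "O"), rbind(c(0, 0, 0), c(1.5, 0, 0)))
  expect_error(multi_state_model(list(s1, s2), c(0.5, 0.5)), "identical")
  m <- multi_state_model(list(s1, s1), c(0.5, 0.5))
  expect_equal(n_states(m), 2L)
  expect_error(multi_state_model(list(s1), c(0.5, 0.5)), "rows")
})
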