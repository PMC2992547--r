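test_that("rotatable-bond perception follows the standard convention", {
  butane <- make_fixture(fixture_spec(4, "chain", seed = 1))$mol
  rbs <- perceive_rotatable_bonds(butane)
  expect_length(rbs, 1)
  expect_equal(sort(rbs[[1]]$axis), c(2, 3))          # only C2-C3 rotates

  expect_length(perceive_rotatable_bonds(ethane_mol()), 0)      # only H moves
  expect_length(perceive_rotatable_bonds(cyclohexane_mol()), 0) # all in-ring

  # amide exclusion: CH3-C(=O)-NH-CH3 keeps only the N-CH3 bond candidates
  X <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.2, 1.1, 0), c(2.2, -1.2, 0),
             c(3.6, -1.3, 0))
  amide <- mol_record("nma_heavy", c("C", "C", "O", "N", "C"), X,
    data.frame(i = c(1, 2, 2, 4), j = c(2, 3, 4, 5),
               order = c("1", "2", "1", "1")))
  axes <- lapply(perceive_rotatable_bonds(amide), `[[`, "axis")
  expect_false(any(vapply(axes, function(a) setequal(a, c(2, 4)), logical(1))))

  # disconnected graphs are rejected
  dis <- mol_record("dis", c("C", "C"), rbind(c(0, 0, 0), c(5, 0, 0)),
                    data.frame(i = integer(0), j = integer(0),
                               order = character(0)))
  expect_error(perceive_rotatable_bonds(dis), "disconnected")
})

test_that("moving set partitions the molecule and contains the k side", {
  fx <- make_fixture(fixture_spec(9, "branched", seed = 4))
  for (rb in perceive_rotatable_bonds(fx$mol)) {
    expect_false(rb$axis[1] %in% rb$moving)
    expect_true(rb$axis[2] %in% rb$moving)
    expect_lte(length(rb$moving), length(fx$mol$elements) / 2)
  }
})

test_that("set/measure torsions close the round trip and preserve internals", {
  fx <- make_fixture(fixture_spec(10, "chain", seed = 2))
  mol <- fx$mol
  rbs <- perceive_rotatable_bonds(mol)
  b <- mol$bonds
  d0 <- sqrt(rowSums((fx$conf$coords[b$i, ] - fx$conf$coords[b$j, ])^2))
  angle_of <- function(X, i, j, k) {
    u <- X[i, ] - X[j, ]; w <- X[k, ] - X[j, ]
    acos(sum(u * w) / sqrt(sum(u^2) * sum(w^2))) * 180 / pi
  }
  adj <- lapply(seq_along(mol$elements), function(a)
    c(b$j[b$i == a], b$i[b$j == a]))
  triples <- do.call(rbind, lapply(seq_along(adj), function(j) {
    if (length(adj[[j]]) < 2) return(NULL)
    t(utils::combn(adj[[j]], 2))[, c(1, 2), drop = FALSE] |>
      (\(m) cbind(m[, 1], j, m[, 2]))()
  }))
  a0 <- apply(triples, 1, function(q) angle_of(fx$conf$coords, q[1], q[2], q[3]))

  set.seed(99)
  for (rep in 1:100) {
    tv <- runif(length(rbs), -180, 180)
    cf <- set_torsions(mol, fx$conf, tv, rbs)
    expect_lt(max(abs(wrap_angle(measure_torsions(mol, cf, rbs) - tv))), 1e-4)
    if (rep <= 5) {  # internal-coordinate preservation, spot-checked
      d1 <- sqrt(rowSums((cf$coords[b$i, ] - cf$coords[b$j, ])^2))
      expect_lt(max(abs(d1 - d0)), 1e-6)
      a1 <- apply(triples, 1, function(q) angle_of(cf$coords, q[1], q[2], q[3]))
      expect_lt(max(abs(a1 - a0)), 1e-4)
    }
  }

  # identity: driving to the measured torsions leaves coordinates untouched
  tv0 <- measure_torsions(mol, fx$conf, rbs)
  expect_lt(max(abs(set_torsions(mol, fx$conf, tv0, rbs)$coords -
                    fx$conf$coords)), 1e-9)
  expect_error(set_torsions(mol, fx$conf, c(tv0, 0), rbs), "length")
})

test_that("anti butane reproduces the independent internal-coordinate oracle", {
  # planar zigzag oracle: all-anti chain of 4 with bond r and angle theta;
  # in a trans zigzag the C3->C4 step is parallel to C1->C2
  r <- 1.53; th <- 109.4712206344907 * pi / 180
  P <- rbind(c(0, 0, 0),
             c(r, 0, 0),
             c(r - r * cos(th), r * sin(th), 0),
             c(2 * r - r * cos(th), r * sin(th), 0))
  d_oracle <- sqrt(sum((P[4, ] - P[1, ])^2))

  fx <- make_fixture(fixture_spec(4, "chain", seed = 1))
  rbs <- perceive_rotatable_bonds(fx$mol)
  anti <- set_torsions(fx$mol, fx$conf, 180, rbs)
  d_impl <- sqrt(sum((anti$coords[4, ] - anti$coords[1, ])^2))
  expect_equal(d_impl, d_oracle, tolerance = 1e-6)
})

test_that("dihedral measurement uses the signed wrapped convention", {
  Xcis <- rbind(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0))
  mol4 <- mol_record("q", c("C", "C", "C", "C"), Xcis,
                     data.frame(i = 1:3, j = 2:4, order = "1"))
  rb <- perceive_rotatable_bonds(mol4)
  expect_equal(measure_torsions(mol4, conformation(Xcis), rb), 0)
  Xtrans <- rbind(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(-1, 0, 0))
  expect_equal(measure_torsions(mol4, conformation(Xtrans), rb), -180)
  Xlin <- rbind(c(3, 0, 0), c(2, 0, 0), c(1, 0, 0), c(0, 0, 0))
  expect_error(measure_torsions(mol4, conformation(Xlin), rb), "collinear")
})

test_that("radius of gyration matches closed forms and is rigid-invariant", {
  expect_equal(radius_of_gyration(matrix(c(3, -2, 7), 1, 3)), 0)
  d <- 2.7
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(d, 0, 0))), d / 2)
  s <- 1.9
  sq <- rbind(c(0, 0, 0), c(s, 0, 0), c(s, s, 0), c(0, s, 0))
  expect_equal(radius_of_gyration(sq), s / sqrt(2))
  set.seed(7)
  for (i in 1:10) {
    X <- matrix(rnorm(30), 10, 3)
    expect_equal(radius_of_gyration(random_rigid_motion(X)),
                 radius_of_gyration(X), tolerance = 1e-9)
  }
})

test_that("superpose_rmsd agrees with the quaternion oracle", {
  set.seed(31)
  X <- matrix(rnorm(15, sd = 2), 5, 3)
  expect_equal(superpose_rmsd(X, X), 0, tolerance = 1e-9)
  expect_lt(superpose_rmsd(random_rigid_motion(X), X), 1e-6)
  for (i in 1:20) {
    A <- matrix(rnorm(15, sd = 2), 5, 3)
    B <- matrix(rnorm(15, sd = 2), 5, 3)
    expect_equal(superpose_rmsd(A, B), quaternion_rmsd(A, B), tolerance = 1e-8)
    expect_equal(superpose_rmsd(A, B), superpose_rmsd(B, A), tolerance = 1e-9)
  }
  expect_error(superpose_rmsd(X[1:2, ], X[1:2, ]), "3 atom pairs")
  lin <- cbind(1:5, 0, 0)
  expect_error(superpose_rmsd(lin, lin), "collinear")
})

test_that("best-fit RMSD is symmetry-corrected and never beats identity", {
  benz <- benzene_mol()
  expect_length(heavy_automorphisms(benz), 12)
  rot <- c(2:6, 1)
  confB <- conformation(rbind(benz$coords[1:6, ][rot, ], benz$coords[7:12, ]))
  expect_lt(best_fit_rmsd(confB, conformation(benz$coords), benz), 1e-9)

  # asymmetric molecule (trivial automorphism group): symmetry correction
  # changes nothing
  fx <- make_fixture(fixture_spec(8, "branched", seed = 1))
  expect_length(heavy_automorphisms(fx$mol), 1)
  set.seed(5)
  rbs <- perceive_rotatable_bonds(fx$mol)
  other <- set_torsions(fx$mol, fx$conf, runif(length(rbs), -180, 180), rbs)
  id_map <- cbind(fx$mol$heavy_idx, fx$mol$heavy_idx)
  expect_equal(best_fit_rmsd(other, fx$conf, fx$mol),
               superpose_rmsd(other, fx$conf, id_map))

  # palindromic pentane with asymmetric torsions: the reversal automorphism
  # must beat the identity mapping
  pent <- make_fixture(fixture_spec(5, "chain", seed = 1))
  prbs <- perceive_rotatable_bonds(pent$mol)
  A <- set_torsions(pent$mol, pent$conf, c(60, 180), prbs)
  rev_heavy <- rev(seq_along(pent$mol$heavy_idx))
  Bcoords <- A$coords
  Bcoords[pent$mol$heavy_idx, ] <- A$coords[pent$mol$heavy_idx[rev_heavy], ]
  B <- conformation(Bcoords)
  id_rmsd <- superpose_rmsd(B, A, cbind(pent$mol$heavy_idx, pent$mol$heavy_idx))
  bf <- best_fit_rmsd(B, A, pent$mol)
  expect_gt(id_rmsd, 0.1)
  expect_lt(bf, 1e-9)
  expect_lte(bf, id_rmsd)

  # property: best-fit <= identity over random conformer pairs
  set.seed(17)
  for (i in 1:10) {
    c1 <- set_torsions(pent$mol, pent$conf, runif(2, -180, 180), prbs)
    c2 <- set_torsions(pent$mol, pent$conf, runif(2, -180, 180), prbs)
    expect_lte(best_fit_rmsd(c1, c2, pent$mol),
               superpose_rmsd(c1, c2, mol = pent$mol) + 1e-12)
  }
})

test_that("geometric dissimilarity is a symmetric heavy-atom metric", {
  fx <- make_fixture(fixture_spec(6, "chain", seed = 3))
  expect_equal(geometric_dissimilarity(fx$conf, fx$conf, fx$mol), 0)
  rbs <- perceive_rotatable_bonds(fx$mol)
  set.seed(2)
  for (i in 1:5) {
    a <- set_torsions(fx$mol, fx$conf, runif(length(rbs), -180, 180), rbs)
    b <- set_torsions(fx$mol, fx$conf, runif(length(rbs), -180, 180), rbs)
    gab <- geometric_dissimilarity(a, b, fx$mol)
    expect_gte(gab, 0)
    expect_equal(gab, geometric_dissimilarity(b, a, fx$mol), tolerance = 1e-9)
  }
  # flipped terminal butane torsion against the quaternion oracle
  bu <- make_fixture(fixture_spec(4, "chain", seed = 1))
  brb <- perceive_rotatable_bonds(bu$mol)
  flip <- set_torsions(bu$mol, bu$conf,
                       wrap_angle(measure_torsions(bu$mol, bu$conf, brb) + 180),
                       brb)
  expect_equal(geometric_dissimilarity(flip, bu$conf, bu$mol),
               quaternion_rmsd(flip$coords[bu$mol$heavy_idx, ],
                               bu$conf$coords[bu$mol$heavy_idx, ]),
               tolerance = 1e-8)
})
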