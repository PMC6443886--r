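# Geometry kernel: dihedrals, Kabsch superposition, radius of gyration.

test_that("dihedral reproduces the standard convention on canonical cases", {
  expect_equal(dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), 0)
  expect_equal(dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)), 180)
  expect_equal(dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 0, 1)), 90)
})

test_that("dihedral matches the independent projection oracle", {
  # tabulated quadruple from the interface contract
  p <- list(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(-0.5, 1, 0.866))
  expect_equal(dihedral(p[[1]], p[[2]], p[[3]], p[[4]]),
               oracle_dihedral(p[[1]], p[[2]], p[[3]], p[[4]]),
               tolerance = 1e-10)
  set.seed(101)
  for (i in 1:50) {
    q <- lapply(1:4, function(j) rnorm(3, sd = 2))
    got <- dihedral(q[[1]], q[[2]], q[[3]], q[[4]])
    if (is.na(got)) next
    expect_equal(got, oracle_dihedral(q[[1]], q[[2]], q[[3]], q[[4]]),
                 tolerance = 1e-9)
  }
})

test_that("dihedral is invariant under atom-order reversal and negates under mirroring", {
  # IUPAC torsions are viewing-direction independent: phi(ABCD) = phi(DCBA)
  set.seed(7)
  for (i in 1:20) {
    q <- lapply(1:4, function(j) rnorm(3, sd = 2))
    fwd <- dihedral(q[[1]], q[[2]], q[[3]], q[[4]])
    if (is.na(fwd)) next
    expect_equal(dihedral(q[[4]], q[[3]], q[[2]], q[[1]]), fwd,
                 tolerance = 1e-10)
    mir <- lapply(q, function(p) c(p[1], p[2], -p[3]))
    got <- dihedral(mir[[1]], mir[[2]], mir[[3]], mir[[4]])
    expect_equal(abs(got), abs(fwd), tolerance = 1e-10)
    if (abs(abs(fwd) - 180) > 1e-9 && abs(fwd) > 1e-9)
      expect_equal(got, -fwd, tolerance = 1e-10)
  }
})

test_that("dihedral rejects a zero-length central bond and warns on collinearity", {
  expect_error(dihedral(c(0, 1, 0), c(0, 0, 0), c(0, 0, 0), c(1, 1, 0)),
               "central bond")
  expect_warning(
    got <- dihedral(c(0, 0, 2), c(0, 0, 1), c(0, 0, 0), c(1, 0, 0)),
    "collinear")
  expect_true(is.na(got))
})

test_that("kabsch_superpose recovers rigid motions exactly", {
  set.seed(11)
  P <- matrix(rnorm(15, sd = 3), 5, 3)
  self <- kabsch_superpose(P, P)
  expect_equal(self$rmsd, 0, tolerance = 1e-12)
  for (i in 1:10) {
    g <- random_rigid()
    Q <- P %*% t(g$R) + matrix(g$t, 5, 3, byrow = TRUE)
    fit <- kabsch_superpose(P, Q)
    expect_lt(fit$rmsd, 1e-9)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
    expect_equal(fit$transformed, Q, tolerance = 1e-9)
  }
})

test_that("kabsch_superpose matches the closed-form quaternion oracle", {
  set.seed(12)
  for (i in 1:25) {
    n <- sample(3:5, 1)
    P <- matrix(rnorm(3 * n, sd = 2), n, 3)
    Q <- matrix(rnorm(3 * n, sd = 2), n, 3)
    expect_equal(kabsch_superpose(P, Q)$rmsd, oracle_rmsd(P, Q),
                 tolerance = 1e-9)
  }
})

test_that("kabsch_superpose excludes reflections (mirror images stay distant)", {
  set.seed(13)
  P <- matrix(rnorm(15, sd = 3), 5, 3)
  Q <- P
  Q[, 3] <- -Q[, 3]  # a chiral set and its mirror image
  fit <- kabsch_superpose(P, Q)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_gt(fit$rmsd, 0.1)
})

test_that("kabsch_superpose validates its inputs", {
  expect_error(kabsch_superpose(matrix(0, 2, 3), matrix(0, 2, 3)),
               "at least 3")
  collinear <- cbind(1:4, 0, 0)
  expect_error(kabsch_superpose(collinear, collinear), "collinear")
  expect_error(kabsch_superpose(matrix(0, 4, 3), matrix(0, 5, 3)),
               "same number")
})

test_that("rmsd is symmetric and rigid-motion invariant", {
  set.seed(14)
  A <- matrix(rnorm(12, sd = 2), 4, 3)
  B <- matrix(rnorm(12, sd = 2), 4, 3)
  expect_equal(kabsch_superpose(A, B)$rmsd, kabsch_superpose(B, A)$rmsd,
               tolerance = 1e-9)
  g <- random_rigid()
  A2 <- A %*% t(g$R) + matrix(g$t, 4, 3, byrow = TRUE)
  expect_equal(kabsch_superpose(A2, B)$rmsd, kabsch_superpose(A, B)$rmsd,
               tolerance = 1e-9)
})

test_that("radius_of_gyration matches hand computation and scales correctly", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1, 3)), 0)
  two <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(radius_of_gyration(two), 1)
  set.seed(15)
  X <- matrix(rnorm(12, sd = 2), 4, 3)
  w <- runif(4, 1, 16)
  expect_equal(radius_of_gyration(X, weights = w), oracle_rog(X, w),
               tolerance = 1e-12)
  # rigid-motion invariance and linear scaling
  g <- random_rigid()
  X2 <- X %*% t(g$R) + matrix(g$t, 4, 3, byrow = TRUE)
  expect_equal(radius_of_gyration(X2, weights = w),
               radius_of_gyration(X, weights = w), tolerance = 1e-9)
  expect_equal(radius_of_gyration(3 * X, weights = w),
               3 * radius_of_gyration(X, weights = w), tolerance = 1e-9)
  expect_error(radius_of_gyration(X[0, , drop = FALSE]), "empty")
})

test_that("conformation method uses the backbone selection and masses", {
  topo <- heptamer_topology()
  conf <- build_conformation(topo, extended_torsions(topo))
  sel <- backbone_selection(topo)
  expect_equal(radius_of_gyration(conf),
               oracle_rog(conf$coords[sel, ], topo$atoms$mass[sel]),
               tolerance = 1e-12)
  expect_equal(radius_of_gyration(conf, mass_weighted = FALSE),
               oracle_rog(conf$coords[sel, ]), tolerance = 1e-12)
})
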