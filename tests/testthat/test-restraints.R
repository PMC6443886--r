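# ROESY calibration, restraint construction and the flat-bottom penalty.

make_peaks <- function(I, r_ref = 2.5, I_ref = 1) {
  n <- length(I)
  roesy_peaks(res_a = c(rep(1L, n), 0L), role_a = c(rep("H_A", n), "cal"),
              res_b = c(rep(2L, n), 0L), role_b = c(rep("H_N", n), "cal"),
              intensity = c(I, I_ref),
              is_ref = c(rep(FALSE, n), TRUE),
              r_ref = c(rep(NA, n), r_ref))
}

test_that("peaks_to_distances implements the r^-6 calibration", {
  pk <- make_peaks(c(1, 1 / 64), r_ref = 2.5)
  d <- peaks_to_distances(pk)
  expect_equal(d$distance[1], 2.5)       # I = I_ref
  expect_equal(d$distance[2], 5.0)       # I = I_ref/64 -> 2 r_ref
  expect_equal(d$distance[3], 2.5)       # the reference itself
  pk2 <- make_peaks(64, r_ref = 3.0)
  expect_equal(peaks_to_distances(pk2)$distance[1], 1.5)  # inverse case
})

test_that("distances are scale covariant and monotone in intensity", {
  set.seed(41)
  I <- runif(10, 0.01, 100)
  d1 <- peaks_to_distances(make_peaks(I))$distance
  d2 <- peaks_to_distances(make_peaks(I * 1234.5, I_ref = 1234.5))$distance[1:10]
  # rescaling every intensity (reference included) changes nothing
  expect_equal(d2, d1[1:10], tolerance = 1e-12)
  o <- order(I)
  expect_true(all(diff(d1[1:10][o]) < 0))
})

test_that("peak-table invariants are enforced", {
  expect_error(make_peaks(c(1, -2)), "positive")
  pk <- make_peaks(1)
  pk$is_ref <- FALSE
  expect_error(peaks_to_distances(pk), "reference")
  pk2 <- make_peaks(1)
  pk2$is_ref <- c(TRUE, TRUE)
  expect_error(peaks_to_distances(pk2), "exactly one")
})

test_that("distances_to_restraints applies slack to the upper bound", {
  d <- data.frame(res_a = 1L, role_a = "H_A", res_b = 2L, role_b = "H_N",
                  distance = 3.0)
  expect_equal(distances_to_restraints(d)$restraints$r_upper, 3.0)
  expect_equal(distances_to_restraints(d, slack = 0.5)$restraints$r_upper, 3.5)
  expect_equal(distances_to_restraints(d)$restraints$k, 32)
  expect_error(distances_to_restraints(d, slack = -1), "slack")
  empty <- distances_to_restraints(d[0, ])
  expect_equal(nrow(empty$restraints), 0)
})

test_that("restraint energy is flat inside and k*delta^2 outside the bound", {
  topo <- heptamer_topology()
  conf <- build_conformation(topo, extended_torsions(topo))
  a <- atom_index(topo, 1, "H_A")
  b <- atom_index(topo, 10, "H_A")
  r <- sqrt(sum((conf$coords[a, ] - conf$coords[b, ])^2))
  mk <- function(r_upper, k = 32)
    data.frame(res_a = 1L, role_a = "H_A", res_b = 10L, role_b = "H_A",
               r_upper = r_upper, k = k)
  expect_equal(restraint_energy(mk(r + 0.3), conf), 0)
  expect_equal(restraint_energy(mk(r - 1.0), conf), 32, tolerance = 1e-9)
  expect_equal(restraint_energy(mk(r - 0.5), conf), 8, tolerance = 1e-9)
  # continuity and once-differentiability at the bound
  eps <- 1e-7
  expect_lt(restraint_energy(mk(r - eps), conf), 1e-10)
  expect_equal(restraint_energy(mk(r - 0.5, k = 0), conf), 0)
})

test_that("total_restraint_energy sums active restraints and reports inactive", {
  topo <- heptamer_topology()
  conf <- build_conformation(topo, extended_torsions(topo))
  a <- atom_index(topo, 1, "H_A")
  b <- atom_index(topo, 10, "H_A")
  r <- sqrt(sum((conf$coords[a, ] - conf$coords[b, ])^2))
  rs <- restraint_set(data.frame(
    id = 1:3,
    res_a = 1L, role_a = "H_A", res_b = 10L, role_b = "H_A",
    r_upper = c(r - 0.5, r - 0.5, r - 1.25),
    k = 32, active = c(TRUE, TRUE, FALSE), source = "test",
    stringsAsFactors = FALSE))
  e <- total_restraint_energy(rs, conf)
  expect_equal(e$total, 16, tolerance = 1e-9)      # two violations of 8 each
  expect_equal(unname(e$penalties[3]), 32 * 1.25^2, tolerance = 1e-9)
  expect_length(e$penalties, 3)                     # inactive still reported
  none <- restraint_set(rs$restraints[0, ])
  expect_equal(total_restraint_energy(none, conf)$total, 0)
})

test_that("unresolvable proton references name the offending atom", {
  topo <- heptamer_topology()
  conf <- build_conformation(topo, extended_torsions(topo))
  bad <- data.frame(res_a = 3L, role_a = "H_N", res_b = 1L, role_b = "H_A",
                    r_upper = 3, k = 32)
  expect_error(restraint_energy(bad, conf), "H_N.*position 3")
})

test_that("restraint and peak TSV round trips preserve content", {
  topo <- heptamer_topology()
  conf <- build_conformation(topo, template_torsions("helix", topo))
  pk <- forward_roesy(conf, sigma_log = 0.05, seed = 5)
  f1 <- tempfile(fileext = ".tsv")
  write_roesy_tsv(pk, f1)
  back <- read_roesy_tsv(f1)
  expect_equal(back$intensity, pk$intensity, tolerance = 1e-12)
  set <- distances_to_restraints(
    peaks_to_distances(pk)[seq_len(10), ], slack = 0.3)
  f2 <- tempfile(fileext = ".tsv")
  write_restraints_tsv(set, f2)
  back2 <- read_restraints_tsv(f2)
  expect_equal(back2$restraints$r_upper, set$restraints$r_upper,
               tolerance = 1e-12)
  expect_true(all(back2$restraints$active))
})
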