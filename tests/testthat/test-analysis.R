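# Trajectory analytics: RMSD/ROG series, torsion distributions, clustering,
# merging, RDF.

two_state_traj <- function(n_frames = 200, seed = 81, pops = c(0.7, 0.3)) {
  spec <- generator_spec(template = c("helix", "extended"), n_frames = n_frames,
                         populations = pops, seed = seed)
  generate_trajectory(spec, heptamer_topology())
}

test_that("trajectory container validates frames and windows", {
  topo <- heptamer_topology()
  conf <- build_conformation(topo, extended_torsions(topo))
  tr <- trajectory(topo, list(conf, conf, conf))
  expect_equal(n_frames(tr), 3)
  expect_equal(set_window(tr, 2, 3)$window, c(2L, 3L))
  expect_equal(set_window(tr, fraction = 0.5)$window, c(3L, 3L))
  expect_error(trajectory(topo, list()), "frame")
  expect_error(set_window(tr, 0, 3), "window")
  expect_error(trajectory(topo, list(conf$coords[-1, ])), "atom count")
})

test_that("rmsd_series is zero on copies and consistent across frames", {
  topo <- heptamer_topology()
  conf <- build_conformation(topo, extended_torsions(topo))
  tr <- trajectory(topo, list(conf, conf))
  s <- rmsd_series(tr, conf)
  expect_equal(s, c(0, 0), tolerance = 1e-9)
  expect_equal(s[1], s[2])
  expect_error(rmsd_series(tr, conf$coords[1:5, ]), "selection mismatch")
})

test_that("rmsd_series matches the noise-model expectation", {
  # frames = reference + iid per-coordinate Gaussian noise sigma; after
  # optimal superposition E[RMSD] ~ sigma * sqrt((3N - 6) / N)
  topo <- heptamer_topology()
  conf <- build_conformation(topo, extended_torsions(topo))
  sel <- backbone_selection(topo)
  sigma <- 0.4
  set.seed(82)
  frames <- replicate(500, {
    x <- conf$coords
    x + matrix(rnorm(length(x), sd = sigma), nrow(x), 3)
  }, simplify = FALSE)
  s <- rmsd_series(trajectory(topo, frames), conf)
  expected <- sigma * sqrt((3 * length(sel) - 6) / length(sel))
  expect_lt(abs(mean(s) - expected) / expected, 0.1)
})

test_that("rog_series is rigid-motion invariant and scales linearly", {
  gen <- two_state_traj(20)
  tr <- gen$trajectory
  r1 <- rog_series(tr)
  g <- { set.seed(83); random_rigid() }
  moved <- tr
  for (f in seq_len(n_frames(tr)))
    moved$coords[, , f] <- tr$coords[, , f] %*% t(g$R) +
      matrix(g$t, dim(tr$coords)[1], 3, byrow = TRUE)
  expect_equal(rog_series(moved), r1, tolerance = 1e-9)
  scaled <- tr
  scaled$coords <- tr$coords * 2.5
  expect_equal(rog_series(scaled), 2.5 * r1, tolerance = 1e-9)
})

test_that("torsion distributions conserve counts and honour the window", {
  topo <- heptamer_topology()
  conf <- build_conformation(topo, template_torsions("helix", topo))
  tr <- trajectory(topo, rep(list(conf), 6))
  td <- torsion_distribution(tr)
  n_res <- nrow(topo$residues)
  expect_equal(sum(td$histogram), 6 * n_res)
  # identical frames: every residue contributes one point, repeated 6 times,
  # so at most one bin per residue is occupied and bin counts are multiples
  # of the frame count
  expect_lte(sum(td$histogram > 0), n_res)
  expect_true(all(td$histogram[td$histogram > 0] %% 6 == 0))
  per_res <- split(paste(td$samples$phi, td$samples$psi),
                   td$samples$position_index)
  expect_true(all(lengths(lapply(per_res, unique)) == 1))
  half <- torsion_distribution(set_window(tr, fraction = 0.5))
  expect_equal(sum(half$histogram), 3 * n_res)
  expect_equal(td$n_undefined, 0)
})

test_that("clustering recovers a planted two-state mixture", {
  gen <- two_state_traj(300, seed = 84)
  cl <- cluster_frames(gen$trajectory, n_clusters = 2)
  truth <- as.numeric(sort(table(gen$labels), decreasing = TRUE)) / 300
  expect_equal(cl$populations, truth, tolerance = 1e-9)
  # labels agree with ground truth up to permutation
  expect_equal(length(unique(paste(cl$labels, gen$labels))), 2)
  expect_true(all(cl$representatives %in% cl$frames))
  for (c in seq_along(cl$populations)) {
    rep_lab <- cl$labels[match(cl$representatives[c], cl$frames)]
    expect_equal(rep_lab, c)  # representative belongs to its cluster
  }
  expect_equal(sum(cl$populations), 1, tolerance = 1e-9)
})

test_that("single-cluster and precondition edge cases behave", {
  topo <- heptamer_topology()
  conf <- build_conformation(topo, extended_torsions(topo))
  tr <- trajectory(topo, rep(list(conf), 10))
  cl <- cluster_frames(tr, n_clusters = 1)
  expect_equal(cl$populations, 1.0)
  expect_error(cluster_frames(tr, n_clusters = 11), "exceeds")
  expect_error(cluster_frames(tr, n_clusters = 0), ">= 1")
})

test_that("frame-order shuffling permutes labels but not populations", {
  gen <- two_state_traj(120, seed = 85)
  cl1 <- cluster_frames(gen$trajectory, n_clusters = 2)
  set.seed(86)
  perm <- sample(120)
  shuffled <- trajectory(gen$trajectory$topology,
                         gen$trajectory$coords[, , perm])
  cl2 <- cluster_frames(shuffled, n_clusters = 2)
  expect_equal(sort(cl1$populations), sort(cl2$populations), tolerance = 1e-9)
  expect_equal(cl1$labels[perm], cl2$labels)
})

test_that("average linkage agrees with an independent implementation on toys", {
  set.seed(87)
  for (i in 1:6) {
    n <- 6
    pts <- matrix(rnorm(2 * n), n, 2)
    D <- as.matrix(dist(pts))
    hc <- hclust(as.dist(D), method = "average")
    for (k in 2:4) {
      ours <- cutree(hc, k)
      oracle <- oracle_average_linkage(D, k)
      # same partition up to label permutation
      expect_equal(length(unique(paste(ours, oracle))), k)
    }
  }
})

test_that("merging re-sums populations and respects the threshold", {
  # three-state construction mirroring the reported merge: two clusters whose
  # representatives differ by ~0.5 A backbone RMSD (59% + 40%) plus a distant
  # 1% cluster; merging at 1.0 A joins the first two into a 99% conformation
  topo <- heptamer_topology()
  helix <- template_torsions("helix", topo)
  near <- torsion_state(helix$position_index, helix$phi + 8, helix$psi - 8)
  far <- template_torsions("extended", topo)
  spec <- generator_spec(template = list(helix, near, far), noise_sd = 0.5,
                         n_frames = 100, populations = c(0.59, 0.40, 0.01),
                         seed = 88)
  gen <- generate_trajectory(spec, topo)
  cl <- cluster_frames(gen$trajectory, n_clusters = 3)
  merged <- merge_similar_clusters(cl, threshold = 1.0)
  expect_length(merged$populations, 2)
  truth <- as.numeric(table(gen$labels))
  expect_equal(max(merged$populations), sum(truth[1:2]) / 100,
               tolerance = 1e-9)
  expect_equal(sum(merged$populations), 1, tolerance = 1e-9)
  expect_length(merged$merge_log, 1)
  expect_lt(merged$merge_log[[1]]$rep_rmsd, 1.0)
  # threshold 0 never merges
  expect_length(merge_similar_clusters(cl, threshold = 0)$populations, 3)
})

test_that("three mutually close clusters merge transitively into one", {
  topo <- heptamer_topology()
  helix <- template_torsions("helix", topo)
  mk <- function(d) torsion_state(helix$position_index, helix$phi + d,
                                  helix$psi - d)
  spec <- generator_spec(template = list(helix, mk(6), mk(-6)),
                         noise_sd = 0.3, n_frames = 90,
                         populations = c(1, 1, 1) / 3, seed = 89)
  gen <- generate_trajectory(spec, topo)
  cl <- cluster_frames(gen$trajectory, n_clusters = 3)
  merged <- merge_similar_clusters(cl, threshold = 2.0)
  expect_length(merged$populations, 1)
  expect_equal(merged$populations, 1.0, tolerance = 1e-9)
})

test_that("RDF places a planted delta peak in the exact 0.1-A bin", {
  ig <- ideal_gas_frames(0.02, 9, 30, seed = 90, planted_radius = 1.83)
  rdf <- compute_rdf(ig$frames, ig$reference, bin_width = 0.1,
                     density = 0.02, r_max = 9)
  # the 1.8-1.9 A bin holds exactly one planted count per frame (the gas
  # contributes nothing that close at this density with high probability)
  bin <- which(rdf$edges[-1] > 1.83 & rdf$edges[-length(rdf$edges)] <= 1.83)
  expect_equal(unname(rdf$counts[bin]), 30)
  expect_equal(rdf$r[bin], 1.85)
})

test_that("RDF conserves raw pair counts within the radius", {
  set.seed(91)
  frames <- replicate(5, matrix(runif(3 * 50, -4, 4), 50, 3),
                      simplify = FALSE)
  rdf <- compute_rdf(frames, c(0, 0, 0), bin_width = 0.1, density = 0.05,
                     r_max = 20)  # radius covers the whole box
  expect_equal(sum(rdf$counts), 5 * 50)
  expect_error(compute_rdf(list(), c(0, 0, 0)), "zero frames")
  tr <- two_state_traj(5, seed = 92)$trajectory
  expect_error(compute_rdf(tr, 1, integer()), "empty target")
  expect_error(compute_rdf(tr, 1, 2, bin_width = 0), "bin width")
})

test_that("trajectory RDF normalizes by frames, references and shell volume", {
  # one target fixed at 1.8 A from one reference in every frame
  topo <- heptamer_topology()
  conf <- build_conformation(topo, extended_torsions(topo))
  tr <- trajectory(topo, rep(list(conf), 4))
  a <- atom_index(topo, 1, "N")
  d <- sqrt(sum((conf$coords[a, ] - conf$coords[a + 1, ])^2))
  rdf <- compute_rdf(tr, a, a + 1L, bin_width = 0.1, density = 0.033456,
                     r_max = 5)
  bin <- findInterval(d, rdf$edges, left.open = TRUE)
  expect_equal(sum(rdf$counts), 4)
  expect_equal(which(rdf$counts > 0), bin)
  shell <- 4 * pi * rdf$r[bin]^2 * 0.1
  expect_equal(rdf$g[bin], 4 / (4 * 1 * shell * 0.033456), tolerance = 1e-9)
})
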