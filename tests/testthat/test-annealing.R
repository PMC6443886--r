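# Simulated-annealing sampler: schedules, stand-in energy, Metropolis MC.

test_that("schedule totals reproduce the staged protocols", {
  expect_equal(schedule_total(default_sa_schedule()), 900)
  expect_equal(schedule_total(default_heatup_schedule()), 890)
  expect_equal(schedule_total(anneal_schedule(300, 7)), 7)
  expect_error(schedule_total(list()), "invalid")
  expect_error(anneal_schedule(numeric(), numeric()), "non-empty")
  expect_error(anneal_schedule(300, -1), "> 0")
  expect_error(anneal_schedule(-10, 5), ">= 0")
})

test_that("stand-in energy terms follow their declared forms", {
  topo <- heptamer_topology()
  conf <- build_conformation(topo, extended_torsions(topo))
  e <- stand_in_energy(conf)
  expect_equal(e$restraint, 0)
  expect_equal(e$total, e$steric + e$torsion + e$restraint, tolerance = 1e-9)
  # rigid builder keeps amides/rings planar: the planarity term vanishes
  expect_equal(e$torsion, 0, tolerance = 1e-9)
  # two pseudo-atoms exactly at contact distance contribute eps each
  par <- list(pair_i = 0L, pair_j = 1L, sigma = 2.2, eps = 1, cap = 100,
              restr_a = integer(), restr_b = integer(),
              restr_upper = numeric(), restr_k = numeric(),
              omega_quads = matrix(0L, 0, 4), k_omega = 10)
  toy <- rbind(c(0, 0, 0), c(2.2, 0, 0))
  expect_equal(triazolamer:::.energy_cpp(toy, par)$steric, 1.0,
               tolerance = 1e-12)
  # overlap is capped and flagged, not an error
  toy2 <- rbind(c(0, 0, 0), c(0.005, 0, 0))
  e2 <- triazolamer:::.energy_cpp(toy2, par)
  expect_equal(e2$steric, 100)
  expect_true(e2$clash)
})

test_that("a zero-step schedule returns the initial conformer unchanged", {
  topo <- heptamer_topology()
  sch <- anneal_schedule(0, 0.001, steps_per_ps = 100)  # rounds to 0 steps
  r <- run_annealing(topo, restraint_set(), sch, seed = 1)
  ext <- build_conformation(topo, extended_torsions(topo))
  expect_equal(r$conformation$coords, ext$coords, tolerance = 1e-12)
  expect_equal(r$acceptance_rate, 0)
})

test_that("annealing is deterministic given (inputs, seed)", {
  topo <- heptamer_topology()
  conf <- build_conformation(topo, template_torsions("helix", topo))
  pk <- forward_roesy(conf, sigma_log = 0, seed = 2)
  rset <- distances_to_restraints(peaks_to_distances(pk)[1:15, ])
  sch <- default_sa_schedule(steps_per_ps = 5)
  a <- run_annealing(topo, rset, sch, seed = 99)
  b <- run_annealing(topo, rset, sch, seed = 99)
  expect_identical(a$conformation$coords, b$conformation$coords)
  expect_identical(a$per_restraint, b$per_restraint)
  expect_identical(a$acceptance_rate, b$acceptance_rate)
  c <- run_annealing(topo, rset, sch, seed = 100)
  expect_false(identical(a$conformation$coords, c$conformation$coords))
})

test_that("campaigns assign sequential distinct seeds and are reproducible", {
  topo <- heptamer_topology()
  sch <- anneal_schedule(c(300, 0), c(2, 1), steps_per_ps = 20)
  camp <- run_campaign(topo, restraint_set(), sch, n_replicas = 4,
                       base_seed = 10)
  expect_length(camp, 4)
  expect_equal(vapply(camp, `[[`, 0, "seed"), 10:13)
  one <- run_campaign(topo, restraint_set(), sch, n_replicas = 1,
                      base_seed = 10)
  expect_equal(one[[1]]$seed, 10)
  expect_identical(one[[1]]$conformation$coords, camp[[1]]$conformation$coords)
  expect_error(run_campaign(topo, restraint_set(), sch, n_replicas = 0),
               ">= 1")
})

test_that("flat-energy sampling accepts everything and mixes to uniform torsions", {
  # detailed-balance sanity: eps = 0 and no restraints make the landscape
  # flat, so every move is accepted and the stationary torsion marginal is
  # uniform on (-180, 180]; thinned frames decorrelate the random walk
  topo <- heptamer_topology()
  w <- move_params(eps = 0, k_omega = 0)
  tr <- production_trajectory(topo, n_steps = 10000, stride = 200,
                              temperature = 300, seed = 5, weights = w)
  td <- torsion_distribution(tr)
  ok <- !is.na(td$samples$phi)
  pooled <- c(td$samples$phi[ok], td$samples$psi[!is.na(td$samples$psi)])
  ks <- suppressWarnings(stats::ks.test(pooled / 360 + 0.5, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("annealing lowers the energy from the extended start", {
  topo <- heptamer_topology()
  conf <- build_conformation(topo, template_torsions("helix", topo))
  pk <- forward_roesy(conf, sigma_log = 0, seed = 6)
  rset <- distances_to_restraints(peaks_to_distances(pk)[1:20, ])
  sch <- default_sa_schedule(steps_per_ps = 5)
  camp <- run_campaign(topo, rset, sch, n_replicas = 20, base_seed = 3)
  init <- vapply(camp, `[[`, 0, "initial_total")
  fin <- vapply(camp, function(r) r$energy$total, 0)
  expect_lt(mean(fin), mean(init))
  expect_true(all(vapply(camp, `[[`, 0, "acceptance_rate") >= 0 &
                    vapply(camp, `[[`, 0, "acceptance_rate") <= 1))
})

test_that("a single long-range restraint is satisfied by most replicas", {
  # scaled version of the satisfaction contract (9,000-step schedules,
  # 20 replicas instead of 100): the restrained termini come within bounds
  # while unrestrained replicas stay extended more than half the time
  topo <- heptamer_topology()
  rs <- restraint_set(data.frame(
    id = 1L, res_a = 1L, role_a = "H_A", res_b = 10L, role_b = "H_A",
    r_upper = 6, k = 32, active = TRUE, source = "test",
    stringsAsFactors = FALSE))
  sch <- default_sa_schedule(steps_per_ps = 10)
  camp <- run_campaign(topo, rs, sch, n_replicas = 20, base_seed = 17)
  pen <- vapply(camp, function(r) r$energy$restraint, 0)
  expect_gte(sum(pen < 5), 18)
  # generator-free null: random conformers mostly violate it
  set.seed(18)
  viol <- replicate(40, {
    conf <- build_conformation(topo, random_torsions(topo))
    total_restraint_energy(rs, conf)$total > 5
  })
  expect_gt(mean(viol), 0.5)
})

test_that("infeasible restraints complete with an irreducible penalty", {
  topo <- heptamer_topology()
  planted <- plant_artifact_restraints(restraint_set(), topo)
  sch <- anneal_schedule(c(300, 0), c(5, 2), steps_per_ps = 20)
  r <- run_annealing(topo, planted$set, sch, seed = 4)
  expect_true(all(r$per_restraint > 5))
})
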