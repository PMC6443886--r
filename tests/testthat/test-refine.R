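# Iterative restraint pruning.

fake_result <- function(pen, ids) {
  structure(list(per_restraint = setNames(pen, ids)),
            class = "replica_result")
}

test_that("prune_once removes exactly the restraints above the ceiling", {
  rs <- restraint_set(data.frame(
    id = 1:3, res_a = 1L, role_a = "H_A", res_b = 10L, role_b = "H_A",
    r_upper = 3, k = 32, active = TRUE, source = "t",
    stringsAsFactors = FALSE))
  # per-replica minimum statistic: min over replicas per restraint
  results <- list(fake_result(c(0.2, 7.1, 0.0), 1:3),
                  fake_result(c(0.4, 9.0, 0.1), 1:3))
  out <- prune_once(results, rs, pruning_config(penalty_ceiling = 5))
  expect_equal(out$removed, 2L)
  expect_equal(out$set$restraints$active, c(TRUE, FALSE, TRUE))
  expect_length(out$set$history, 1)
  # all satisfied -> converged with no removals
  ok <- list(fake_result(c(0, 0, 0), 1:3))
  expect_length(prune_once(ok, rs, pruning_config())$removed, 0)
  # everything above the ceiling goes in one pass
  bad <- list(fake_result(c(9, 9, 9), 1:3))
  out2 <- prune_once(bad, rs, pruning_config())
  expect_equal(out2$removed, 1:3)
  expect_false(any(out2$set$restraints$active))
  expect_error(prune_once(list(), rs), "empty")
})

test_that("the per-replica-minimum statistic spares restraints any replica satisfies", {
  rs <- restraint_set(data.frame(
    id = 1:2, res_a = 1L, role_a = "H_A", res_b = 10L, role_b = "H_A",
    r_upper = 3, k = 32, active = TRUE, source = "t",
    stringsAsFactors = FALSE))
  results <- list(fake_result(c(50, 50), 1:2), fake_result(c(0.5, 50), 1:2))
  expect_equal(prune_once(results, rs, pruning_config())$removed, 2L)
  # mean statistic would remove both
  expect_equal(
    prune_once(results, rs,
               pruning_config(penalty_statistic = "mean"))$removed, 1:2)
})

test_that("refine converges in one pass on a consistent synthetic set", {
  topo <- heptamer_topology()
  conf <- build_conformation(topo, template_torsions("helix", topo))
  pk <- forward_roesy(conf, sigma_log = 0, seed = 51)
  rset <- distances_to_restraints(
    peaks_to_distances(pk)[pk$role_a != "calibration", ], slack = 0.5)
  sch <- default_sa_schedule(steps_per_ps = 10)
  out <- refine(topo, rset, sch, pruning_config(), n_replicas = 8,
                base_seed = 60)
  expect_true(out$converged)
  expect_equal(out$iterations, 1)
  expect_true(all(out$set$restraints$active))
})

test_that("refine removes exactly the planted contradictory restraints", {
  topo <- heptamer_topology()
  conf <- build_conformation(topo, template_torsions("helix", topo))
  pk <- forward_roesy(conf, sigma_log = 0, seed = 52)
  base <- distances_to_restraints(
    peaks_to_distances(pk)[pk$role_a != "calibration", ][1:20, ], slack = 0.5)
  planted <- plant_artifact_restraints(base, topo)
  sch <- default_sa_schedule(steps_per_ps = 10)
  out <- refine(topo, planted$set, sch, pruning_config(), n_replicas = 8,
                base_seed = 70)
  expect_true(out$converged)
  expect_lte(out$iterations, 3)
  removed <- unlist(lapply(out$history, `[[`, "removed"))
  expect_setequal(removed, planted$planted_ids)
  # monotone shrinkage and full audit trail
  active <- out$set$restraints$id[out$set$restraints$active]
  expect_setequal(c(active, removed), planted$set$restraints$id)
  expect_false(anyDuplicated(c(active, removed)) > 0)
})

test_that("an empty initial set converges immediately but still runs a campaign", {
  topo <- heptamer_topology()
  sch <- anneal_schedule(c(300, 0), c(2, 1), steps_per_ps = 10)
  out <- refine(topo, restraint_set(), sch, pruning_config(), n_replicas = 2,
                base_seed = 1)
  expect_true(out$converged)
  expect_length(out$results, 2)
})

test_that("non-convergence at max_iterations is flagged, not raised", {
  topo <- heptamer_topology()
  planted <- plant_artifact_restraints(restraint_set(), topo)
  sch <- anneal_schedule(c(300, 0), c(2, 1), steps_per_ps = 10)
  # ceiling 0 removes something every pass until the set is empty; with
  # max_iterations = 1 the loop must stop unconverged
  cfg <- pruning_config(penalty_ceiling = 0, max_iterations = 1)
  out <- refine(topo, planted$set, sch, cfg, n_replicas = 2, base_seed = 5)
  expect_false(out$converged)
  expect_equal(out$iterations, 1)
})

test_that("the refinement JSON report is complete", {
  topo <- heptamer_topology()
  planted <- plant_artifact_restraints(restraint_set(), topo)
  sch <- anneal_schedule(c(300, 0), c(2, 1), steps_per_ps = 10)
  out <- refine(topo, planted$set, sch, pruning_config(), n_replicas = 2,
                base_seed = 5)
  path <- tempfile(fileext = ".json")
  write_refinement_json(out, path)
  rep <- jsonlite::read_json(path, simplifyVector = FALSE)
  expect_true(rep$converged)
  expect_equal(rep$n_active, 0L)
  expect_equal(sort(unlist(lapply(rep$history, `[[`, "removed"))),
               planted$planted_ids)
})
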