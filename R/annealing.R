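# Restrained torsion-space simulated annealing: a Metropolis Monte-Carlo
# stand-in for restrained gas-phase annealing MD. One randomly chosen backbone
# torsion is perturbed per step by Gaussian noise whose width scales with the
# current temperature; moves are accepted with the Metropolis ratio
# min(1, exp(-dE / RT)), and 0 K stages run greedy descent. The schedule's
# picosecond durations are mapped to steps via steps_per_ps so the staged
# protocol's proportions are preserved.

#' Staged annealing temperature schedule
#'
#' @param temperature Stage temperatures (K, >= 0).
#' @param duration Stage durations (ps, > 0).
#' @param steps_per_ps Monte-Carlo steps per schedule picosecond (default 100).
#' @return An `anneal_schedule`.
#' @export
anneal_schedule <- function(temperature, duration, steps_per_ps = 100) {
  if (length(temperature) != length(duration) || length(temperature) < 1L)
    stop("value error: schedule needs matched, non-empty stage vectors")
  if (any(duration <= 0)) stop("value error: stage durations must be > 0")
  if (any(temperature < 0)) stop("value error: temperatures must be >= 0")
  if (steps_per_ps <= 0) stop("value error: steps_per_ps must be > 0")
  structure(list(stages = data.frame(temperature = temperature,
                                     duration = duration),
                 steps_per_ps = steps_per_ps),
            class = "anneal_schedule")
}

#' Default gas-phase simulated-annealing schedule
#'
#' Heat from near 0 to 600 K and cool back to 0 K over nine stages totalling
#' 900 ps: (10 K, 5 ps; 100 K, 5 ps; 200 K, 90 ps; 600 K, 400 ps; 400 K,
#' 100 ps; 200 K, 200 ps; 100 K, 75 ps; 10 K, 20 ps; 0 K, 5 ps).
#'
#' @param steps_per_ps Monte-Carlo steps per schedule picosecond.
#' @return An [anneal_schedule()].
#' @export
default_sa_schedule <- function(steps_per_ps = 100) {
  anneal_schedule(c(10, 100, 200, 600, 400, 200, 100, 10, 0),
                  c(5, 5, 90, 400, 100, 200, 75, 20, 5),
                  steps_per_ps)
}

#' Default solvent heat-up schedule
#'
#' The staged 0 -> 300 K solvated heat-up totalling 890 ps: (10 K, 10 ps;
#' 50 K, 10 ps; 100 K, 20 ps; 100 K, 50 ps; 200 K, 100 ps; 300 K, 200 ps;
#' 300 K, 500 ps). Retained for protocol bookkeeping; the desk-scale sampler
#' has no solvent model.
#'
#' @param steps_per_ps Monte-Carlo steps per schedule picosecond.
#' @return An [anneal_schedule()].
#' @export
default_heatup_schedule <- function(steps_per_ps = 100) {
  anneal_schedule(c(10, 50, 100, 100, 200, 300, 300),
                  c(10, 10, 20, 50, 100, 200, 500),
                  steps_per_ps)
}

#' Total schedule duration in picoseconds
#'
#' @param schedule An [anneal_schedule()].
#' @return Sum of stage durations (ps).
#' @export
schedule_total <- function(schedule) {
  if (!inherits(schedule, "anneal_schedule") ||
      nrow(schedule$stages) == 0L)
    stop("value error: empty or invalid schedule")
  sum(schedule$stages$duration)
}

#' Move-size and steric parameters for the sampler
#'
#' `sigma_move = sigma_hi * sqrt(T / t_ref)` clamped to `[sigma_lo, sigma_hi]`
#' degrees: large single-torsion moves at high temperature for barrier
#' crossing, fine moves while cooling. The steric term is a capped `r^-12`
#' repulsion over nonbonded pairs more than 3 bonds apart with per-role
#' contact radii; it is declared non-physical and exists only to prevent chain
#' self-intersection.
#'
#' @param sigma_hi,sigma_lo Move-size clamp (degrees).
#' @param t_ref Reference temperature (K) for the move-size scaling.
#' @param eps Steric prefactor (kcal/mol).
#' @param cap Per-pair steric energy cap (kcal/mol).
#' @param k_omega Planarity restoring constant (kcal/mol) for amide omega
#'   torsions; identically zero for rigid-builder conformers, retained for
#'   externally supplied coordinates.
#' @return List of move parameters.
#' @export
move_params <- function(sigma_hi = 30, sigma_lo = 2, t_ref = 600, eps = 1,
                        cap = 100, k_omega = 10) {
  list(sigma_hi = sigma_hi, sigma_lo = sigma_lo, t_ref = t_ref, eps = eps,
       cap = cap, k_omega = k_omega)
}

# assemble the parameter list consumed by the compiled energy/annealing kernels
.energy_params <- function(topology, restraints = restraint_set(),
                           weights = move_params()) {
  rs <- restraints$restraints
  rs <- rs[rs$active, , drop = FALSE]
  ab <- if (nrow(rs)) .resolve_restraint_atoms(topology, rs) else
    matrix(integer(), 0, 2)
  sp <- topology$steric_pairs
  list(pair_i = as.integer(sp$i - 1L), pair_j = as.integer(sp$j - 1L),
       sigma = as.numeric(sp$sigma), eps = weights$eps, cap = weights$cap,
       restr_a = as.integer(ab[, 1] - 1L), restr_b = as.integer(ab[, 2] - 1L),
       restr_upper = as.numeric(rs$r_upper), restr_k = as.numeric(rs$k),
       omega_quads = topology$omega_quads - 1L, k_omega = weights$k_omega,
       active_ids = rs$id)
}

#' Stand-in potential energy of a conformation
#'
#' Substitute for a molecular-mechanics force field at desk scale:
#' `steric + torsion + restraint`, where steric is the capped `r^-12`
#' repulsion, torsion is an amide-planarity term (zero for built conformers),
#' and restraint is [total_restraint_energy()] over active restraints.
#' Overlapping atoms (r < 0.01 A) contribute the cap and set the `clash` flag
#' rather than raising an error.
#'
#' @param conf A `conformation`.
#' @param restraints A [restraint_set()].
#' @param weights [move_params()] list (steric/torsion constants).
#' @return An `energy_breakdown` list: `steric`, `torsion`, `restraint`,
#'   `total`, `per_restraint`, `clash`.
#' @export
stand_in_energy <- function(conf, restraints = restraint_set(),
                            weights = move_params()) {
  par <- .energy_params(conf$topology, restraints, weights)
  e <- .energy_cpp(conf$coords, par)
  e$per_restraint <- setNames(as.numeric(e$per_restraint), par$active_ids)
  class(e) <- "energy_breakdown"
  e
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf(
    "energy_breakdown: total %.3f (steric %.3f, torsion %.3f, restraint %.3f) kcal/mol\n",
    x$total, x$steric, x$torsion, x$restraint))
  invisible(x)
}

#' Run one restrained simulated-annealing replica
#'
#' Deterministic given `(inputs, seed)`. Starting structure defaults to the
#' fully extended (all-180) conformer. Infeasible restraints do not error:
#' the replica completes and reports its irreducible penalty.
#'
#' @param topology A [foldamer_topology].
#' @param restraints A [restraint_set()].
#' @param schedule An [anneal_schedule()].
#' @param seed Integer seed.
#' @param start Optional starting [torsion_state()].
#' @param weights [move_params()].
#' @param replica_id Identifier stored on the result.
#' @return A `replica_result`: final torsions and conformation, energy
#'   breakdown, per-restraint penalties, acceptance rate, seed.
#' @export
run_annealing <- function(topology, restraints, schedule, seed,
                          start = NULL, weights = move_params(),
                          replica_id = 1L) {
  stopifnot(inherits(schedule, "anneal_schedule"))
  if (is.null(start)) start <- extended_torsions(topology)
  v0 <- .torsion_vector(topology, start)
  par <- .energy_params(topology, restraints, weights)
  zm <- topology$zmatrix
  n_tor <- 2L * nrow(topology$residues)
  steps <- as.integer(round(schedule$stages$duration * schedule$steps_per_ps))
  set.seed(as.integer(seed))
  res <- .anneal_cpp(zm[, 1:3, drop = FALSE] - 1L, zm[, "bond"], zm[, "angle"],
                     zm[, "toroff"], as.integer(zm[, "link"]), v0, par,
                     schedule$stages$temperature, steps,
                     weights$sigma_hi, weights$t_ref, weights$sigma_lo,
                     seq_len(n_tor))
  coords <- res$coords
  rownames(coords) <- topology$atoms$label
  n <- nrow(topology$residues)
  tor <- wrap_angle(as.numeric(res$torsions))
  final <- torsion_state(topology$residues$position_index,
                         tor[seq(1, 2 * n, by = 2)], tor[seq(2, 2 * n, by = 2)])
  structure(list(
    replica_id = replica_id, seed = seed,
    torsions = final,
    conformation = conformation(topology, coords,
                                sprintf("sa_replica_%d_seed_%d", replica_id,
                                        seed)),
    energy = list(steric = res$steric, torsion = res$torsion,
                  restraint = res$restraint, total = res$total),
    per_restraint = setNames(as.numeric(res$per_restraint), par$active_ids),
    acceptance_rate = if (res$steps > 0) res$accepted / res$steps else 0,
    initial_total = res$initial_total,
    clash = res$clash
  ), class = "replica_result")
}

#' @export
print.replica_result <- function(x, ...) {
  cat(sprintf(
    "replica_result %d (seed %d): total %.2f kcal/mol, restraint %.2f, acceptance %.2f\n",
    x$replica_id, x$seed, x$energy$total, x$energy$restraint,
    x$acceptance_rate))
  invisible(x)
}

#' Run a replica campaign of simulated-annealing searches
#'
#' Replica `i` uses seed `base_seed + i - 1`, so campaigns are deterministic
#' and order-stable; the default replica count follows the 100-parallel-runs
#' protocol.
#'
#' @param topology A [foldamer_topology].
#' @param restraints A [restraint_set()].
#' @param schedule An [anneal_schedule()].
#' @param n_replicas Number of replicas (default 100).
#' @param base_seed Seed of replica 1.
#' @param start,weights Passed to [run_annealing()].
#' @return List of `replica_result` (class `sa_campaign`).
#' @export
run_campaign <- function(topology, restraints, schedule, n_replicas = 100,
                         base_seed = 1L, start = NULL,
                         weights = move_params()) {
  if (n_replicas < 1L) stop("value error: n_replicas must be >= 1")
  out <- vector("list", n_replicas)
  for (i in seq_len(n_replicas))
    out[[i]] <- run_annealing(topology, restraints, schedule,
                              seed = base_seed + i - 1L, start = start,
                              weights = weights, replica_id = i)
  class(out) <- "sa_campaign"
  out
}

#' @export
print.sa_campaign <- function(x, ...) {
  tot <- vapply(x, function(r) r$energy$total, 0)
  cat(sprintf("sa_campaign: %d replicas, total energy %.2f-%.2f kcal/mol\n",
              length(x), min(tot), max(tot)))
  invisible(x)
}
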