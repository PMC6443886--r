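# Iterative restraint pruning: run an SA campaign, flag restraints whose
# penalty statistic exceeds the ceiling as spectral-interpretation artifacts,
# deactivate them, repeat until no restraint passes the ceiling.
#
# Note on the inequality direction: the source protocol's wording ("penalties
# < 5 kcal/mol ... removed") contradicts its own stopping rule ("until no
# restraint passed the penalty ceiling") and NOE practice; restraints are
# removed when the statistic EXCEEDS the ceiling.

#' Pruning configuration
#'
#' @param penalty_ceiling Ceiling in kcal/mol (default 5).
#' @param penalty_statistic Aggregation of a restraint's penalties across
#'   replicas: `"min"` (per-replica minimum, the default: a restraint is an
#'   artifact only if even the best replica violates it), `"mean"` or
#'   `"median"` for sensitivity analysis.
#' @param max_iterations Cap on refinement iterations; defaults (NULL) to the
#'   initial restraint count, which guarantees termination.
#' @return A `pruning_config`.
#' @export
pruning_config <- function(penalty_ceiling = .DEFAULT_PENALTY_CEILING,
                           penalty_statistic = c("min", "mean", "median"),
                           max_iterations = NULL) {
  if (penalty_ceiling < 0) stop("value error: ceiling must be >= 0")
  if (!is.null(max_iterations) && max_iterations < 1L)
    stop("value error: max_iterations must be >= 1")
  structure(list(penalty_ceiling = penalty_ceiling,
                 penalty_statistic = match.arg(penalty_statistic),
                 max_iterations = max_iterations),
            class = "pruning_config")
}

# per-restraint penalty statistic across replica results
.penalty_statistics <- function(results, ids, statistic) {
  mat <- vapply(results, function(r) {
    if (!all(as.character(ids) %in% names(r$per_restraint)))
      stop("value error: replica results lack penalties for the active set")
    r$per_restraint[as.character(ids)]
  }, numeric(length(ids)))
  mat <- matrix(mat, nrow = length(ids))
  f <- switch(statistic, min = function(x) min(x), mean = mean,
              median = stats::median)
  setNames(apply(mat, 1, f), ids)
}

#' One pruning pass over campaign results
#'
#' Computes the configured penalty statistic per active restraint across the
#' replicas and deactivates every restraint whose statistic exceeds the
#' ceiling. Removal is deactivation: the audit trail is preserved in the
#' restraint table and the pruning history.
#'
#' @param results List of `replica_result` (an `sa_campaign`).
#' @param set A [restraint_set()].
#' @param cfg A [pruning_config()].
#' @return List with the updated `set` and `removed` (ids, possibly empty).
#' @export
prune_once <- function(results, set, cfg = pruning_config()) {
  if (length(results) == 0L) stop("value error: empty results list")
  rs <- set$restraints
  ids <- rs$id[rs$active]
  if (length(ids) == 0L) {
    set$history <- c(set$history,
                     list(list(iteration = length(set$history) + 1L,
                               statistics = numeric(), removed = integer())))
    return(list(set = set, removed = integer()))
  }
  stat <- .penalty_statistics(results, ids, cfg$penalty_statistic)
  removed <- ids[stat > cfg$penalty_ceiling]
  rs$active[rs$id %in% removed] <- FALSE
  set$restraints <- rs
  set$history <- c(set$history,
                   list(list(iteration = length(set$history) + 1L,
                             statistics = stat,
                             removed = as.integer(removed))))
  list(set = set, removed = as.integer(removed))
}

#' Iterative restraint refinement
#'
#' Alternates [run_campaign()] and [prune_once()] until a pass removes nothing
#' or `max_iterations` is reached. The returned campaign was run on the
#' converged set (when the last pass removed restraints without converging,
#' one further campaign is run on the final set).
#'
#' @param topology A [foldamer_topology].
#' @param initial_set A [restraint_set()].
#' @param schedule An [anneal_schedule()].
#' @param cfg A [pruning_config()].
#' @param n_replicas,base_seed,weights Campaign parameters; each iteration `t`
#'   uses `base_seed + (t - 1) * n_replicas` so replicas never share seeds.
#' @return List: `set` (final restraint set), `results` (final campaign),
#'   `history` (per-iteration statistics and removals), `converged` flag,
#'   `iterations`.
#' @export
refine <- function(topology, initial_set, schedule, cfg = pruning_config(),
                   n_replicas = 100, base_seed = 1L,
                   weights = move_params()) {
  set <- initial_set
  max_it <- cfg$max_iterations
  if (is.null(max_it))
    max_it <- max(1L, sum(initial_set$restraints$active))
  converged <- FALSE
  results <- NULL
  it <- 0L
  while (it < max_it) {
    it <- it + 1L
    results <- run_campaign(topology, set, schedule, n_replicas,
                            base_seed + (it - 1L) * n_replicas,
                            weights = weights)
    step <- prune_once(results, set, cfg)
    set <- step$set
    if (length(step$removed) == 0L) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    # max_iterations exhausted with removals in the last pass: report the
    # campaign for the final active set
    results <- run_campaign(topology, set, schedule, n_replicas,
                            base_seed + it * n_replicas, weights = weights)
  }
  list(set = set, results = results, history = set$history,
       converged = converged, iterations = it)
}

#' Write a JSON refinement report
#'
#' @param refinement Result of [refine()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_refinement_json <- function(refinement, path) {
  hist <- lapply(refinement$history, function(h)
    list(iteration = h$iteration,
         statistics = as.list(h$statistics),
         removed = h$removed))
  jsonlite::write_json(
    list(converged = refinement$converged,
         iterations = refinement$iterations,
         n_active = sum(refinement$set$restraints$active),
         history = hist),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
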