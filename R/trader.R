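# The Trader optimizer. A population of C binary candidate solutions is
# partitioned into T trader groups; each iteration the group master
# distributes values to every slave, every slave retails (small random
# flips), one importing-exporting event mixes two masters, and group sizes
# are reallocated in proportion to group properties (sum of member scores,
# min_members guaranteed). Every trial is kept only if its score strictly
# improves, so the best-so-far never worsens; the stop rule is a score-
# evaluation budget, not an iteration count.

engine_args <- function(dataset, cfg) {
  list(cov = coverage_masks(dataset),
       se = unname(dataset$se),
       pairs = adverse_index_pairs(dataset),
       n_main = n_main_targets(dataset),
       hard = cfg$ddar_mode == "hard",
       lambda = cfg$lambda)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  expr
}

run_result <- function(raw, dataset, algorithm) {
  sel <- as.integer(raw$best)
  structure(list(
    algorithm = algorithm,
    selection = sel,
    drugs = dataset$drugs[sel == 1L],
    objective = raw$objective,
    score = raw$best_score,
    feasible = raw$feasible,
    evaluations = raw$evaluations,
    trace = raw$trace,
    group_sizes = raw$group_sizes
  ), class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("%s: objective %.4f (%s), %d evaluations, selected {%s}\n",
              x$algorithm, x$objective,
              if (x$feasible) "feasible" else "INFEASIBLE",
              as.integer(x$evaluations), paste(x$drugs, collapse = ", ")))
  invisible(x)
}

#' Run the Trader optimizer on an instance
#'
#' Maximizes the coverage-minus-mean-side-effect score (reported negated,
#' lower is better) over binary selections of candidate drugs. Seeded runs
#' are fully reproducible: same seed and configuration give an identical
#' trace.
#'
#' @param dataset a [candidate_dataset()].
#' @param cfg a [trader_config()]; `cfg$seed` (or the `seed` argument)
#'   seeds the run.
#' @param seed overrides `cfg$seed` when non-NULL.
#' @param record_groups record per-iteration group sizes (diagnostics).
#' @return A `run_result`: selection, selected drugs, reported objective,
#'   per-iteration best-so-far trace (first entry after initialization),
#'   evaluations used, feasibility flag, and optionally the group-size
#'   history (iterations x groups).
#' @export
run_trader <- function(dataset, cfg = trader_config(), seed = NULL,
                       record_groups = FALSE) {
  if (!inherits(dataset, "candidate_dataset") || !n_candidates(dataset)) {
    stop("run_trader needs a nonempty candidate_dataset", call. = FALSE)
  }
  a <- engine_args(dataset, cfg)
  raw <- with_seed(if (is.null(seed)) cfg$seed else seed,
    cpp_trader(a$cov, a$se, a$pairs, a$n_main,
               cfg$population_size, cfg$n_groups, cfg$min_members,
               cfg$max_evaluations, cfg$retailing_fraction,
               a$hard, a$lambda, record_groups))
  run_result(raw, dataset, "trader")
}

#' Random-search baseline
#'
#' Samples Bernoulli(0.5) selections (all-zero repaired) under the same
#' scoring and evaluation accounting as the Trader engine.
#'
#' @param dataset a [candidate_dataset()].
#' @param budget number of score evaluations.
#' @param seed integer seed.
#' @param cfg a [trader_config()] (adverse-reaction mode; `trace_every`
#'   checkpoints the best-so-far every `population_size` evaluations).
#' @return A `run_result`.
#' @export
random_search <- function(dataset, budget = 10000L, seed = NULL,
                          cfg = trader_config()) {
  stopifnot(budget >= 1L)
  a <- engine_args(dataset, cfg)
  raw <- with_seed(if (is.null(seed)) cfg$seed else seed,
    cpp_random_search(a$cov, a$se, a$pairs, a$n_main, as.integer(budget),
                      a$hard, a$lambda, cfg$population_size))
  run_result(raw, dataset, "random")
}

#' Hill-climbing baseline
#'
#' First-improvement single-bit flips in a random scan order, with a fresh
#' random restart whenever no neighbor improves; shares the scoring and
#' evaluation accounting of the other engines.
#'
#' @inheritParams random_search
#' @return A `run_result`.
#' @export
hill_climb <- function(dataset, budget = 10000L, seed = NULL,
                       cfg = trader_config()) {
  stopifnot(budget >= 1L)
  a <- engine_args(dataset, cfg)
  raw <- with_seed(if (is.null(seed)) cfg$seed else seed,
    cpp_hill_climb(a$cov, a$se, a$pairs, a$n_main, as.integer(budget),
                   a$hard, a$lambda, cfg$population_size))
  run_result(raw, dataset, "hillclimb")
}

#' Exhaustive oracle: exact optimum by full enumeration
#'
#' Enumerates every nonempty selection (up to 20 candidates), applying the
#' identical score as the optimizers, and returns the global optimum.
#' Deterministic.
#'
#' @param dataset a [candidate_dataset()] with at most 20 candidates.
#' @param cfg a [trader_config()] (adverse-reaction mode).
#' @return An `oracle_result`: `optimal_selection` (binary vector),
#'   `optimal_objective` (reported scale, lower is better), `enumerated`
#'   (count of feasible nonempty selections evaluated).
#' @export
exhaustive_oracle <- function(dataset, cfg = trader_config()) {
  m <- n_candidates(dataset)
  if (m > 20L) {
    stop("exhaustive oracle supports at most 20 candidates", call. = FALSE)
  }
  a <- engine_args(dataset, cfg)
  raw <- cpp_oracle(a$cov, a$se, a$pairs, a$n_main, a$hard, a$lambda)
  structure(list(
    optimal_selection = as.integer(raw$optimal_selection),
    optimal_score = raw$optimal_score,
    optimal_objective = raw$optimal_objective,
    enumerated = raw$enumerated
  ), class = "oracle_result")
}

#' @export
print.oracle_result <- function(x, ...) {
  cat(sprintf("oracle: objective %.4f over %d feasible selections\n",
              x$optimal_objective, as.integer(x$enumerated)))
  invisible(x)
}
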