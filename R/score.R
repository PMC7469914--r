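# The combination objective. Internally the score of a selection is
# maximized:
#
#   score = AT - sum(SE_i over selected) / (number selected)
#
# where AT is the number of distinct main targets covered by the union of
# the selected drugs. All reported objectives negate the score so that
# lower is better (the convention of the printed benchmark tables, where
# every best value is the most negative). Under the hard adverse-reaction
# mode any selection containing an adverse pair scores a finite
# infeasibility sentinel, -(sum of all SE + number of main targets + 1),
# strictly worse than every feasible score; under penalty mode the score is
# reduced by lambda per violating pair.

#' Trader configuration
#'
#' @param population_size total number of candidate solutions C.
#' @param n_groups number of trader groups T (>= 2).
#' @param min_members guaranteed members per group M (default 2, which
#'   ensures no group is ever eliminated during regrouping).
#' @param max_evaluations score-function budget (>= `population_size`).
#' @param retailing_fraction fraction of the solution length bounding the
#'   number of bits a retailing move may flip (ceiling, floor 1).
#' @param ddar_mode adverse-reaction handling: `"hard"` (infeasible) or
#'   `"penalty"` (subtract `lambda` per violating pair).
#' @param lambda penalty weight per adverse pair (penalty mode only).
#' @param seed optional integer seed used by [run_trader()] and the
#'   baselines for reproducible runs.
#' @return A `trader_config` list.
#' @export
trader_config <- function(population_size = 50L, n_groups = 5L,
                          min_members = 2L, max_evaluations = 10000L,
                          retailing_fraction = 0.1,
                          ddar_mode = c("hard", "penalty"), lambda = 1,
                          seed = NULL) {
  ddar_mode <- match.arg(ddar_mode)
  C <- as.integer(population_size); T <- as.integer(n_groups)
  M <- as.integer(min_members)
  if (T < 2L) stop("n_groups must be >= 2", call. = FALSE)
  if (C < M * T) stop("population_size must be >= min_members * n_groups",
                      call. = FALSE)
  if (max_evaluations < C) {
    stop("max_evaluations must be at least population_size", call. = FALSE)
  }
  structure(list(population_size = C, n_groups = T, min_members = M,
                 max_evaluations = as.integer(max_evaluations),
                 retailing_fraction = retailing_fraction,
                 ddar_mode = ddar_mode, lambda = lambda, seed = seed),
            class = "trader_config")
}

#' Infeasibility sentinel of an instance
#'
#' Finite score assigned under hard adverse-reaction mode to any selection
#' containing an adverse pair; strictly worse than every feasible score.
#'
#' @param dataset a [candidate_dataset()].
#' @return scalar sentinel score (on the maximized scale).
#' @export
infeasible_sentinel <- function(dataset) {
  -(sum(dataset$se) + n_main_targets(dataset) + 1)
}

#' Score a selection of candidate drugs
#'
#' @param selection binary 0/1 vector over the instance's candidates.
#' @param dataset a [candidate_dataset()].
#' @param cfg a [trader_config()] (adverse-reaction mode and lambda).
#' @return scalar score on the maximized scale; negate for the reported
#'   (lower-is-better) objective.
#' @export
score_selection <- function(selection, dataset, cfg = trader_config()) {
  m <- length(dataset$drugs)
  stopifnot(length(selection) == m, all(selection %in% c(0, 1)))
  idx <- which(selection == 1)
  if (!length(idx)) {
    stop_classed("syntrader_empty_selection",
                 "all-zero selection has no defined score; repair it first")
  }
  at <- length(unique(unlist(dataset$coverage[idx], use.names = FALSE)))
  base <- at - sum(dataset$se[idx]) / length(idx)
  viol <- count_adverse_violations(selection, dataset)
  if (viol == 0L) return(base)
  if (cfg$ddar_mode == "hard") infeasible_sentinel(dataset)
  else base - cfg$lambda * viol

}

#' Count adverse-reaction violations in a selection
#' @inheritParams score_selection
#' @return number of selected unordered adverse pairs.
#' @export
count_adverse_violations <- function(selection, dataset) {
  if (!nrow(dataset$adverse)) return(0L)
  i <- match(dataset$adverse$drug_a, dataset$drugs)
  j <- match(dataset$adverse$drug_b, dataset$drugs)
  sum(selection[i] == 1 & selection[j] == 1)
}

#' Reported (lower-is-better) objective of a selection
#' @inheritParams score_selection
#' @return negated score.
#' @export
reported_objective <- function(selection, dataset, cfg = trader_config()) {
  -score_selection(selection, dataset, cfg)
}
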