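# R-level reference implementations of the Trader operators. These define
# the move semantics (flip / copy with improvement-only acceptance) on
# plain binary vectors and are the unit-testable counterparts of the
# compiled engine inside run_trader(). Each accepted-or-reverted trial
# consumes exactly one score evaluation.

repair_zero <- function(vec) {
  if (!any(vec == 1)) vec[sample.int(length(vec), 1L)] <- 1L
  vec
}

sample_distinct <- function(m, r) sample.int(m, r)

#' Initialize a Trader population
#'
#' Creates `population_size` solutions with i.i.d. Bernoulli(0.5) bits
#' (all-zero vectors repaired by setting one uniform random bit), assigns
#' groups round-robin so initial sizes are equal (+/-1), and scores every
#' solution (consuming `population_size` evaluations).
#'
#' @param dataset a [candidate_dataset()].
#' @param cfg a [trader_config()].
#' @return list with `population` (C x m 0/1 matrix), `groups` (1-based
#'   group index per solution), `scores`, `evaluations`.
#' @export
init_population <- function(dataset, cfg = trader_config()) {
  m <- n_candidates(dataset)
  C <- cfg$population_size
  pop <- matrix(as.integer(runif(C * m) < 0.5), nrow = C, ncol = m)
  for (i in seq_len(C)) pop[i, ] <- repair_zero(pop[i, ])
  groups <- ((seq_len(C) - 1L) %% cfg$n_groups) + 1L
  scores <- vapply(seq_len(C),
                   function(i) score_selection(pop[i, ], dataset, cfg),
                   numeric(1))
  list(population = pop, groups = groups, scores = scores, evaluations = C)
}

#' Proportional group quotas with largest-remainder rounding
#'
#' Each group receives `min_members` base members plus a share of the
#' distributable pool `C - min_members * T` proportional to its property
#' (sum of member scores). Properties are shifted by `-min + 1` when any
#' is nonpositive so the proportions are well defined; largest-remainder
#' rounding forces the shares to sum exactly to the pool.
#'
#' @param properties per-group property values (sum of member scores).
#' @param cfg a [trader_config()].
#' @return integer vector of group sizes summing to `population_size`,
#'   every entry >= `min_members`.
#' @export
group_quotas <- function(properties, cfg = trader_config()) {
  T <- cfg$n_groups; M <- cfg$min_members; C <- cfg$population_size
  stopifnot(length(properties) == T)
  pool <- C - M * T
  if (pool == 0L) return(rep(M, T))
  p <- properties
  if (min(p) <= 0) p <- p - min(p) + 1
  raw <- p / sum(p) * pool
  base <- floor(raw)
  rem <- pool - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(M + base)
}

#' Retailing: small random perturbation of a slave solution
#'
#' Flips R distinct positions (R uniform in 1..max(1, ceiling(m *
#' `retailing_fraction`))) of the slave via `V(K) <- |V(K) - 1|`; the trial
#' replaces the slave only if its score strictly improves, otherwise the
#' previous values are restored.
#'
#' @param slave binary vector (must not be its group's master).
#' @param dataset,cfg instance and configuration.
#' @return list: `vec` (resulting vector), `score`, `accepted`, `trial`.
#' @export
retailing_step <- function(slave, dataset, cfg = trader_config()) {
  m <- length(slave)
  rmax <- max(1L, as.integer(ceiling(m * cfg$retailing_fraction)))
  r <- sample.int(rmax, 1L)
  k <- sample_distinct(m, r)
  trial <- slave
  trial[k] <- abs(trial[k] - 1L)
  trial <- repair_zero(trial)
  accept_if_better(slave, trial, dataset, cfg)
}

#' Distributing: copy positions from the group master to a slave
#'
#' Copies R positions (R uniform in 1..m, positions sampled without
#' replacement) from the master to the slave, with improvement-only
#' acceptance.
#'
#' @param master,slave binary vectors from the same group; `master` is the
#'   group's best solution.
#' @inheritParams retailing_step
#' @return as [retailing_step()].
#' @export
distributing_step <- function(master, slave, dataset, cfg = trader_config()) {
  m <- length(slave)
  stopifnot(length(master) == m)
  r <- sample.int(m, 1L)
  k <- sample_distinct(m, r)
  trial <- slave
  trial[k] <- master[k]
  trial <- repair_zero(trial)
  accept_if_better(slave, trial, dataset, cfg)
}

#' Importing-exporting: copy positions between two group masters
#'
#' Copies R positions (ranges as in distributing) from the exporter master
#' to the importer master, with improvement-only acceptance. The two
#' masters must belong to distinct groups.
#'
#' @param exporter,importer binary master vectors.
#' @param exporter_group,importer_group their group indices.
#' @inheritParams retailing_step
#' @return as [retailing_step()] (the resulting importer).
#' @export
importing_exporting_step <- function(exporter, importer, exporter_group,
                                     importer_group, dataset,
                                     cfg = trader_config()) {
  if (exporter_group == importer_group) {
    stop("importing-exporting requires masters of distinct groups",
         call. = FALSE)
  }
  distributing_step(exporter, importer, dataset, cfg)
}

accept_if_better <- function(current, trial, dataset, cfg) {
  s_cur <- score_selection(current, dataset, cfg)
  s_new <- score_selection(trial, dataset, cfg)
  if (s_new > s_cur) {
    list(vec = trial, score = s_new, accepted = TRUE, trial = trial)
  } else {
    list(vec = current, score = s_cur, accepted = FALSE, trial = trial)
  }
}
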