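# Benchmark protocol: every algorithm runs n_runs times per instance under
# an equal score-evaluation budget, with per-run seeds; the report carries
# worst/best/mean/sample-STD, a 95% t-interval on the mean, a p-value
# against the random-search score distribution on the same instance and
# budget ("produced by chance"), one-sided Wilcoxon rank-sum comparisons
# against a base algorithm, and convergence / stability traces. All
# objectives are on the reported scale (negated score, lower is better).

ALGORITHM_RUNNERS <- function(cfg) {
  list(
    trader = function(ds, budget, seed) {
      cfg$max_evaluations <- as.integer(budget)
      run_trader(ds, cfg, seed = seed)
    },
    random = function(ds, budget, seed) random_search(ds, budget, seed, cfg),
    hillclimb = function(ds, budget, seed) hill_climb(ds, budget, seed, cfg)
  )
}

#' One-sided Wilcoxon rank-sum comparison of two score samples
#'
#' Tests whether the base algorithm is more efficient than the other, i.e.
#' whether its reported objectives are stochastically smaller. H0 (equal
#' performance) is rejected in favor of H1 (base more efficient) when
#' p < 0.05. The exact distribution is used when both samples have at most
#' 25 observations and no ties; otherwise the tie-corrected normal
#' approximation with continuity correction.
#'
#' @param base_scores,other_scores numeric samples of reported objectives
#'   (lower is better), each of size >= 2.
#' @return list: `p_value`, `decision` (`"H0"`/`"H1"`), `statistic`
#'   (rank-sum U of the base sample), `tie_warning`.
#' @export
wilcoxon_compare <- function(base_scores, other_scores) {
  stopifnot(length(base_scores) >= 2L, length(other_scores) >= 2L)
  pooled <- c(base_scores, other_scores)
  if (length(unique(pooled)) == 1L) {
    warning("constant identical samples; rank-sum test degenerate (p = 1)",
            call. = FALSE)
    return(list(p_value = 1, decision = "H0",
                statistic = length(base_scores) * length(other_scores) / 2,
                tie_warning = TRUE))
  }
  ties <- anyDuplicated(pooled) > 0L
  exact <- !ties && length(base_scores) <= 25L && length(other_scores) <= 25L
  wt <- suppressWarnings(
    stats::wilcox.test(base_scores, other_scores, alternative = "less",
                       exact = exact, correct = TRUE))
  list(p_value = unname(wt$p.value),
       decision = if (wt$p.value < 0.05) "H1" else "H0",
       statistic = unname(wt$statistic),
       tie_warning = ties)
}

ci_t95 <- function(x) {
  n <- length(x); mu <- mean(x); s <- stats::sd(x)
  if (n < 2L || s == 0) return(c(low = mu, high = mu))
  half <- stats::qt(0.975, n - 1L) * s / sqrt(n)
  c(low = mu - half, high = mu + half)
}

#' Run the benchmark protocol
#'
#' @param instances named list of [candidate_dataset()] objects.
#' @param algorithms subset of `c("trader", "random", "hillclimb")`; the
#'   first is the base for the pairwise Wilcoxon comparisons.
#' @param n_runs independent seeded runs per algorithm and instance (>= 2).
#' @param budget score-evaluation budget per run (equal across algorithms).
#' @param base_seed run r uses seed `base_seed + r - 1` for every
#'   algorithm.
#' @param cfg a [trader_config()] (population/group structure and
#'   adverse-reaction mode; its budget is overridden by `budget`).
#' @return A `benchmark_report`: `summary` (worst/best/mean/std/p_value/
#'   CI per instance x algorithm), `pairwise` (Wilcoxon vs the base),
#'   `raw` (per-run objectives), `convergence` (mean best objective per
#'   iteration checkpoint), `n_runs`, `budget`.
#' @export
run_benchmark <- function(instances, algorithms = c("trader", "random",
                                                    "hillclimb"),
                          n_runs = 50L, budget = 10000L, base_seed = 1L,
                          cfg = trader_config()) {
  stopifnot(n_runs >= 2L, length(instances) >= 1L)
  if (is.null(names(instances)) || any(!nzchar(names(instances)))) {
    stop("instances must be a named list", call. = FALSE)
  }
  algorithms <- match.arg(algorithms, c("trader", "random", "hillclimb"),
                          several.ok = TRUE)
  runners <- ALGORITHM_RUNNERS(cfg)
  seeds <- base_seed + seq_len(n_runs) - 1L

  raw <- list(); conv <- list()
  for (ins in names(instances)) {
    ds <- instances[[ins]]
    for (alg in union(algorithms, "random")) {  # random needed for p_chance
      objs <- numeric(n_runs)
      traces <- vector("list", n_runs)
      for (r in seq_len(n_runs)) {
        res <- runners[[alg]](ds, budget, seeds[r])
        objs[r] <- res$objective
        traces[[r]] <- res$trace
      }
      raw[[paste(ins, alg, sep = "\r")]] <- objs
      len <- max(lengths(traces))
      padded <- vapply(traces, function(tr) {
        c(tr, rep(tr[length(tr)], len - length(tr)))
      }, numeric(len))
      conv[[paste(ins, alg, sep = "\r")]] <-
        if (is.matrix(padded)) rowMeans(padded) else mean(padded)
    }
  }

  summary <- do.call(rbind, lapply(names(instances), function(ins) {
    do.call(rbind, lapply(algorithms, function(alg) {
      x <- raw[[paste(ins, alg, sep = "\r")]]
      chance <- raw[[paste(ins, "random", sep = "\r")]]
      ci <- ci_t95(x)
      p <- if (alg == "random") NA_real_ else {
        suppressWarnings(wilcoxon_compare(x, chance)$p_value)
      }
      data.frame(instance = ins, algorithm = alg,
                 worst = max(x), best = min(x), mean = mean(x),
                 std = stats::sd(x), p_value = p,
                 ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
                 n_runs = n_runs, stringsAsFactors = FALSE)
    }))
  }))

  base_alg <- algorithms[1]
  pairwise <- NULL
  if (length(algorithms) > 1L) {
    pairwise <- do.call(rbind, lapply(names(instances), function(ins) {
      base <- raw[[paste(ins, base_alg, sep = "\r")]]
      do.call(rbind, lapply(setdiff(algorithms, base_alg), function(alg) {
        cmp <- suppressWarnings(
          wilcoxon_compare(base, raw[[paste(ins, alg, sep = "\r")]]))
        data.frame(instance = ins, base = base_alg, algorithm = alg,
                   p_value = cmp$p_value, decision = cmp$decision,
                   stringsAsFactors = FALSE)
      }))
    }))
  }

  raw_df <- do.call(rbind, lapply(names(raw), function(key) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    data.frame(instance = parts[1], algorithm = parts[2],
               run = seq_along(raw[[key]]), objective = raw[[key]],
               stringsAsFactors = FALSE)
  }))

  conv_df <- do.call(rbind, lapply(names(conv), function(key) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    data.frame(instance = parts[1], algorithm = parts[2],
               iteration = seq_along(conv[[key]]),
               mean_best_objective = conv[[key]], stringsAsFactors = FALSE)
  }))

  structure(list(summary = summary, pairwise = pairwise, raw = raw_df,
                 convergence = conv_df, n_runs = n_runs, budget = budget,
                 base_algorithm = base_alg),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("benchmark_report: %d instance(s), %d run(s), budget %d\n",
              length(unique(x$summary$instance)), x$n_runs, x$budget))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Recompute benchmark statistics from stored raw scores
#'
#' Pure function of the raw per-run objectives; regeneration from the same
#' raw table is bit-identical.
#'
#' @param raw data frame with columns instance, algorithm, run, objective.
#' @return summary data frame as in [run_benchmark()] (without p-values
#'   against chance unless a `random` algorithm is present).
#' @export
summarize_raw_scores <- function(raw) {
  keys <- unique(raw[c("instance", "algorithm")])
  do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    ins <- keys$instance[i]; alg <- keys$algorithm[i]
    x <- raw$objective[raw$instance == ins & raw$algorithm == alg]
    chance <- raw$objective[raw$instance == ins & raw$algorithm == "random"]
    ci <- ci_t95(x)
    p <- if (alg == "random" || !length(chance)) NA_real_ else {
      suppressWarnings(wilcoxon_compare(x, chance)$p_value)
    }
    data.frame(instance = ins, algorithm = alg, worst = max(x),
               best = min(x), mean = mean(x), std = stats::sd(x),
               p_value = p, ci_low = unname(ci["low"]),
               ci_high = unname(ci["high"]), n_runs = length(x),
               stringsAsFactors = FALSE)
  }))
}

#' Write a benchmark report as TSV files
#'
#' Emits `table2.tsv` (summary statistics), `table4.tsv` (pairwise Wilcoxon
#' p-values), `convergence.tsv`, `stability.tsv` (per-run best objectives)
#' and `raw_scores.tsv` into `dir`.
#'
#' @param report a `benchmark_report`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_benchmark_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, file) {
    utils::write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  w(report$summary, "table2.tsv")
  if (!is.null(report$pairwise)) w(report$pairwise, "table4.tsv")
  w(report$convergence, "convergence.tsv")
  w(report$raw, "stability.tsv")
  w(report$raw, "raw_scores.tsv")
  invisible(dir)
}
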