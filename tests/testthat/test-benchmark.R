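# Benchmark protocol: repeated seeded runs, summary statistics, Wilcoxon
# comparisons, report regeneration and TSV export.

test_that("a deterministically solved instance reports zero spread", {
  ds <- single_candidate_instance()
  rep <- run_benchmark(list(TRIV = ds), c("trader", "random"), n_runs = 10,
                       budget = 60,
                       cfg = trader_config(population_size = 10L,
                                           n_groups = 2L,
                                           max_evaluations = 60L))
  tr <- rep$summary[rep$summary$algorithm == "trader", ]
  expect_equal(tr$worst, -1); expect_equal(tr$best, -1)
  expect_equal(tr$mean, -1); expect_equal(tr$std, 0)
  expect_equal(tr$ci_low, -1); expect_equal(tr$ci_high, -1)
  # worst >= mean >= best on the reported scale
  expect_true(all(rep$summary$worst >= rep$summary$mean &
                  rep$summary$mean >= rep$summary$best))
  expect_true(all(rep$summary$ci_low <= rep$summary$mean &
                  rep$summary$mean <= rep$summary$ci_high))
})

test_that("wilcoxon_compare retains H0 on itself and rejects on separation", {
  x <- c(-3.2, -2.9, -4.1, -3.3, -2.2)
  self <- suppressWarnings(wilcoxon_compare(x, x))
  expect_gte(self$p_value, 0.05)
  expect_equal(self$decision, "H0")

  # fully separated samples, n = 50 vs 50: base holds the entire lower
  # rank block, so the base U statistic is 0 and the other-sample U is
  # n1 * n2 = 2500; H1 at any practical alpha
  base <- -(101:150); other <- -(1:50)
  cmp <- wilcoxon_compare(base, other)
  expect_equal(unname(cmp$statistic), 0)
  expect_equal(50 * 50 - cmp$statistic, 2500)
  expect_lt(cmp$p_value, 1e-15)
  expect_equal(cmp$decision, "H1")

  # small-sample overlapping path stays a valid probability
  small <- wilcoxon_compare(c(-2, -1), c(-1.5, -0.5))
  expect_gt(small$p_value, 0); expect_lte(small$p_value, 1)

  expect_warning(deg <- wilcoxon_compare(rep(-1, 5), rep(-1, 5)), "constant")
  expect_equal(deg$p_value, 1)
  expect_equal(deg$decision, "H0")
})

test_that("STD and CI match an independent implementation and regeneration is pure", {
  ds <- generate_instance(generator_spec(12, 3, seed = 21))
  rep <- run_benchmark(list(G = ds), c("trader", "random"), n_runs = 12,
                       budget = 300,
                       cfg = trader_config(population_size = 20L,
                                           n_groups = 4L,
                                           max_evaluations = 300L))
  for (alg in c("trader", "random")) {
    x <- rep$raw$objective[rep$raw$algorithm == alg & rep$raw$instance == "G"]
    row <- rep$summary[rep$summary$algorithm == alg, ]
    n <- length(x); mu <- sum(x) / n
    s2 <- sum((x - mu)^2) / (n - 1)  # direct sample-variance formula
    half <- qt(0.975, n - 1) * sqrt(s2 / n)
    expect_equal(row$mean, mu)
    expect_equal(row$std, sqrt(s2))
    expect_equal(row$ci_low, mu - half)
    expect_equal(row$ci_high, mu + half)
  }
  # regeneration from stored raw scores is bit-identical
  expect_identical(summarize_raw_scores(rep$raw), summarize_raw_scores(rep$raw))
  regen <- summarize_raw_scores(rep$raw)
  key <- order(rep$summary$instance, rep$summary$algorithm)
  key2 <- order(regen$instance, regen$algorithm)
  for (col in c("worst", "best", "mean", "std", "ci_low", "ci_high")) {
    expect_identical(rep$summary[[col]][key], regen[[col]][key2], info = col)
  }
})

test_that("benchmark reports write the protocol TSV files", {
  ds <- generate_instance(generator_spec(8, 2, seed = 2))
  rep <- run_benchmark(list(A = ds), c("trader", "random", "hillclimb"),
                       n_runs = 4, budget = 100,
                       cfg = trader_config(population_size = 10L,
                                           n_groups = 2L,
                                           max_evaluations = 100L))
  dir <- withr::local_tempdir()
  write_benchmark_report(rep, dir)
  for (f in c("table2.tsv", "table4.tsv", "convergence.tsv",
              "stability.tsv", "raw_scores.tsv")) {
    expect_true(file.exists(file.path(dir, f)), info = f)
  }
  t2 <- read.delim(file.path(dir, "table2.tsv"))
  expect_setequal(t2$algorithm, c("trader", "random", "hillclimb"))
  t4 <- read.delim(file.path(dir, "table4.tsv"))
  expect_equal(t4$base[1], "trader")
  expect_true(all(t4$p_value >= 0 & t4$p_value <= 1))
  conv <- read.delim(file.path(dir, "convergence.tsv"))
  expect_true(all(c("instance", "algorithm", "iteration",
                    "mean_best_objective") %in% names(conv)))
  expect_error(run_benchmark(list(ds), "trader"), "named")
})
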