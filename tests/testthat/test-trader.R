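# Trader operators and the full optimizer run.

test_that("init_population splits groups evenly, repairs zeros, and is seeded", {
  ds <- generate_instance(generator_spec(6, 2, seed = 1))
  cfg <- trader_config(population_size = 8L, n_groups = 2L,
                       max_evaluations = 100L)
  set.seed(4)
  st <- init_population(ds, cfg)
  expect_equal(as.vector(table(st$groups)), c(4L, 4L))
  expect_equal(st$evaluations, 8L)
  expect_true(all(st$population %in% c(0L, 1L)))
  expect_true(all(rowSums(st$population) >= 1))
  set.seed(4)
  expect_identical(init_population(ds, cfg), st)

  # m = 1: every solution is forced to [1]
  ds1 <- single_candidate_instance()
  set.seed(9)
  st1 <- init_population(ds1, cfg)
  expect_true(all(st1$population == 1L))
})

test_that("group quotas follow largest-remainder proportional allocation", {
  cfg <- trader_config(population_size = 40L, n_groups = 4L,
                       max_evaluations = 100L)
  # shifted properties 10:20:30:40, pool 32 -> shares 3,6,10,13
  expect_equal(group_quotas(c(10, 20, 30, 40), cfg), c(5L, 8L, 12L, 15L))
  # equal properties -> equal sizes
  expect_equal(group_quotas(rep(7, 4), cfg), rep(10L, 4))
  # zero distributable pool -> every group exactly min_members
  cfg0 <- trader_config(population_size = 8L, n_groups = 4L,
                        max_evaluations = 100L)
  expect_equal(group_quotas(c(-3, 0, 5, 100), cfg0), rep(2L, 4))
  # negative properties are shifted, never dropped; sizes still sum to C
  q <- group_quotas(c(-10, -5, 0, 5), cfg)
  expect_equal(sum(q), 40L)
  expect_true(all(q >= 2L))
})

test_that("retailing flips few bits and keeps changes only when improving", {
  ds <- generate_instance(generator_spec(4, 2, seed = 2))
  cfg <- trader_config(max_evaluations = 100L)
  set.seed(21)
  for (i in 1:50) {
    slave <- rbinom(4, 1, 0.5)
    if (!sum(slave)) slave[1] <- 1L
    res <- retailing_step(slave, ds, cfg)
    # m = 4 -> R = 1 always (ceiling(0.4) = 1); one flipped bit, except
    # when flipping empties the vector and the repair sets another bit
    expect_lte(sum(res$trial != slave), if (sum(slave) > 1) 1L else 2L)
    if (res$accepted) {
      expect_gt(score_selection(res$vec, ds, cfg),
                score_selection(slave, ds, cfg))
    } else {
      expect_identical(res$vec, slave)
    }
    expect_true(all(res$vec %in% c(0L, 1L)))
  }
})

test_that("distributing copies master values; full copy and no-op behave", {
  ds <- generate_instance(generator_spec(3, 2, seed = 3))
  cfg <- trader_config(max_evaluations = 100L)
  master <- c(1L, 1L, 0L)
  set.seed(5)
  for (i in 1:50) {
    slave <- c(0L, 0L, 1L)
    res <- distributing_step(master, slave, ds, cfg)
    # every trial bit comes from master or slave at that position
    expect_true(all(res$trial == master | res$trial == slave))
  }
  # master and slave identical: trial is always the same vector
  res <- distributing_step(master, master, ds, cfg)
  expect_identical(res$vec, master)
  expect_false(res$accepted)
})

test_that("importing-exporting requires masters of distinct groups", {
  ds <- generate_instance(generator_spec(3, 2, seed = 3))
  cfg <- trader_config(max_evaluations = 100L)
  expect_error(
    importing_exporting_step(c(1L, 0L, 1L), c(0L, 1L, 0L), 2L, 2L, ds, cfg),
    "distinct groups")
  set.seed(8)
  res <- importing_exporting_step(c(1L, 0L, 1L), c(0L, 1L, 0L), 1L, 2L,
                                  ds, cfg)
  expect_true(all(res$vec %in% c(0L, 1L)))
})

test_that("run_trader finds the unique optimum of a single-candidate instance", {
  ds <- single_candidate_instance()
  cfg <- trader_config(population_size = 10L, n_groups = 2L,
                       max_evaluations = 11L)
  res <- run_trader(ds, cfg, seed = 1)
  expect_equal(res$objective, -1)
  expect_equal(res$selection, 1L)
  expect_equal(res$drugs, "D1")
})

test_that("seeded runs are bit-identical and traces never worsen", {
  ds <- generate_instance(generator_spec(15, 4, ddar_density = 0.1, seed = 7))
  cfg <- trader_config(max_evaluations = 2000L)
  a <- run_trader(ds, cfg, seed = 123, record_groups = TRUE)
  b <- run_trader(ds, cfg, seed = 123, record_groups = TRUE)
  expect_identical(a$trace, b$trace)
  expect_identical(a$selection, b$selection)
  expect_identical(a$group_sizes, b$group_sizes)
  c_ <- run_trader(ds, cfg, seed = 124)
  expect_false(identical(a$trace, c_$trace))
  # reported objective is best-so-far: non-increasing
  expect_true(all(diff(a$trace) <= 0))
  # reported solution scores back to the reported objective
  expect_equal(reported_objective(a$selection, ds, cfg), a$objective)
})

test_that("group sizes always sum to C with every group at least M", {
  ds <- generate_instance(generator_spec(12, 3, ddar_density = 0.15, seed = 9))
  for (seed in 1:5) {
    cfg <- trader_config(population_size = 30L, n_groups = 5L,
                         max_evaluations = 1500L)
    res <- run_trader(ds, cfg, seed = seed, record_groups = TRUE)
    expect_true(all(rowSums(res$group_sizes) == 30L))
    expect_true(all(res$group_sizes >= 2L))
    expect_true(all(res$selection %in% c(0L, 1L)))
    # evaluation accounting: budget overshoot bounded by one iteration
    per_iter <- 2 * (30L - 5L) + 1
    expect_lte(res$evaluations, 1500 + per_iter)
    expect_gte(res$evaluations, 1500)
  }
})

test_that("hard mode never reports an adverse selection when feasible ones exist", {
  for (seed in 1:5) {
    ds <- generate_instance(generator_spec(10, 2, ddar_density = 0.4,
                                           seed = seed))
    res <- run_trader(ds, trader_config(max_evaluations = 1200L), seed = seed)
    expect_true(res$feasible)
    expect_equal(count_adverse_violations(res$selection, ds), 0L)
  }
})

test_that("trader configuration rejects inconsistent shapes", {
  expect_error(trader_config(population_size = 5L, n_groups = 5L), ">=")
  expect_error(trader_config(n_groups = 1L), ">= 2")
  expect_error(trader_config(max_evaluations = 10L), "at least")
  expect_error(run_trader(list(), trader_config()), "candidate_dataset")
})
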