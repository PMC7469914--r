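# Relational matrix IO and candidate-instance construction.

test_that("TSV matrices parse, reject unknown labels, and handle empty files", {
  dir <- withr::local_tempdir()
  write_fixture_tsvs(dir)
  mats <- load_matrices(dir)
  expect_s3_class(mats$drug_targets, "drug_targets")
  expect_equal(nrow(mats$drug_targets), 3L)
  expect_setequal(unique(mats$drug_targets$drug), c("d1", "d2"))
  expect_setequal(unique(mats$drug_targets$target), c("t1", "t2"))

  # header-only files are valid empty matrices
  writeLines("drug\ttarget\ttarget_class\teffect",
             file.path(dir, "drug_target.tsv"))
  writeLines("drug_a\tdrug_b", file.path(dir, "ddar.tsv"))
  empty <- load_matrices(dir)
  expect_equal(nrow(empty$drug_targets), 0L)
  expect_equal(nrow(empty$ddar), 0L)

  # unknown effect label names the offending line (header = line 1)
  writeLines(c("drug\ttarget\ttarget_class\teffect",
               "d1\tt1\tprotein\tBLOCKS"),
             file.path(dir, "drug_target.tsv"))
  expect_error(load_matrices(dir), "BLOCKS.*line 2")

  expect_error(load_matrices(file.path(dir, "nope")), "not found")
})

test_that("matrix round-trip through TSV reproduces identical cells", {
  mats <- list(
    drug_targets = rule_fixture()$dt,
    drug_diseases = drug_diseases(c("CAND", "D_E"), c("ht", "ht")),
    ddar = adverse_pairs(c("D_E", "CAND"), c("CAND", "D_P1")),
    relations = rule_fixture()$relations,
    formulas = c(CAND = "C24H29N5O3")
  )
  dir <- withr::local_tempdir()
  write_matrices(mats, dir)
  back <- load_matrices(dir)
  for (nm in c("drug_targets", "drug_diseases", "ddar", "relations")) {
    expect_equal(as.data.frame(back[[nm]]), as.data.frame(mats[[nm]]),
                 info = nm)
  }
  expect_equal(back$formulas, mats$formulas)
})

test_that("adverse pairs are normalized symmetric with zero diagonal", {
  ap <- adverse_pairs(c("b", "a", "b"), c("a", "b", "a"))
  expect_equal(nrow(ap), 1L)
  expect_equal(ap$drug_a, "a")
  expect_error(adverse_pairs("x", "x"), "diagonal")
  ds <- generate_instance(generator_spec(10, 2, ddar_density = 0.3, seed = 3))
  A <- adverse_matrix(ds)
  expect_true(isSymmetric(A))
  expect_true(all(diag(A) == FALSE))
})

test_that("build_candidate_dataset filters by effect match and counts SE", {
  dt <- drug_targets(
    drug   = c("G", "G", "A", "A", "A", "A", "A", "B", "C"),
    target = c("t1", "t2", "t1", "x1", "x2", "x3", "x4", "t1", "t9"),
    target_class = rep("protein", 9),
    effect = c("INH", "AGO", "INH", "INH", "INH", "INH", "INH", "AGO", "INH")
  )
  ht <- ht_targets(c("t1", "t2"), c("INH", "AGO"))
  # A matches t1 with INH (4 extra targets -> SE 4); B touches t1 with the
  # wrong effect; C touches nothing relevant
  ds <- build_candidate_dataset("G", ht, dt, adverse_pairs(), c("A", "B", "C"))
  expect_equal(ds$drugs, "A")
  expect_equal(unname(ds$se["A"]), 4)
  expect_equal(ds$coverage[["A"]], "t1")
  expect_equal(nrow(ds$main_targets), 2L)

  expect_error(build_candidate_dataset("NOPE", ht, dt, adverse_pairs(), "A"),
               class = "syntrader_lookup_error")
  expect_error(build_candidate_dataset("G", ht, dt, adverse_pairs(), c("B", "C")),
               class = "syntrader_empty_instance")
})

test_that("a Nicardipine-shaped pool yields 15 targets, 4 main, 40 candidates", {
  # given drug hits 15 targets of which 4 are disease targets; 40 mined
  # drugs each hit at least one main target with the required effect
  main_t <- sprintf("mt%d", 1:4)
  side_t <- sprintf("st%d", 1:11)
  eff <- c("INH", "ANT", "INH", "AGO")
  rows <- data.frame(drug = "NIC", target = c(main_t, side_t),
                     target_class = "protein",
                     effect = c(eff, rep("INH", 11)),
                     stringsAsFactors = FALSE)
  set.seed(99)
  for (i in 1:40) {
    j <- sample(4, 1)
    rows <- rbind(rows, data.frame(drug = sprintf("c%02d", i),
                                   target = main_t[j],
                                   target_class = "protein",
                                   effect = eff[j], stringsAsFactors = FALSE))
  }
  dt <- drug_targets(rows$drug, rows$target, rows$target_class, rows$effect)
  ht <- ht_targets(main_t, eff)
  ds <- build_candidate_dataset("NIC", ht, dt, adverse_pairs(),
                                sprintf("c%02d", 1:40))
  expect_equal(length(unique(dt$target[dt$drug == "NIC"])), 15L)
  expect_equal(nrow(ds$main_targets), 4L)
  expect_equal(n_candidates(ds), 40L)
})

test_that("SE counts equal a brute-force recount from the raw matrices", {
  for (seed in 1:5) {
    ds <- generate_instance(generator_spec(12, 3, seed = seed))
    mats <- instance_as_matrices(ds)
    rebuilt <- build_candidate_dataset(ds$given_drug, mats$ht,
                                       mats$drug_targets, mats$ddar,
                                       ds$drugs)
    expect_equal(rebuilt$se, ds$se)
    expect_equal(rebuilt$coverage, ds$coverage)
    # direct recount from the edge list
    key_ht <- paste(mats$ht$target, mats$ht$effect)
    for (d in ds$drugs) {
      rows <- mats$drug_targets[mats$drug_targets$drug == d, ]
      covered <- sum(paste(rows$target, rows$effect) %in% key_ht)
      expect_equal(unname(ds$se[d]), nrow(rows) - covered)
    }
    expect_lte(n_candidates(ds), length(unique(mats$drug_targets$drug)) - 1L)
  }
})

test_that("candidate_dataset validates coverage and adverse membership", {
  ht <- ht_targets(c("T1", "T2"), c("INH", "INH"))
  expect_error(
    candidate_dataset("G", ht, c("a", "b"), list("T1", character(0)), c(0, 0)),
    "nonempty subset")
  expect_error(
    candidate_dataset("G", ht, c("a", "b"), list("T1", "T9"), c(0, 0)),
    "nonempty subset")
  expect_error(
    candidate_dataset("G", ht, "a", list("T1"), -1),
    "nonnegative")
  expect_error(
    candidate_dataset("G", ht, c("a", "b"), list("T1", "T2"), c(0, 0),
                      adverse_pairs("a", "zz")),
    "non-candidate")
})
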