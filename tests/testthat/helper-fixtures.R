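# Shared fixtures and independent oracles used across the suite.

# Independent brute-force optimum: plain R enumeration over subset masks,
# recomputing the score from the raw dataset fields (no shared code with
# the compiled engines). `reverse` enumerates masks high-to-low as a
# cross-check of tie-breaking independence.
brute_oracle <- function(dataset, hard = TRUE, lambda = 1, reverse = FALSE) {
  m <- length(dataset$drugs)
  stopifnot(m <= 16)
  A <- adverse_matrix(dataset)
  best <- -Inf
  best_sel <- NULL
  n_feasible <- 0L
  masks <- seq_len(2^m - 1)
  if (reverse) masks <- rev(masks)
  for (msk in masks) {
    sel <- as.integer(intToBits(msk)[1:m])
    idx <- which(sel == 1L)
    viol <- sum(A[idx, idx, drop = FALSE]) / 2
    if (hard && viol > 0) next
    at <- length(unique(unlist(dataset$coverage[idx], use.names = FALSE)))
    s <- at - sum(dataset$se[idx]) / length(idx) - if (hard) 0 else lambda * viol
    n_feasible <- n_feasible + 1L
    if (s > best) { best <- s; best_sel <- sel }
  }
  list(score = best, objective = -best, selection = best_sel,
       enumerated = n_feasible)
}

# Hand-built 12-drug fixture exercising all five rule templates plus the
# agonist/antagonist counter-example (a drug agonizing a receptor is not
# admitted when the disease needs an antagonist on it).
rule_fixture <- function() {
  dt <- drug_targets(
    drug = c("CAND",  "ANGII", "D_E",   "D_P1", "D_P2", "D_EX",
             "D_EY",  "D_OUT", "D_MULTI", "D_MULTI", "D_WRONG",
             "D_E1",  "D_NONE"),
    target = c("P_AT1R", "P_AT1R", "E_ACE", "P_R1", "P_R2", "E_X",
               "E_Y", "T_OUT", "P2", "E_ACE", "P2",
               "E1", "T_OUT2"),
    target_class = c("protein", "protein", "enzyme", "protein", "protein",
                     "enzyme", "enzyme", "protein", "protein", "enzyme",
                     "protein", "enzyme", "protein"),
    effect = c("ANT", "AGO", "INH", "AGO", "ANT", "IND",
               "INH", "INH", "INH", "ANT", "AGO",
               "INH", "IND")
  )
  relations <- target_relations(
    source = c("E_ACE", "P_R1", "P_R2", "E_X", "E_Y"),
    source_class = c("enzyme", "protein", "protein", "enzyme", "enzyme"),
    sink = c("P2", "E1", "P2", "E1", "P2"),
    sink_class = c("protein", "enzyme", "protein", "enzyme", "protein"),
    effect = c("INH", "INH", "INH", "INH", "AGO")
  )
  ht <- ht_targets(c("P_AT1R", "P2", "E1"), c("ANT", "INH", "INH"))
  expected <- sort(c("CAND", "D_E", "D_P1", "D_P2", "D_EX", "D_MULTI",
                     "D_E1"))
  list(dt = dt, relations = relations, ht = ht, expected = expected)
}

# Tiny deterministic instance: one candidate covering the single main
# target with zero side effects.
single_candidate_instance <- function() {
  candidate_dataset("GIVEN", ht_targets("T1", "INH"), "D1",
                    list("T1"), 0)
}

# Random component vector for similarity property tests.
random_component_vector <- function() {
  pool <- c("C", "H", "N", "O", "S", "Cl", "Br", "F", "P")
  k <- sample(2:6, 1)
  stats::setNames(sample(1:40, k, replace = TRUE), sample(pool, k))
}

write_fixture_tsvs <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(c("drug\ttarget\ttarget_class\teffect",
               "d1\tt1\tprotein\tINH",
               "d1\tt2\tprotein\tAGO",
               "d2\tt1\tprotein\tINH"),
             file.path(dir, "drug_target.tsv"))
  writeLines(c("drug\tdisease", "d1\tht", "d2\tht"),
             file.path(dir, "drug_disease.tsv"))
  writeLines(c("drug_a\tdrug_b", "d1\td2"), file.path(dir, "ddar.tsv"))
  writeLines(c("source\tsource_class\tsink\tsink_class\teffect",
               "e1\tenzyme\tt1\tprotein\tINH"),
             file.path(dir, "target_relations.tsv"))
  dir
}
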