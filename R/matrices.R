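# Relational stores for the drug-disease, drug-target and drug-drug
# adverse-reaction matrices. All three are sparse and kept as validated
# edge lists (one relation per row) rather than dense matrices; identifiers
# are opaque case-sensitive strings.

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df[required]
}

new_edge_list <- function(df, class) {
  rownames(df) <- NULL
  structure(df, class = c(class, "data.frame"))
}

#' Drug-target interaction matrix (edge list)
#'
#' One row per (drug, target) interaction carrying the target class
#' (enzyme or protein) and the effect label. At most one effect per
#' (drug, target) pair; a pair absent from the list is the zero cell.
#'
#' @param drug,target,target_class,effect character vectors of equal length.
#' @return A `drug_targets` data frame with columns
#'   `drug`, `target`, `target_class`, `effect`.
#' @export
drug_targets <- function(drug, target, target_class, effect) {
  df <- data.frame(drug = as.character(drug), target = as.character(target),
                   target_class = as.character(target_class),
                   effect = as.character(effect), stringsAsFactors = FALSE)
  assert_effects(df$effect)
  assert_classes(df$target_class)
  key <- paste(df$drug, df$target, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop(sprintf("duplicate (drug, target) pair: %s",
                 gsub("\r", " / ", dup)), call. = FALSE)
  }
  new_edge_list(df, "drug_targets")
}

#' Drug-disease indication matrix (edge list)
#'
#' Binary indication matrix: a row means the drug is used for treating the
#' disease.
#'
#' @param drug,disease character vectors of equal length.
#' @return A `drug_diseases` data frame with columns `drug`, `disease`.
#' @export
drug_diseases <- function(drug, disease) {
  df <- unique(data.frame(drug = as.character(drug),
                          disease = as.character(disease),
                          stringsAsFactors = FALSE))
  new_edge_list(df, "drug_diseases")
}

#' Drug-drug adverse-reaction pairs
#'
#' Symmetric binary matrix over drugs, stored as normalized unordered pairs
#' (`drug_a < drug_b` lexicographically, no self pairs, no duplicates).
#'
#' @param drug_a,drug_b character vectors of equal length.
#' @return An `adverse_pairs` data frame with columns `drug_a`, `drug_b`.
#' @export
adverse_pairs <- function(drug_a = character(), drug_b = character()) {
  a <- as.character(drug_a); b <- as.character(drug_b)
  if (any(a == b)) {
    stop("adverse-reaction pair with identical drugs (diagonal must be zero)",
         call. = FALSE)
  }
  lo <- pmin(a, b); hi <- pmax(a, b)
  df <- unique(data.frame(drug_a = lo, drug_b = hi, stringsAsFactors = FALSE))
  df <- df[order(df$drug_a, df$drug_b), , drop = FALSE]
  new_edge_list(df, "adverse_pairs")
}

#' Target-target relations
#'
#' Directed relations between enzymes and proteins with an effect label,
#' used by rules 2-5 of the miner (enzyme->protein, protein->enzyme,
#' protein->protein, enzyme->enzyme).
#'
#' @param source,source_class,sink,sink_class,effect character vectors.
#' @return A `target_relations` data frame.
#' @export
target_relations <- function(source = character(), source_class = character(),
                             sink = character(), sink_class = character(),
                             effect = character()) {
  df <- data.frame(source = as.character(source),
                   source_class = as.character(source_class),
                   sink = as.character(sink),
                   sink_class = as.character(sink_class),
                   effect = as.character(effect), stringsAsFactors = FALSE)
  assert_effects(df$effect)
  assert_classes(df$source_class, what = "source_class")
  assert_classes(df$sink_class, what = "sink_class")
  if (any(df$source == df$sink)) {
    stop("target relation with source == sink", call. = FALSE)
  }
  new_edge_list(df, "target_relations")
}

#' Disease target set with required effects
#'
#' The (target, required effect) pairs whose modulation controls the
#' disease. Pairs are unique; the same target may appear with two distinct
#' effects when the evidence conflicts (both are retained and flagged at
#' derivation time).
#'
#' @param target,effect character vectors of equal length, at least one entry.
#' @return An `ht_targets` data frame with columns `target`, `effect`.
#' @export
ht_targets <- function(target, effect) {
  df <- data.frame(target = as.character(target),
                   effect = as.character(effect), stringsAsFactors = FALSE)
  if (nrow(df) < 1L) {
    stop("disease target set must contain at least one entry", call. = FALSE)
  }
  assert_effects(df$effect)
  df <- unique(df)
  df <- df[order(df$target, df$effect), , drop = FALSE]
  new_edge_list(df, "ht_targets")
}

# --- file IO -----------------------------------------------------------------

#' Read the TSV matrix files
#'
#' Loads the tab-separated exports of the relational matrices. Each file is
#' one relation per row with a header naming the columns:
#' `drug_target.tsv` (drug, target, target_class, effect),
#' `drug_disease.tsv` (drug, disease), `ddar.tsv` (drug_a, drug_b),
#' `target_relations.tsv` (source, source_class, sink, sink_class, effect)
#' and optionally `formulas.tsv` (drug, formula).
#'
#' @param dir directory containing the TSV files.
#' @return A list with elements `drug_targets`, `drug_diseases`, `ddar`,
#'   `relations` and (if present) `formulas` (named character vector).
#' @export
load_matrices <- function(dir) {
  dt <- read_tsv_checked(file.path(dir, "drug_target.tsv"),
                         c("drug", "target", "target_class", "effect"))
  ddi <- read_tsv_checked(file.path(dir, "drug_disease.tsv"),
                          c("drug", "disease"))
  ar <- read_tsv_checked(file.path(dir, "ddar.tsv"), c("drug_a", "drug_b"))
  rel <- read_tsv_checked(file.path(dir, "target_relations.tsv"),
                          c("source", "source_class", "sink", "sink_class",
                            "effect"))
  out <- list(
    drug_targets = drug_targets(dt$drug, dt$target, dt$target_class,
                                dt$effect),
    drug_diseases = drug_diseases(ddi$drug, ddi$disease),
    ddar = adverse_pairs(ar$drug_a, ar$drug_b),
    relations = target_relations(rel$source, rel$source_class, rel$sink,
                                 rel$sink_class, rel$effect)
  )
  fpath <- file.path(dir, "formulas.tsv")
  if (file.exists(fpath)) {
    f <- read_tsv_checked(fpath, c("drug", "formula"))
    out$formulas <- stats::setNames(f$formula, f$drug)
  }
  out
}

#' Write the TSV matrix files
#'
#' Inverse of [load_matrices()]; writing then re-loading reproduces
#' identical edge lists.
#'
#' @param matrices list as returned by [load_matrices()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_matrices <- function(matrices, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, file) {
    utils::write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  w(matrices$drug_targets, "drug_target.tsv")
  w(matrices$drug_diseases, "drug_disease.tsv")
  w(matrices$ddar, "ddar.tsv")
  w(matrices$relations, "target_relations.tsv")
  if (!is.null(matrices$formulas)) {
    w(data.frame(drug = names(matrices$formulas),
                 formula = unname(matrices$formulas),
                 stringsAsFactors = FALSE), "formulas.tsv")
  }
  invisible(dir)
}
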