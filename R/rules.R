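# If-Then association rules admitting drugs into the candidate pool.
#
# Rule 1 admits a drug that hits a disease target with exactly the required
# effect. Rules 2-5 admit a drug that hits an enzyme/protein whose one-hop
# relation to a disease enzyme/protein carries the required effect:
#   rule 2: enzyme  -> protein,   rule 3: protein -> enzyme,
#   rule 4: protein -> protein,   rule 5: enzyme  -> enzyme.
# Effect equality is strict label equality (no INH~ANT aliasing): a drug
# agonizing a receptor is not admitted when the disease requires an
# antagonist on it, even though both act on the same target.

#' Derive the disease target set from the indication and interaction matrices
#'
#' Collects, for every drug indicated for `disease`, the (target, effect)
#' pairs it touches; the union (unique pairs, sorted by target then effect)
#' is the disease target set. When two indicated drugs touch the same
#' target with conflicting effects both pairs are retained and flagged via
#' a message and the `conflicts` attribute.
#'
#' @param ddi a [drug_diseases()] indication matrix.
#' @param dt a [drug_targets()] interaction matrix.
#' @param disease disease identifier present in `ddi`.
#' @return An [ht_targets()] set, with attribute `conflicts` (character
#'   vector of targets carrying more than one required effect).
#' @export
derive_ht_targets <- function(ddi, dt, disease) {
  if (!(disease %in% ddi$disease)) {
    stop_classed("syntrader_lookup_error",
                 "disease '%s' absent from the indication matrix", disease)
  }
  indicated <- unique(ddi$drug[ddi$disease == disease])
  rows <- dt[dt$drug %in% indicated, , drop = FALSE]
  if (!nrow(rows)) {
    stop_classed("syntrader_empty_ht",
                 "no drug indicated for '%s' has recorded targets", disease)
  }
  ht <- ht_targets(rows$target, rows$effect)
  conflicts <- unique(ht$target[duplicated(ht$target)])
  if (length(conflicts)) {
    message(sprintf(
      "derive_ht_targets: %d target(s) carry conflicting required effects (retained): %s",
      length(conflicts), paste(conflicts, collapse = ", ")))
  }
  attr(ht, "conflicts") <- conflicts
  ht
}

#' Apply the five If-Then rules
#'
#' Admits every drug for which at least one rule fires, and returns one
#' trace per firing: the rule id, the matched disease target and the
#' entity/effect path that justified the admission. Relation chaining is
#' exactly one hop; removing a relation can only shrink the admitted set.
#'
#' @param dt a [drug_targets()] matrix over all drugs.
#' @param relations a [target_relations()] frame (may be empty).
#' @param ht an [ht_targets()] set (nonempty).
#' @return list with `drugs` (sorted unique admitted identifiers) and
#'   `traces` (data frame: drug, rule_id, matched_target, path).
#' @export
apply_rules <- function(dt, relations, ht) {
  stopifnot(inherits(ht, "ht_targets"), nrow(ht) >= 1L)
  key_ht <- paste(ht$target, ht$effect, sep = "\r")

  # rule 1: D -> T with F(D,T) = F(HT,T)
  hit1 <- dt[paste(dt$target, dt$effect, sep = "\r") %in% key_ht, ,
             drop = FALSE]
  traces <- data.frame(
    drug = hit1$drug, rule_id = rep(1L, nrow(hit1)),
    matched_target = hit1$target,
    path = sprintf("%s -[%s]-> %s", hit1$drug, hit1$effect, hit1$target),
    stringsAsFactors = FALSE
  )

  # rules 2-5: source -> sink with F(source,sink) = F(HT,sink);
  # any drug interacting with the source is admitted.
  if (!is.null(relations) && nrow(relations)) {
    fire <- relations[paste(relations$sink, relations$effect, sep = "\r")
                      %in% key_ht, , drop = FALSE]
    if (nrow(fire)) {
      rule_of <- function(src, snk) {
        ifelse(src == "enzyme" & snk == "protein", 2L,
        ifelse(src == "protein" & snk == "enzyme", 3L,
        ifelse(src == "protein" & snk == "protein", 4L, 5L)))
      }
      fire$rule_id <- rule_of(fire$source_class, fire$sink_class)
      touch <- merge(dt, fire, by.x = "target", by.y = "source")
      if (nrow(touch)) {
        traces <- rbind(traces, data.frame(
          drug = touch$drug, rule_id = touch$rule_id,
          matched_target = touch$sink,
          path = sprintf("%s -[%s]-> %s -[%s]-> %s", touch$drug,
                         touch$effect.x, touch$target, touch$effect.y,
                         touch$sink),
          stringsAsFactors = FALSE
        ))
      }
    }
  }

  traces <- unique(traces)
  traces <- traces[order(traces$drug, traces$rule_id, traces$matched_target,
                         traces$path), , drop = FALSE]
  rownames(traces) <- NULL
  list(drugs = sort(unique(traces$drug)), traces = traces)
}
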