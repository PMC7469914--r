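#' Drug-target effect labels
#'
#' The four ways a drug or biomolecule can act on a target: inhibit,
#' induce, agonize, antagonize. An absent interaction is encoded as the
#' absence of a row in the edge-list representation (the zero cell of the
#' drug-target matrix), never as a fifth label.
#'
#' @format Character vector of the four effect tokens.
#' @export
EFFECT_LEVELS <- c("INH", "IND", "AGO", "ANT")

#' Target classes recognized in target-target relations
#' @format Character vector.
#' @export
TARGET_CLASSES <- c("enzyme", "protein")

# Validate a vector of effect tokens; `rows` gives 1-based data-row numbers
# used in error messages (header is line 1, so file line = row + 1).
assert_effects <- function(effect, rows = seq_along(effect), what = "effect") {
  bad <- which(!(effect %in% EFFECT_LEVELS))
  if (length(bad)) {
    stop(sprintf(
      "unknown %s label '%s' (line %d); expected one of %s",
      what, effect[bad[1]], rows[bad[1]] + 1L,
      paste(EFFECT_LEVELS, collapse = "/")
    ), call. = FALSE)
  }
  invisible(effect)
}

assert_classes <- function(cls, rows = seq_along(cls), what = "target_class") {
  bad <- which(!(cls %in% TARGET_CLASSES))
  if (length(bad)) {
    stop(sprintf(
      "unknown %s '%s' (line %d); expected one of %s",
      what, cls[bad[1]], rows[bad[1]] + 1L,
      paste(TARGET_CLASSES, collapse = "/")
    ), call. = FALSE)
  }
  invisible(cls)
}

stop_classed <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
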