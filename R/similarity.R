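# Chemical-formula parsing (Hill notation, underscore-tolerant) and the
# weighted component similarity between two drugs. Per shared component r
# the weight is
#
#   w_r = min(d_r, 1) * min(C_a,r, C_b,r) / (max(C_a,r, C_b,r) + eps)
#
# with d_r the corpus frequency of the component. Two reporting modes ship:
# "literal", sum(w_r C_a,r C_b,r) / sum(w_r sqrt(C_a,r C_b,r)), which is
# unbounded; and "normalized" (default), the weighted cosine
# sum(w_r C_a,r C_b,r) / (sqrt(sum(w_r C_a,r^2)) sqrt(sum(w_r C_b,r^2))),
# bounded in [0, 1].

ELEMENT_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf",
  "Es", "Fm", "Md", "No", "Lr", "Rf", "Db", "Sg", "Bh", "Hs", "Mt", "Ds",
  "Rg", "Cn", "Nh", "Fl", "Mc", "Lv", "Ts", "Og")

#' Parse a chemical formula into component counts
#'
#' Hill-notation parser tolerating underscores and whitespace as subscript
#' markers (e.g. `"C_24_H_34_N_2_O_5_"` parses like `"C24H34N2O5"`).
#' Implicit counts are 1; repeated element tokens accumulate. A hydrogen
#' count of exactly 1 in a carbon-rich formula (>= 10 carbons) triggers a
#' plausibility warning, since such strings are usually truncated exports.
#'
#' @param text nonempty formula string.
#' @return named integer vector of element counts (a component vector).
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  clean <- gsub("[_[:space:]]", "", text)
  if (!nzchar(clean)) stop("empty formula", call. = FALSE)
  m <- gregexpr("[A-Z][a-z]?[0-9]*", clean)[[1]]
  toks <- regmatches(clean, gregexpr("[A-Z][a-z]?[0-9]*", clean))[[1]]
  covered <- paste(toks, collapse = "")
  if (!identical(covered, clean)) {
    # first position not covered by a valid token
    pos <- 1L
    for (i in seq_along(toks)) {
      if (m[i] != pos) break
      pos <- pos + attr(m, "match.length")[i]
    }
    stop(sprintf("cannot parse formula '%s' at position %d", text, pos),
         call. = FALSE)
  }
  sym <- sub("[0-9]*$", "", toks)
  cnt <- sub("^[A-Z][a-z]?", "", toks)
  cnt <- ifelse(cnt == "", 1L, as.integer(cnt))
  bad <- which(!(sym %in% ELEMENT_SYMBOLS))
  if (length(bad)) {
    stop(sprintf("unknown element token '%s' in formula '%s' at position %d",
                 sym[bad[1]], text, m[bad[1]]), call. = FALSE)
  }
  out <- tapply(cnt, sym, sum)
  out <- stats::setNames(as.integer(out), names(out))
  out <- out[order(names(out))]
  if (!is.na(out["H"]) && out["H"] == 1L &&
      !is.na(out["C"]) && out["C"] >= 10L) {
    warning(sprintf(
      "formula '%s': hydrogen count 1 with %d carbons looks implausible (truncated formula?)",
      text, out["C"]), call. = FALSE)
  }
  out
}

#' Component weights from a formula corpus
#'
#' The data frequency `d_r` of component r is the fraction of corpus drugs
#' whose formula contains r; with no corpus every `d_r` is 1. Frequencies
#' above 1 are clamped at use time.
#'
#' @param corpus optional list of component vectors (or character formulas)
#'   defining the frequencies.
#' @param eps small positive ridge in the weight denominator.
#' @return A `component_weights` list with `d` (named frequencies) and `eps`.
#' @export
component_weights <- function(corpus = NULL, eps = 1e-12) {
  d <- numeric(0)
  if (!is.null(corpus) && length(corpus)) {
    vecs <- lapply(corpus, function(x) {
      if (is.character(x)) parse_formula(x) else x
    })
    all_sym <- sort(unique(unlist(lapply(vecs, names))))
    d <- vapply(all_sym, function(s) {
      mean(vapply(vecs, function(v) s %in% names(v), logical(1)))
    }, numeric(1))
  }
  structure(list(d = d, eps = eps), class = "component_weights")
}

#' Weighted similarity between two component vectors
#'
#' @param a,b named nonnegative integer vectors (from [parse_formula()]).
#' @param weights a [component_weights()] object (default: all `d_r = 1`).
#' @param mode `"normalized"` (weighted cosine, in \[0, 1\]) or `"literal"`
#'   (unbounded ratio form).
#' @return scalar similarity; 0 when the component supports are disjoint.
#' @export
formula_similarity <- function(a, b, weights = component_weights(),
                               mode = c("normalized", "literal")) {
  mode <- match.arg(mode)
  if (!length(a) || !length(b)) {
    stop("component vectors must be nonempty", call. = FALSE)
  }
  comps <- sort(union(names(a), names(b)))
  ca <- ifelse(comps %in% names(a), a[comps], 0)
  cb <- ifelse(comps %in% names(b), b[comps], 0)
  ca[is.na(ca)] <- 0; cb[is.na(cb)] <- 0
  d <- rep(1, length(comps))
  if (length(weights$d)) {
    known <- comps %in% names(weights$d)
    d[known] <- weights$d[comps[known]]
  }
  eps <- weights$eps
  w <- pmin(d, 1) * pmin(ca, cb) / (pmax(ca, cb) + eps)
  # (ca * cb) first keeps the expression bit-symmetric in its arguments
  num <- sum(w * (ca * cb))
  if (mode == "literal") {
    den <- sum(w * sqrt(ca * cb))
    if (den == 0) return(0)
    return(num / den)
  }
  den <- sqrt(sum(w * ca^2)) * sqrt(sum(w * cb^2))
  if (den == 0) return(0)
  num / den
}

#' Pairwise similarity table
#'
#' @param formulas named character vector of formulas (names are drug ids).
#' @param pairs two-column data frame / matrix of drug id pairs.
#' @param weights,mode forwarded to [formula_similarity()]; by default the
#'   weights' frequencies are estimated from `formulas` as the corpus.
#' @return data frame: drug_a, drug_b, similarity.
#' @export
similarity_table <- function(formulas, pairs,
                             weights = component_weights(as.list(formulas)),
                             mode = "normalized") {
  vecs <- lapply(formulas, parse_formula)
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  miss <- setdiff(unique(c(pairs[[1]], pairs[[2]])), names(vecs))
  if (length(miss)) {
    stop(sprintf("no formula for drug '%s'", miss[1]), call. = FALSE)
  }
  sim <- mapply(function(x, y) {
    formula_similarity(vecs[[x]], vecs[[y]], weights, mode)
  }, pairs[[1]], pairs[[2]])
  data.frame(drug_a = pairs[[1]], drug_b = pairs[[2]], similarity = sim,
             stringsAsFactors = FALSE)
}
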