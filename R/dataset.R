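# One optimization instance: a given drug to substitute, its disease-relevant
# ("main") targets, and the candidate drugs that cover at least one of them,
# each with a side-effect count (its drug-target interactions that are NOT
# main-target hits), plus the adverse-reaction pairs among the candidates.

#' Construct a candidate dataset
#'
#' @param given_drug identifier of the drug to substitute.
#' @param main_targets an [ht_targets()] frame restricted to the given drug:
#'   the targets (with required effects) the combination must cover.
#' @param drugs character vector of candidate drug identifiers (excluding
#'   `given_drug`, no duplicates).
#' @param coverage list (one element per candidate) of character vectors:
#'   the main targets the candidate covers with the required effect. Every
#'   candidate must cover at least one main target.
#' @param se nonnegative side-effect counts, one per candidate: the number
#'   of the candidate's drug-target interactions that are not covered main
#'   targets.
#' @param adverse an [adverse_pairs()] frame restricted to the candidates.
#' @return A `candidate_dataset` object.
#' @export
candidate_dataset <- function(given_drug, main_targets, drugs, coverage, se,
                              adverse = adverse_pairs()) {
  stopifnot(is.character(drugs), length(drugs) >= 1L,
            length(coverage) == length(drugs), length(se) == length(drugs))
  if (anyDuplicated(drugs)) stop("duplicate candidate drugs", call. = FALSE)
  if (given_drug %in% drugs) {
    stop("given drug cannot be its own candidate", call. = FALSE)
  }
  if (!inherits(main_targets, "ht_targets")) {
    stop("main_targets must be an ht_targets object", call. = FALSE)
  }
  se <- as.numeric(se)
  if (any(se < 0)) stop("side-effect counts must be nonnegative", call. = FALSE)
  coverage <- lapply(coverage, function(x) sort(unique(as.character(x))))
  ok <- vapply(coverage, function(x) {
    length(x) >= 1L && all(x %in% main_targets$target)
  }, logical(1))
  if (!all(ok)) {
    stop(sprintf(
      "candidate '%s' must cover a nonempty subset of the main targets",
      drugs[which(!ok)[1]]), call. = FALSE)
  }
  if (!inherits(adverse, "adverse_pairs")) {
    adverse <- adverse_pairs(adverse[[1]], adverse[[2]])
  }
  extra <- setdiff(unique(c(adverse$drug_a, adverse$drug_b)), drugs)
  if (length(extra)) {
    stop(sprintf("adverse pair mentions non-candidate drug '%s'", extra[1]),
         call. = FALSE)
  }
  structure(list(
    given_drug = as.character(given_drug),
    main_targets = main_targets,
    drugs = drugs,
    coverage = stats::setNames(coverage, drugs),
    se = stats::setNames(se, drugs),
    adverse = adverse
  ), class = "candidate_dataset")
}

#' @export
print.candidate_dataset <- function(x, ...) {
  cat(sprintf(
    "candidate_dataset: given drug '%s', %d main target(s), %d candidate(s), %d adverse pair(s)\n",
    x$given_drug, nrow(x$main_targets), length(x$drugs), nrow(x$adverse)))
  invisible(x)
}

#' Number of candidate drugs in an instance
#' @param dataset a `candidate_dataset`.
#' @return integer count.
#' @export
n_candidates <- function(dataset) length(dataset$drugs)

#' Adverse-reaction matrix of an instance
#'
#' @param dataset a `candidate_dataset`.
#' @return symmetric logical matrix (zero diagonal) over the candidates.
#' @export
adverse_matrix <- function(dataset) {
  m <- length(dataset$drugs)
  A <- matrix(FALSE, m, m, dimnames = list(dataset$drugs, dataset$drugs))
  if (nrow(dataset$adverse)) {
    i <- match(dataset$adverse$drug_a, dataset$drugs)
    j <- match(dataset$adverse$drug_b, dataset$drugs)
    A[cbind(i, j)] <- TRUE
    A[cbind(j, i)] <- TRUE
  }
  A
}

# 0-based index pairs for the C++ engines
adverse_index_pairs <- function(dataset) {
  if (!nrow(dataset$adverse)) {
    return(matrix(integer(), ncol = 2))
  }
  cbind(match(dataset$adverse$drug_a, dataset$drugs) - 1L,
        match(dataset$adverse$drug_b, dataset$drugs) - 1L)
}

# Coverage bitmasks over the main targets (bit t set when the candidate
# covers main target t). Engines require <= 30 main targets.
coverage_masks <- function(dataset) {
  tg <- unique(dataset$main_targets$target)
  if (length(tg) > 30L) {
    stop("engines support at most 30 distinct main targets", call. = FALSE)
  }
  vapply(dataset$coverage, function(x) {
    sum(bitwShiftL(1L, match(unique(x), tg) - 1L))
  }, integer(1))
}

n_main_targets <- function(dataset) length(unique(dataset$main_targets$target))

#' Build an optimization instance from the raw matrices
#'
#' Restricts the mined drug set to candidates for substituting `given_drug`:
#' the given drug's main targets are the disease targets it hits with
#' exactly the required effect; a mined drug becomes a candidate when it
#' hits at least one of those main targets with the required effect
#' (partial matches contribute only their matching targets). The
#' side-effect count of candidate i is its total number of drug-target
#' interactions minus its covered main targets.
#'
#' @param given_drug drug identifier present in `dt`.
#' @param ht an [ht_targets()] set for the disease.
#' @param dt a [drug_targets()] matrix.
#' @param ddar an [adverse_pairs()] matrix.
#' @param mined character vector of drug identifiers admitted by the miner.
#' @return A [candidate_dataset()].
#' @export
build_candidate_dataset <- function(given_drug, ht, dt, ddar, mined) {
  if (!(given_drug %in% dt$drug)) {
    stop_classed("syntrader_lookup_error",
                 "given drug '%s' absent from the drug-target matrix",
                 given_drug)
  }
  key_dt <- paste(dt$target, dt$effect, sep = "\r")
  key_ht <- paste(ht$target, ht$effect, sep = "\r")
  own <- dt[dt$drug == given_drug & key_dt %in% key_ht, , drop = FALSE]
  if (!nrow(own)) {
    stop_classed("syntrader_empty_instance",
                 "given drug '%s' hits none of the disease targets with the required effect",
                 given_drug)
  }
  main <- ht_targets(own$target, own$effect)
  main_key <- paste(main$target, main$effect, sep = "\r")

  cand <- setdiff(unique(mined), given_drug)
  cov <- list(); se <- numeric(); keep <- character()
  for (d in cand) {
    rows <- dt[dt$drug == d, , drop = FALSE]
    hit <- rows$target[paste(rows$target, rows$effect, sep = "\r") %in% main_key]
    if (length(hit)) {
      keep <- c(keep, d)
      cov[[d]] <- sort(unique(hit))
      se[d] <- nrow(rows) - length(unique(hit))
    }
  }
  if (!length(keep)) {
    stop_classed("syntrader_empty_instance",
                 "no mined drug covers a main target of '%s'", given_drug)
  }
  ar <- ddar[ddar$drug_a %in% keep & ddar$drug_b %in% keep, , drop = FALSE]
  candidate_dataset(given_drug, main, keep, cov[keep], se[keep],
                    adverse_pairs(ar$drug_a, ar$drug_b))
}
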