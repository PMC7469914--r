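# Synthetic instance generation. Real candidate pools (drug-target
# interactions, per-drug side-effect counts, adverse-reaction pairs) come
# from curated databases that are not redistributable; the generator
# emulates their structure so every other module is testable: each
# candidate covers a nonempty random subset of the main targets (subset
# size follows a truncated geometric law favoring single-target coverage),
# side-effect counts are Poisson, and adverse pairs are Bernoulli on the
# unordered candidate pairs. Presets reproduce the (targets, main targets,
# candidates) shapes of the nine hypertension benchmark drugs; per-candidate
# side-effect values are synthetic because no published per-drug counts
# exist.

#' Generator specification
#'
#' @param n_candidates number of candidate drugs (>= 1).
#' @param n_main_targets number of main targets (>= 1, <= 30).
#' @param se_rate mean side-effect count per candidate (Poisson).
#' @param coverage_p success probability of the truncated geometric law for
#'   covered-subset sizes (larger favors single-target coverage).
#' @param ddar_density probability an unordered candidate pair is adverse.
#' @param seed integer seed; same spec + seed give identical instances.
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(n_candidates, n_main_targets = 1L, se_rate = 2,
                           coverage_p = 0.6, ddar_density = 0.05, seed = 1L) {
  stopifnot(n_candidates >= 1L, n_main_targets >= 1L, n_main_targets <= 30L,
            se_rate >= 0, ddar_density >= 0, ddar_density <= 1)
  structure(list(n_candidates = as.integer(n_candidates),
                 n_main_targets = as.integer(n_main_targets),
                 se_rate = se_rate, coverage_p = coverage_p,
                 ddar_density = ddar_density, seed = as.integer(seed)),
            class = "generator_spec")
}

#' Benchmark instance shape presets
#'
#' The (total targets, main targets, candidates) shapes of the nine
#' hypertension benchmark drugs: Trandolapril, Atenolol, Carteolol,
#' Nicardipine, Felodipine, Nifedipine, Nisoldipine, Doxazosin, Prazosin.
#'
#' @format Named list with elements `tnt`, `tnmt`, `tnc` per preset.
#' @export
TABLE1_PRESETS <- list(
  TRA = list(tnt = 1L,  tnmt = 1L, tnc = 16L),
  ATE = list(tnt = 2L,  tnmt = 1L, tnc = 26L),
  CAR = list(tnt = 2L,  tnmt = 2L, tnc = 28L),
  NIC = list(tnt = 15L, tnmt = 4L, tnc = 40L),
  FEL = list(tnt = 13L, tnmt = 5L, tnc = 50L),
  NIF = list(tnt = 8L,  tnmt = 5L, tnc = 50L),
  NIS = list(tnt = 5L,  tnmt = 5L, tnc = 50L),
  DOX = list(tnt = 6L,  tnmt = 3L, tnc = 112L),
  PRA = list(tnt = 6L,  tnmt = 3L, tnc = 112L)
)

#' Generator spec for a named preset
#'
#' @param preset one of `names(TABLE1_PRESETS)`.
#' @param seed integer seed.
#' @param ... overrides forwarded to [generator_spec()].
#' @return A `generator_spec` shaped like the preset.
#' @export
preset_spec <- function(preset, seed = 1L, ...) {
  p <- TABLE1_PRESETS[[match.arg(preset, names(TABLE1_PRESETS))]]
  args <- list(n_candidates = p$tnc, n_main_targets = p$tnmt, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(generator_spec, args)
}

rtrunc_geom <- function(n, p, max_size) {
  pmin(1L + stats::rgeom(n, p), max_size)
}

#' Generate a synthetic candidate dataset
#'
#' @param spec a [generator_spec()].
#' @return A [candidate_dataset()] (deterministic per seed).
#' @export
generate_instance <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  m <- spec$n_candidates
  nt <- spec$n_main_targets
  targets <- sprintf("T%02d", seq_len(nt))
  effects <- sample(EFFECT_LEVELS, nt, replace = TRUE)
  drugs <- sprintf("D%03d", seq_len(m))

  sizes <- rtrunc_geom(m, spec$coverage_p, nt)
  coverage <- lapply(sizes, function(k) sort(sample(targets, k)))
  se <- stats::rpois(m, spec$se_rate)

  if (m >= 2L && spec$ddar_density > 0) {
    idx <- utils::combn(m, 2L)
    hit <- stats::runif(ncol(idx)) < spec$ddar_density
    adverse <- adverse_pairs(drugs[idx[1L, hit]], drugs[idx[2L, hit]])
  } else {
    adverse <- adverse_pairs()
  }
  candidate_dataset("GIVEN", ht_targets(targets, effects), drugs, coverage,
                    se, adverse)
}

#' Generate an instance with a planted, provably optimal subset
#'
#' Constructs an instance in which a designated k-subset covers all main
#' targets with zero side effects while every other candidate carries at
#' least one side effect; the planted subset is therefore the unique
#' selection attaining the maximal score, which is re-verified by
#' [exhaustive_oracle()] before returning. Planted drugs are never mutually
#' adverse, keeping the optimum feasible under hard mode.
#'
#' @param spec a [generator_spec()] with `n_candidates <= 20` and
#'   `n_main_targets >= k`.
#' @param k planted subset size.
#' @param max_retries verification retries with derived seeds.
#' @return list: `dataset` (a [candidate_dataset()]), `oracle` (the
#'   verifying `oracle_result`), `planted` (binary vector).
#' @export
plant_optimum <- function(spec, k, max_retries = 100L) {
  stopifnot(inherits(spec, "generator_spec"), k >= 1L,
            k <= spec$n_candidates, spec$n_candidates <= 20L,
            k <= spec$n_main_targets)
  for (r in seq_len(max_retries)) {
    seed_r <- (spec$seed + 7919L * (r - 1L)) %% .Machine$integer.max
    set.seed(seed_r)
    m <- spec$n_candidates
    nt <- spec$n_main_targets
    targets <- sprintf("T%02d", seq_len(nt))
    effects <- sample(EFFECT_LEVELS, nt, replace = TRUE)
    drugs <- sprintf("D%03d", seq_len(m))
    planted_idx <- sort(sample.int(m, k))

    # partition the main targets across the planted drugs
    part <- split(sample(targets), rep_len(seq_len(k), nt))
    coverage <- vector("list", m)
    se <- numeric(m)
    pi_ <- 0L
    for (i in seq_len(m)) {
      if (i %in% planted_idx) {
        pi_ <- pi_ + 1L
        coverage[[i]] <- sort(part[[pi_]])
        se[i] <- 0
      } else {
        sz <- rtrunc_geom(1L, spec$coverage_p, nt)
        coverage[[i]] <- sort(sample(targets, sz))
        se[i] <- 1 + stats::rpois(1L, spec$se_rate)
      }
    }
    adverse <- adverse_pairs()
    if (m >= 2L && spec$ddar_density > 0) {
      idx <- utils::combn(m, 2L)
      both_planted <- idx[1L, ] %in% planted_idx & idx[2L, ] %in% planted_idx
      hit <- stats::runif(ncol(idx)) < spec$ddar_density & !both_planted
      adverse <- adverse_pairs(drugs[idx[1L, hit]], drugs[idx[2L, hit]])
    }
    dataset <- candidate_dataset("GIVEN", ht_targets(targets, effects),
                                 drugs, coverage, se, adverse)
    planted <- integer(m)
    planted[planted_idx] <- 1L
    validate_planted(dataset, planted)
    orc <- exhaustive_oracle(dataset)
    if (identical(as.integer(orc$optimal_selection), planted)) {
      return(list(dataset = dataset, oracle = orc, planted = planted))
    }
  }
  stop(sprintf("plant_optimum: verification failed after %d retries",
               max_retries), call. = FALSE)
}

#' Check that a planted selection is feasible under hard mode
#'
#' @param dataset a [candidate_dataset()].
#' @param selection binary vector.
#' @return `TRUE` invisibly; errors when the selection contains an adverse
#'   pair.
#' @export
validate_planted <- function(dataset, selection) {
  if (count_adverse_violations(selection, dataset) > 0L) {
    stop_classed("syntrader_infeasible_plant",
                 "planted selection contains an adverse pair")
  }
  invisible(TRUE)
}

# --- serialization ----------------------------------------------------------

#' Write / read a candidate dataset as JSON
#'
#' @param dataset a [candidate_dataset()].
#' @param path file path.
#' @return `path` (write) or the dataset (read).
#' @export
write_instance_json <- function(dataset, path) {
  x <- list(given_drug = dataset$given_drug,
            main_targets = as.data.frame(unclass(dataset$main_targets),
                                         stringsAsFactors = FALSE),
            drugs = dataset$drugs,
            coverage = unname(lapply(dataset$coverage, identity)),
            se = unname(dataset$se),
            adverse = as.data.frame(unclass(dataset$adverse),
                                    stringsAsFactors = FALSE))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_instance_json
#' @export
read_instance_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  adverse <- if (length(x$adverse)) {
    adverse_pairs(x$adverse$drug_a, x$adverse$drug_b)
  } else adverse_pairs()
  cov <- if (is.list(x$coverage)) x$coverage else as.list(x$coverage)
  candidate_dataset(x$given_drug,
                    ht_targets(x$main_targets$target, x$main_targets$effect),
                    x$drugs, cov, x$se, adverse)
}

#' Express an instance in the TSV matrix dialect
#'
#' Rebuilds raw drug-target and adverse-reaction edge lists from which
#' [build_candidate_dataset()] reconstructs the instance: covered main
#' targets become effect-matched interactions and each side-effect count
#' becomes that many synthetic off-target interactions.
#'
#' @param dataset a [candidate_dataset()].
#' @return list with `drug_targets`, `ddar`, `ht` ready for
#'   [build_candidate_dataset()].
#' @export
instance_as_matrices <- function(dataset) {
  main <- dataset$main_targets
  eff_of <- stats::setNames(main$effect, main$target)
  rows <- data.frame(drug = dataset$given_drug, target = main$target,
                     target_class = "protein", effect = main$effect,
                     stringsAsFactors = FALSE)
  for (i in seq_along(dataset$drugs)) {
    d <- dataset$drugs[i]
    cov <- dataset$coverage[[i]]
    rows <- rbind(rows, data.frame(
      drug = d, target = cov, target_class = "protein",
      effect = unname(eff_of[cov]), stringsAsFactors = FALSE))
    nse <- as.integer(dataset$se[i])
    if (nse > 0) {
      rows <- rbind(rows, data.frame(
        drug = d, target = sprintf("OFF_%s_%02d", d, seq_len(nse)),
        target_class = "protein", effect = "INH", stringsAsFactors = FALSE))
    }
  }
  list(drug_targets = drug_targets(rows$drug, rows$target, rows$target_class,
                                   rows$effect),
       ddar = dataset$adverse,
       ht = ht_targets(main$target, main$effect))
}
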