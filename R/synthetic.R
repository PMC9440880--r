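#' Configuration for the synthetic cohort generator
#'
#' Collects and validates every knob of [generate_cohort()]. The generator
#' plants the statistical structure the analyses look for: repeated
#' subgroups across expeditions (so nontrivial simplices arise), a
#' configurable effect of influence on summit success, cooperative versus
#' polarized expedition regimes, a repeated-partner failure multiplier, and
#' six binarizable personal features.
#'
#' @param n_climbers Number of climbers in the pool.
#' @param n_expeditions Number of expeditions, generated sequentially in
#'   `time_index` order.
#' @param expedition_size_range Integer `c(min, max)` roster sizes, min >= 2.
#' @param group_persistence Probability `rho` in \[0, 1\] that a new
#'   expedition reuses a block of a uniformly chosen earlier expedition's
#'   roster, creating repeated simplices.
#' @param seed_block_size_range Integer `c(min, max)` size of the reused
#'   block.
#' @param base_success_logit Baseline log-odds `beta0` of summit success.
#' @param influence_effect Log-odds of success added per unit of influence
#'   (`beta_zeta`), where each member's influence is recomputed from the
#'   history generated so far, with the same definition the analysis side
#'   uses.
#' @param regime `"cooperative"`, `"polarized"`, or `"mixed"` (each
#'   expedition drawn uniformly between the two).
#' @param cooperative_spillover Log-odds `gamma` added, per unit of the
#'   expedition's maximal simplicial dimension, to members *outside* the
#'   largest simplex in cooperative expeditions (the benefit of a large
#'   weakly-tied subgroup spills over to the whole roster).
#' @param polarized_penalty Log-odds `delta` subtracted from members
#'   outside the largest simplex in polarized expeditions that contain a
#'   simplex of dimension >= 1.
#' @param death_prob Probability that a failed climb is fatal.
#' @param failure_cause_weights Length-4 probability vector over the
#'   failure categories (altitude, logistics, fatigue, accident); must sum
#'   to 1.
#' @param partner_failure_multiplier `kappa` in (0, 1\]: the failure
#'   probability of a record with at least one repeated partner is scaled
#'   by this factor.
#' @param feature_prevalences Length-6 probability vector governing the
#'   personal features: younger-age mixture component, male, hired/sherpa,
#'   probability that an expedition's peak is above 8000 m, oxygen use
#'   ascending, oxygen use descending.
#' @param feature_effects Length-6 log-odds vector of planted effects of
#'   the realized binary personal features (age below cohort median, male,
#'   hired, prior 8000 m experience, oxygen ascent, oxygen descent) on
#'   success; defaults to no effect.
#' @param expeditions_per_year How many `time_index` steps make one year of
#'   climber ageing; defaults to `ceiling(n_expeditions / 25)` so a cohort
#'   spans roughly 25 seasons.
#' @param rng_seed Integer seed; every expedition uses a counter-based
#'   substream derived from it.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_climbers = 100,
                             n_expeditions = 400,
                             expedition_size_range = c(4, 10),
                             group_persistence = 0.6,
                             seed_block_size_range = c(2, 5),
                             base_success_logit = -0.5,
                             influence_effect = 0.8,
                             regime = c("mixed", "cooperative", "polarized"),
                             cooperative_spillover = 0.4,
                             polarized_penalty = 1.5,
                             death_prob = 0.03,
                             failure_cause_weights = c(
                               altitude = 0.35, logistics = 0.25,
                               fatigue = 0.25, accident = 0.15
                             ),
                             partner_failure_multiplier = 1,
                             feature_prevalences = c(
                               age_young = 0.5, male = 0.75, hired = 0.25,
                               high_peak = 0.6, oxygen_ascent = 0.7,
                               oxygen_descent = 0.5
                             ),
                             feature_effects = numeric(6),
                             expeditions_per_year = NULL,
                             rng_seed = 1L) {
  regime <- match.arg(regime)
  cfg <- list(
    n_climbers = as.integer(n_climbers),
    n_expeditions = as.integer(n_expeditions),
    expedition_size_range = as.integer(expedition_size_range),
    group_persistence = group_persistence,
    seed_block_size_range = as.integer(seed_block_size_range),
    base_success_logit = base_success_logit,
    influence_effect = influence_effect,
    regime = regime,
    cooperative_spillover = cooperative_spillover,
    polarized_penalty = polarized_penalty,
    death_prob = death_prob,
    failure_cause_weights = failure_cause_weights,
    partner_failure_multiplier = partner_failure_multiplier,
    feature_prevalences = feature_prevalences,
    feature_effects = feature_effects,
    expeditions_per_year = expeditions_per_year %||%
      max(1L, ceiling(n_expeditions / 25)),
    rng_seed = as.integer(rng_seed)
  )
  probs <- c(
    cfg$group_persistence, cfg$death_prob,
    cfg$failure_cause_weights, cfg$feature_prevalences
  )
  if (any(probs < 0 | probs > 1)) abort("all probabilities must be in [0, 1]")
  if (abs(sum(cfg$failure_cause_weights) - 1) > 1e-8) {
    abort("failure_cause_weights must sum to 1")
  }
  if (length(cfg$failure_cause_weights) != 4) {
    abort("failure_cause_weights must have length 4")
  }
  if (length(cfg$feature_prevalences) != 6) {
    abort("feature_prevalences must have length 6")
  }
  if (length(cfg$feature_effects) != 6) {
    abort("feature_effects must have length 6")
  }
  if (cfg$expedition_size_range[1] < 2 ||
    cfg$expedition_size_range[2] < cfg$expedition_size_range[1]) {
    abort("expedition sizes must be >= 2 with min <= max")
  }
  if (cfg$partner_failure_multiplier <= 0 ||
    cfg$partner_failure_multiplier > 1) {
    abort("partner_failure_multiplier must be in (0, 1]")
  }
  if (cfg$n_climbers < cfg$expedition_size_range[2]) {
    abort("n_climbers must be at least the maximum expedition size")
  }
  structure(cfg, class = "generator_config")
}

# counter-based substream: a fixed hash of (seed, counter), kept < 2^31 so
# inserting or re-running one expedition never perturbs another's draws
substream_seed <- function(seed, counter) {
  as.integer(((abs(seed) %% 2147483647) * 69069 + counter * 1013904223) %% 2147483647)
}

with_substream <- function(seed, counter, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, counter))
  force(expr)
}

sample_int <- function(n, size, replace = FALSE, prob = NULL) {
  # sample() with a length-1 x would sample from 1:x; always treat as a set
  n[sample.int(length(n), size, replace = replace, prob = prob)]
}

#' Generate a synthetic climber/expedition cohort
#'
#' Builds expeditions sequentially in `time_index` order. With probability
#' `group_persistence` an expedition's roster contains a block copied from
#' a uniformly chosen earlier expedition (creating repeated simplices); the
#' remaining seats are drawn uniformly from the climber pool. Each member's
#' success probability is `plogis(beta0 + beta_zeta * zeta + regime term +
#' feature effects)`, with the member's influence `zeta` recomputed from
#' the history generated so far — the same definition the analysis side
#' uses. Failure records draw a cause from `failure_cause_weights`; a
#' record with at least one repeated partner has its failure probability
#' scaled by `partner_failure_multiplier`.
#'
#' @param config A [generator_config()].
#' @return A list of class `climber_cohort`: `records` and `expeditions`
#'   tibbles (the same schemas [read_cohort()] reads), a `truth` tibble of
#'   per-record latent quantities for parameter-recovery tests, and the
#'   `config`.
#' @seealso [planted_truth()]
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "generator_config")) {
    config <- do.call(generator_config, as.list(config))
  }
  cfg <- config
  n <- cfg$n_climbers

  # climber statics and the peak pool live in substream 0
  statics <- with_substream(cfg$rng_seed, 0L, {
    n_peaks <- max(5L, cfg$n_expeditions %/% 20L)
    high <- runif(n_peaks) < cfg$feature_prevalences[[4]]
    peaks <- tibble::tibble(
      peak_id = sprintf("P%03d", seq_len(n_peaks)),
      peak_height = round(ifelse(high, runif(n_peaks, 8000, 8849),
        runif(n_peaks, 6000, 7999)
      ))
    )
    young <- runif(n) < cfg$feature_prevalences[[1]]
    base_age <- ifelse(young, rnorm(n, 31, 5), rnorm(n, 45, 5))
    base_age <- pmin(pmax(round(base_age), 18), 75)
    hired <- runif(n) < cfg$feature_prevalences[[3]]
    nat_pool <- c("USA", "GBR", "JPN", "FRA", "IND", "ESP")
    list(
      peaks = peaks,
      climber = tibble::tibble(
        climber_id = sprintf("C%04d", seq_len(n)),
        base_age = as.integer(base_age),
        sex = ifelse(runif(n) < cfg$feature_prevalences[[2]], "male", "female"),
        is_hired = hired,
        nationality = ifelse(hired, "NPL",
          sample_int(nat_pool, n, replace = TRUE)
        ),
        oxygen_ascent = runif(n) < cfg$feature_prevalences[[5]],
        oxygen_descent = runif(n) < cfg$feature_prevalences[[6]]
      )
    )
  })
  cl <- statics$climber
  median_base_age <- median(cl$base_age)

  rosters <- vector("list", cfg$n_expeditions)
  logs <- vector("list", n) # per climber: positions of their expeditions
  high_logs <- integer(n) # count of prior expeditions on >= 8000 m peaks
  exp_rows <- vector("list", cfg$n_expeditions)
  rec_rows <- vector("list", cfg$n_expeditions)
  truth_rows <- vector("list", cfg$n_expeditions)
  cause_names <- c("altitude", "logistics", "fatigue", "accident")

  for (e in seq_len(cfg$n_expeditions)) {
    out <- with_substream(cfg$rng_seed, e, {
      size <- sample_int(
        cfg$expedition_size_range[1]:cfg$expedition_size_range[2], 1
      )
      roster <- integer(0)
      if (e > 1 && runif(1) < cfg$group_persistence) {
        src <- rosters[[sample_int(seq_len(e - 1L), 1)]]
        bmax <- min(cfg$seed_block_size_range[2], length(src), size)
        bmin <- min(cfg$seed_block_size_range[1], bmax)
        bsize <- sample_int(bmin:bmax, 1)
        roster <- sample_int(src, bsize)
      }
      rest <- setdiff(seq_len(n), roster)
      roster <- sort(c(roster, sample_int(rest, size - length(roster))))

      # relationships from the history built so far
      prior <- unlist(logs[roster], use.names = FALSE)
      A <- list()
      if (length(prior) > 0) {
        tab <- tabulate(prior, nbins = e - 1L)
        rel <- which(tab >= 2L)
        A <- lapply(rel, function(i) roster[roster %in% rosters[[i]]])
      }
      zeta <- integer(length(roster))
      for (a in A) {
        pos <- match(a, roster)
        zeta[pos] <- pmax(zeta[pos], length(a) - 1L)
      }
      max_dim <- if (length(A) > 0) max(lengths(A)) - 1L else 0L
      in_largest <- if (max_dim > 0) {
        roster %in% unique(unlist(A[lengths(A) == max_dim + 1L]))
      } else {
        rep(FALSE, length(roster))
      }
      has_partner <- vapply(
        roster, function(m) any(vapply(A, function(a) m %in% a, logical(1))),
        logical(1)
      )

      regime_e <- if (cfg$regime == "mixed") {
        sample_int(c("cooperative", "polarized"), 1)
      } else {
        cfg$regime
      }

      peak <- statics$peaks[sample_int(seq_len(nrow(statics$peaks)), 1), ]
      age <- pmin(
        cl$base_age[roster] + (e - 1L) %/% cfg$expeditions_per_year, 75L
      )
      x <- cbind(
        age_below_median = as.numeric(age < median_base_age),
        sex_male = as.numeric(cl$sex[roster] == "male"),
        hired_block = as.numeric(cl$is_hired[roster]),
        experience_8000m = as.numeric(high_logs[roster] > 0),
        oxygen_ascent = as.numeric(cl$oxygen_ascent[roster]),
        oxygen_descent = as.numeric(cl$oxygen_descent[roster])
      )
      outsider <- !in_largest & max_dim > 0
      logit <- cfg$base_success_logit + drop(x %*% cfg$feature_effects)
      if (regime_e == "cooperative") {
        # everyone benefits from their relationships, and the largest
        # subgroup's dimension spills over to the rest of the roster
        logit <- logit + cfg$influence_effect * zeta +
          cfg$cooperative_spillover * max_dim * outsider
      } else {
        # polarized: the benefit of group relationships stays inside the
        # dominant subgroup; everyone else is penalized
        logit <- logit + cfg$influence_effect * zeta * in_largest -
          cfg$polarized_penalty * outsider
      }
      p_success <- plogis(logit)
      p_fail <- (1 - p_success) *
        ifelse(has_partner, cfg$partner_failure_multiplier, 1)
      success <- runif(length(roster)) >= p_fail
      died <- !success & runif(length(roster)) < cfg$death_prob
      outcome <- ifelse(success, "summit_success",
        ifelse(died, "death", "no_summit")
      )
      cause <- ifelse(success, "none",
        sample_int(cause_names, length(roster),
          replace = TRUE, prob = cfg$failure_cause_weights
        )
      )

      days <- 5L + rpois(1, 30)
      n_camps <- sample_int(2:5, 1)
      n_hired <- sum(cl$is_hired[roster])

      # plain vectors, bound into tibbles once after the loop
      list(
        roster = roster,
        expedition = list(
          peak_id = peak$peak_id,
          peak_height = peak$peak_height,
          roster = paste(cl$climber_id[roster], collapse = "|"),
          days_to_summit = days,
          n_camps = n_camps,
          n_members = length(roster) - n_hired,
          n_hired = n_hired
        ),
        records = list(
          age = as.integer(age),
          experience_8000m = high_logs[roster],
          outcome = outcome,
          failure_cause = cause
        ),
        truth = list(
          latent_influence = zeta,
          in_largest = in_largest,
          has_repeated_partner = has_partner,
          regime = regime_e,
          p_success = 1 - p_fail
        )
      )
    })
    rosters[[e]] <- out$roster
    exp_rows[[e]] <- out$expedition
    rec_rows[[e]] <- out$records
    truth_rows[[e]] <- out$truth
    for (m in out$roster) logs[[m]] <- c(logs[[m]], e)
    if (out$expedition$peak_height >= 8000) {
      high_logs[out$roster] <- high_logs[out$roster] + 1L
    }
  }

  exp_id <- sprintf("E%05d", seq_len(cfg$n_expeditions))
  roster_idx <- unlist(rosters, use.names = FALSE)
  rec_exp <- rep(exp_id, lengths(rosters))
  pull <- function(rows, field) unlist(lapply(rows, `[[`, field), use.names = FALSE)
  records <- tibble::tibble(
    climber_id = cl$climber_id[roster_idx],
    expedition_id = rec_exp,
    age = pull(rec_rows, "age"),
    sex = cl$sex[roster_idx],
    nationality = cl$nationality[roster_idx],
    is_hired = cl$is_hired[roster_idx],
    oxygen_ascent = cl$oxygen_ascent[roster_idx],
    oxygen_descent = cl$oxygen_descent[roster_idx],
    experience_8000m = pull(rec_rows, "experience_8000m"),
    outcome = pull(rec_rows, "outcome"),
    failure_cause = pull(rec_rows, "failure_cause")
  )
  expeditions <- tibble::tibble(
    expedition_id = exp_id,
    peak_id = pull(exp_rows, "peak_id"),
    peak_height = pull(exp_rows, "peak_height"),
    time_index = seq_len(cfg$n_expeditions),
    roster = pull(exp_rows, "roster"),
    days_to_summit = as.integer(pull(exp_rows, "days_to_summit")),
    n_camps = as.integer(pull(exp_rows, "n_camps")),
    n_members = as.integer(pull(exp_rows, "n_members")),
    n_hired = as.integer(pull(exp_rows, "n_hired"))
  )
  truth <- tibble::tibble(
    climber_id = cl$climber_id[roster_idx],
    expedition_id = rec_exp,
    latent_influence = pull(truth_rows, "latent_influence"),
    in_largest = pull(truth_rows, "in_largest"),
    has_repeated_partner = pull(truth_rows, "has_repeated_partner"),
    regime = rep(vapply(truth_rows, `[[`, character(1), "regime"), lengths(rosters)),
    p_success = pull(truth_rows, "p_success")
  )

  cohort <- list(
    records = records,
    expeditions = expeditions,
    truth = truth,
    config = cfg
  )
  class(cohort) <- "climber_cohort"
  cohort
}

#' @export
print.climber_cohort <- function(x, ...) {
  cat(sprintf(
    "<climber_cohort> %d records, %d expeditions, %d climbers (seed %d)\n",
    nrow(x$records), nrow(x$expeditions),
    length(unique(x$records$climber_id)), x$config$rng_seed
  ))
  invisible(x)
}

#' Ground truth planted by the generator
#'
#' Exposes the planted parameters and the per-record latent influence
#' trajectory of a generated cohort, for parameter-recovery tests. The
#' latent influence is, by construction, the influence the simplicial
#' analysis recomputes from the emitted tables at `tau = 1`.
#'
#' @param cohort A [generate_cohort()] result.
#' @return List with `parameters` (the generator config) and `influence`
#'   (tibble: `climber_id`, `expedition_id`, `latent_influence`,
#'   `in_largest`, `has_repeated_partner`, `regime`, `p_success`).
#' @export
planted_truth <- function(cohort) {
  if (!inherits(cohort, "climber_cohort")) {
    abort("`cohort` must be a climber_cohort from generate_cohort()")
  }
  list(parameters = cohort$config, influence = cohort$truth)
}
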