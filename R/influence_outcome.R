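#' Mann-Whitney U test (pair-count definition, exact or corrected normal p)
#'
#' U counts, over all pairs `(x in a, y in b)`, 1 when `x > y` and 0.5 when
#' `x == y`. The two-sided p-value is computed by exact enumeration of all
#' label assignments when `length(a) + length(b) <= exact_limit` (valid
#' under ties), and otherwise by the normal approximation with tie
#' correction and continuity correction.
#'
#' @param a,b Nonempty numeric (typically integer-valued) samples.
#' @param exact_limit Largest pooled size for which the exact permutation
#'   distribution is enumerated (default 20).
#' @return One-row tibble: `u`, `p_value`, `n_a`, `n_b`, `method`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4)) # U = 0, exact p = 1/3
mann_whitney_u <- function(a, b, exact_limit = 20) {
  if (length(a) == 0 || length(b) == 0) abort("both samples must be nonempty")
  n1 <- length(a)
  n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled) # midranks
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2

  if (n1 + n2 <= exact_limit) {
    picks <- combn(n1 + n2, n1)
    u_perm <- colSums(matrix(r[picks], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_perm - mu) >= abs(u - mu) - 1e-9)
    method <- "exact"
  } else {
    nn <- n1 + n2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (nn * (nn - 1))
    sigma2 <- n1 * n2 / 12 * ((nn + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal_tie_corrected"
  }
  tibble::tibble(u = u, p_value = p, n_a = n1, n_b = n2, method = method)
}

default_influence_bins <- function() {
  list(c(5, 10), c(10, 15), c(15, 20), c(20, 25))
}

#' Influence distributions and tests by outcome category
#'
#' Summarizes climber influence by outcome (summit success, no summit,
#' death) within experience bins, tests success versus no-summit influence
#' with [mann_whitney_u()] per bin, and computes per-category influence
#' histograms normalized so the fractions of each category sum to one.
#' Only climbers belonging to a simplex of dimension at least
#' `min_influence` are considered (mirroring the exclusion of
#' zero-influence climbers). Deaths are summarized but never tested.
#'
#' @param influence_tbl Tibble with `climber_id`, `expedition_id`,
#'   `influence` (see [influence_table()]).
#' @param records Climber-expedition record tibble.
#' @param expeditions Expedition tibble (for the prior-climb counts that
#'   define experience).
#' @param experience_bins List of `c(lo, hi)` prior-climb ranges; default
#'   5-10, 10-15, 15-20, 20-25.
#' @param min_influence Minimum influence for inclusion (default 1).
#' @param alpha Significance level reported alongside the p-values
#'   (default 0.1); no multiple-testing correction is applied.
#' @return List of class `influence_outcome`: `summary` (per bin and
#'   outcome: n, median, quartiles), `tests` (per bin: U, p, significance,
#'   or a skip reason when a group is empty), `histogram` (per outcome and
#'   influence value: fraction).
#' @export
influence_by_outcome <- function(influence_tbl, records, expeditions,
                                 experience_bins = default_influence_bins(),
                                 min_influence = 1, alpha = 0.1) {
  prior <- prior_climb_counts(records, expeditions)
  dat <- influence_tbl |>
    dplyr::inner_join(
      dplyr::select(records, "climber_id", "expedition_id", "outcome"),
      by = c("climber_id", "expedition_id")
    ) |>
    dplyr::left_join(prior, by = c("climber_id", "expedition_id")) |>
    dplyr::filter(.data$influence >= min_influence)

  summary_rows <- list()
  test_rows <- list()
  for (bin in experience_bins) {
    in_bin <- dat[dat$prior_climbs >= bin[1] & dat$prior_climbs < bin[2], ]
    for (oc in outcome_levels) {
      z <- in_bin$influence[in_bin$outcome == oc]
      summary_rows[[length(summary_rows) + 1L]] <- tibble::tibble(
        experience_bin = bin_label(bin),
        outcome = oc,
        n = length(z),
        median = if (length(z)) median(z) else NA_real_,
        q1 = if (length(z)) unname(quantile(z, 0.25)) else NA_real_,
        q3 = if (length(z)) unname(quantile(z, 0.75)) else NA_real_
      )
    }
    zs <- in_bin$influence[in_bin$outcome == "summit_success"]
    zu <- in_bin$influence[in_bin$outcome == "no_summit"]
    if (length(zs) == 0 || length(zu) == 0) {
      test_rows[[length(test_rows) + 1L]] <- tibble::tibble(
        experience_bin = bin_label(bin),
        n_success = length(zs), n_no_summit = length(zu),
        u = NA_real_, p_value = NA_real_, significant = NA,
        skipped = TRUE,
        reason = "empty outcome category in bin"
      )
    } else {
      tst <- mann_whitney_u(zs, zu)
      test_rows[[length(test_rows) + 1L]] <- tibble::tibble(
        experience_bin = bin_label(bin),
        n_success = length(zs), n_no_summit = length(zu),
        u = tst$u, p_value = tst$p_value,
        significant = tst$p_value < alpha,
        skipped = FALSE, reason = NA_character_
      )
    }
  }

  histogram <- dat |>
    dplyr::count(.data$outcome, .data$influence) |>
    dplyr::group_by(.data$outcome) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::select("outcome", "influence", "fraction")

  structure(
    list(
      summary = dplyr::bind_rows(summary_rows),
      tests = dplyr::bind_rows(test_rows),
      histogram = histogram,
      alpha = alpha,
      min_influence = min_influence
    ),
    class = "influence_outcome"
  )
}

#' @export
print.influence_outcome <- function(x, ...) {
  cat("<influence_outcome>\n")
  print(x$tests)
  invisible(x)
}

#' @method tidy influence_outcome
#' @export
tidy.influence_outcome <- function(x, ...) x$tests

#' @method glance influence_outcome
#' @export
glance.influence_outcome <- function(x, ...) {
  tibble::tibble(
    n_bins = nrow(x$tests),
    n_tested = sum(!x$tests$skipped),
    n_significant = sum(x$tests$significant, na.rm = TRUE),
    alpha = x$alpha,
    min_influence = x$min_influence
  )
}

#' Influence-by-outcome summaries across a threshold sweep
#'
#' Recomputes the cohort influence table at each weight threshold and
#' summarizes it with [influence_by_outcome()]. Influence is non-increasing
#' in the threshold: raising `tau` discards weak simplices, so each
#' climber's maximal simplicial dimension can only fall.
#'
#' @inheritParams influence_by_outcome
#' @param tau_values Ascending integer thresholds.
#' @return List of class `influence_tau_sweep`: `influence` (tibble with
#'   `tau`, `expedition_id`, `climber_id`, `influence`) and `summaries`
#'   (named list of [influence_by_outcome()] results per threshold).
#' @export
influence_tau_sweep <- function(records, expeditions, tau_values = 1:4,
                                experience_bins = default_influence_bins(),
                                min_influence = 1, alpha = 0.1) {
  if (any(diff(tau_values) <= 0) || tau_values[1] < 1) {
    abort("`tau_values` must be strictly ascending with minimum >= 1")
  }
  stats <- cohort_complex_stats(expeditions, tau_values = tau_values)
  inf <- dplyr::select(
    stats$influence, "tau", "expedition_id", "climber_id", "influence"
  )
  summaries <- lapply(tau_values, function(t) {
    influence_by_outcome(
      inf[inf$tau == t, c("expedition_id", "climber_id", "influence")],
      records, expeditions,
      experience_bins = experience_bins,
      min_influence = min_influence, alpha = alpha
    )
  })
  names(summaries) <- paste0("tau_", tau_values)
  structure(
    list(influence = inf, summaries = summaries),
    class = "influence_tau_sweep"
  )
}
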