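#' Flag records climbed with at least one repeated partner
#'
#' A record is flagged when at least one co-roster member shares at least
#' one strictly earlier joint expedition with the climber.
#'
#' @param records Climber-expedition record tibble.
#' @param expeditions Expedition tibble (supplies rosters and the temporal
#'   order).
#' @return Tibble `climber_id`, `expedition_id`, `has_repeated_partner`.
#' @export
repeated_partner_flags <- function(records, expeditions) {
  idx <- cohort_index(expeditions)
  inter <- cohort_intersections(idx)
  rows <- lapply(seq_along(idx$rosters), function(e) {
    roster <- idx$rosters[[e]]
    flagged <- unique(unlist(inter[[e]]))
    tibble::tibble(
      climber_id = idx$climbers[roster],
      expedition_id = idx$exp_id[e],
      has_repeated_partner = roster %in% flagged
    )
  })
  out <- dplyr::bind_rows(rows)
  dplyr::left_join(
    dplyr::select(records, "climber_id", "expedition_id"),
    out,
    by = c("climber_id", "expedition_id")
  )
}

#' Count each record's strictly earlier climbs
#'
#' The total number of climbs used for experience normalization: for every
#' (climber, expedition) record, the number of the climber's expeditions
#' with strictly smaller `time_index`, recomputed from the logged history
#' rather than trusted from input columns.
#'
#' @inheritParams repeated_partner_flags
#' @return Tibble `climber_id`, `expedition_id`, `prior_climbs`.
#' @export
prior_climb_counts <- function(records, expeditions) {
  idx <- cohort_index(expeditions)
  counts <- integer(length(idx$climbers))
  rows <- vector("list", length(idx$rosters))
  for (e in seq_along(idx$rosters)) {
    roster <- idx$rosters[[e]]
    rows[[e]] <- tibble::tibble(
      climber_id = idx$climbers[roster],
      expedition_id = idx$exp_id[e],
      prior_climbs = counts[roster]
    )
    counts[roster] <- counts[roster] + 1L
  }
  out <- dplyr::bind_rows(rows)
  dplyr::left_join(
    dplyr::select(records, "climber_id", "expedition_id"),
    out,
    by = c("climber_id", "expedition_id")
  )
}

default_experience_bins <- function(from = 15, to = 40, width = 5) {
  lo <- seq(from, to - width, by = width)
  lapply(lo, function(l) c(l, l + width))
}

bin_label <- function(bin) sprintf("%d-%d", bin[1], bin[2])

#' Failure-rate ratios when climbing with repeated partners
#'
#' For each experience bin and failure category, the ratio of the pooled
#' failure rate of that category among flagged records (at least one
#' repeated partner) in the bin, over the pooled failure rate of the
#' category across *all* records of the climbers contributing to the bin
#' (their personal average). Ratios below 1 mean climbing with repeated
#' partners lowers that failure mode. Records are assigned to bins by their
#' count of strictly earlier climbs, `lo <= prior_climbs < hi`.
#'
#' @inheritParams repeated_partner_flags
#' @param bins List of `c(lo, hi)` prior-climb ranges; default width-5 bins
#'   from `min_total_climbs` up to 40.
#' @param min_total_climbs Records with fewer strictly earlier climbs are
#'   excluded (default 15, so beginners do not dilute the comparison).
#' @param flags Optional precomputed [repeated_partner_flags()] result.
#' @return Tibble `experience_bin`, `failure_category`, `ratio` (`NA` when
#'   the bin is empty or the denominator rate is zero),
#'   `rate_with_partner`, `rate_overall` (the pooled rates the ratio
#'   divides), `n_climbers`, `n_records_with_partner`.
#' @export
failure_ratio_analysis <- function(records, expeditions, bins = NULL,
                                   min_total_climbs = 15, flags = NULL) {
  bins <- bins %||% default_experience_bins(from = min_total_climbs)
  flags <- flags %||% repeated_partner_flags(records, expeditions)
  prior <- prior_climb_counts(records, expeditions)
  dat <- records |>
    dplyr::left_join(flags, by = c("climber_id", "expedition_id")) |>
    dplyr::left_join(prior, by = c("climber_id", "expedition_id"))

  categories <- setdiff(failure_cause_levels, "none")
  rows <- list()
  for (bin in bins) {
    in_bin <- dat$prior_climbs >= bin[1] & dat$prior_climbs < bin[2] &
      dat$prior_climbs >= min_total_climbs
    bin_climbers <- unique(dat$climber_id[in_bin])
    flagged <- dat[in_bin & dat$has_repeated_partner, ]
    all_of_them <- dat[dat$climber_id %in% bin_climbers, ]
    for (cat in categories) {
      num_n <- nrow(flagged)
      den_n <- nrow(all_of_them)
      num_rate <- if (num_n > 0) mean(flagged$failure_cause == cat) else NA_real_
      den_rate <- if (den_n > 0) mean(all_of_them$failure_cause == cat) else NA_real_
      ratio <- if (is.na(num_rate) || is.na(den_rate) || den_rate == 0) {
        NA_real_
      } else {
        num_rate / den_rate
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        experience_bin = bin_label(bin),
        failure_category = cat,
        ratio = ratio,
        rate_with_partner = num_rate,
        rate_overall = den_rate,
        n_climbers = length(bin_climbers),
        n_records_with_partner = num_n
      )
    }
  }
  dplyr::bind_rows(rows)
}
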