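test_that("repeated-partner flags follow the joint history", {
  # first meeting is unflagged, the reunion is flagged for both
  exps <- make_expeditions(list(c("a", "b", "c"), c("a", "b", "d")))
  recs <- make_records(exps)
  fl <- repeated_partner_flags(recs, exps)
  expect_false(any(fl$has_repeated_partner[fl$expedition_id == "e001"]))
  e2 <- fl[fl$expedition_id == "e002", ]
  expect_equal(
    e2$has_repeated_partner[match(c("a", "b", "d"), e2$climber_id)],
    c(TRUE, TRUE, FALSE)
  )
})

test_that("flags equal brute-force pairwise history intersection", {
  coh <- generate_cohort(generator_config(
    n_climbers = 30, n_expeditions = 40, rng_seed = 9
  ))
  fl <- repeated_partner_flags(coh$records, coh$expeditions)
  rosters <- strsplit(coh$expeditions$roster, "|", fixed = TRUE)
  names(rosters) <- coh$expeditions$expedition_id
  tidx <- setNames(coh$expeditions$time_index, coh$expeditions$expedition_id)
  brute <- function(cid, eid) {
    mates <- setdiff(rosters[[eid]], cid)
    earlier <- names(rosters)[tidx < tidx[[eid]]]
    any(vapply(earlier, function(h) {
      cid %in% rosters[[h]] && any(mates %in% rosters[[h]])
    }, logical(1)))
  }
  got <- mapply(brute, fl$climber_id, fl$expedition_id)
  expect_equal(fl$has_repeated_partner, unname(got))
})

test_that("prior climb counts are strictly-earlier tallies", {
  exps <- make_expeditions(list(c("a", "b"), c("a", "c"), c("a", "b")))
  recs <- make_records(exps)
  pc <- prior_climb_counts(recs, exps)
  a <- pc[pc$climber_id == "a", ]
  expect_equal(a$prior_climbs[order(a$expedition_id)], c(0L, 1L, 2L))
  b <- pc[pc$climber_id == "b", ]
  expect_equal(b$prior_climbs[order(b$expedition_id)], c(0L, 1L))
})

test_that("a bin whose flagged records contain no failures gives ratio 0", {
  # climbers a,b meet repeatedly; all flagged records succeed, unflagged fail
  exps <- make_expeditions(list(
    c("a", "b"), c("a", "b"), c("a", "b"), c("a", "b")
  ))
  outcomes <- list(
    e002 = list(a = "summit_success", b = "summit_success"),
    e003 = list(a = "summit_success", b = "summit_success"),
    e004 = list(a = "summit_success", b = "summit_success")
  )
  recs <- make_records(exps, outcomes)
  fr <- failure_ratio_analysis(recs, exps,
    bins = list(c(1, 5)), min_total_climbs = 1
  )
  expect_equal(fr$ratio[fr$failure_category == "altitude"], 0)
})

test_that("empty bins give undefined ratios, not errors", {
  exps <- make_expeditions(list(c("a", "b")))
  recs <- make_records(exps)
  fr <- failure_ratio_analysis(recs, exps,
    bins = list(c(15, 20)), min_total_climbs = 15
  )
  expect_true(all(is.na(fr$ratio)))
  expect_equal(unique(fr$n_records_with_partner), 0L)
})

test_that("ratios are invariant to duplicating every record", {
  coh <- generate_cohort(generator_config(
    n_climbers = 40, n_expeditions = 50,
    partner_failure_multiplier = 0.6, rng_seed = 11
  ))
  bins <- list(c(2, 6), c(6, 10))
  fr1 <- failure_ratio_analysis(coh$records, coh$expeditions,
    bins = bins, min_total_climbs = 2
  )
  # duplicating every record leaves all pooled rates unchanged
  flags <- repeated_partner_flags(coh$records, coh$expeditions)
  dup_records <- dplyr::bind_rows(coh$records, coh$records)
  dup_flags <- dplyr::bind_rows(flags, flags)
  fr2 <- suppressWarnings(failure_ratio_analysis(dup_records, coh$expeditions,
    bins = bins, min_total_climbs = 2, flags = dup_flags
  ))
  expect_equal(fr1$ratio, fr2$ratio)
})

test_that("a null cohort (kappa = 1) keeps failure ratios near 1", {
  # no planted partner effect and no influence effect: every ratio entry
  # should scatter tightly around 1; checked across several seeds
  outside <- 0L
  total <- 0L
  for (seed in 1:20) {
    coh <- generate_cohort(generator_config(
      n_climbers = 800, n_expeditions = 1000,
      expedition_size_range = c(4, 6),
      group_persistence = 0.6, influence_effect = 0,
      base_success_logit = -0.85,
      partner_failure_multiplier = 1, rng_seed = seed
    ))
    fr <- failure_ratio_analysis(coh$records, coh$expeditions,
      bins = list(c(3, 6), c(6, 9), c(9, 30)), min_total_climbs = 3
    )
    ok <- !is.na(fr$ratio)
    outside <- outside + sum(fr$ratio[ok] < 0.8 | fr$ratio[ok] > 1.2)
    total <- total + sum(ok)
  }
  expect_lt(outside / total, 0.1)
})
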