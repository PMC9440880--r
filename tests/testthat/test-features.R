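test_that("feature incidence encodes the six binary features", {
  exps <- make_expeditions(list(c("a", "b")))
  recs <- make_records(exps, outcomes = list(e001 = list(a = "summit_success")))
  recs$age <- c(30L, 50L)
  recs$sex <- c("male", "female")
  recs$oxygen_ascent <- c(TRUE, FALSE)
  recs$oxygen_descent <- c(TRUE, FALSE)
  inc <- feature_incidence(recs, exps, median_age = 40)
  a <- inc[inc$climber_id == "a", ]
  expect_equal(
    unlist(a[, personal_feature_names]),
    c(
      age_below_median = 1L, sex_male = 1L, hired_block = 0L,
      experience_8000m = 0L, oxygen_ascent = 1L, oxygen_descent = 1L
    )
  )
  expect_true(a$success)

  # 8000m experience is recomputed from the expedition history
  exps2 <- make_expeditions(list(c("a", "b"), c("a", "c")), peak_height = 8201)
  recs2 <- make_records(exps2)
  inc2 <- feature_incidence(recs2, exps2, median_age = 40)
  expect_equal(
    inc2$experience_8000m[inc2$expedition_id == "e001"], c(0L, 0L)
  )
  expect_equal(
    inc2$experience_8000m[inc2$climber_id == "a" & inc2$expedition_id == "e002"],
    1L
  )
})

test_that("feature matrices split by the safe-summit criterion", {
  rosters <- list(sprintf("m%02d", 1:12), sprintf("m%02d", 7:18))
  exps <- make_expeditions(rosters)
  recs <- make_records(exps, outcomes = list(
    e001 = setNames(
      as.list(rep("summit_success", 5)), sprintf("m%02d", 1:5)
    )
  ))
  fm <- build_feature_matrix(recs, exps, min_members = 12)
  expect_equal(nrow(fm), 2)
  expect_equal(fm$n_success[fm$expedition_id == "e001"], 5L)
  expect_equal(nrow(fm$P_success[[1]]), 5)
  expect_equal(nrow(fm$P_failure[[1]]), 7)
  # an expedition with no successes still contributes a failure matrix
  expect_equal(nrow(fm$P_success[[2]]), 0)

  # undersized expeditions are skipped and recorded
  fm2 <- build_feature_matrix(recs, exps, min_members = 13)
  expect_equal(nrow(fm2), 0)
  expect_equal(sort(attr(fm2, "skipped")), c("e001", "e002"))
})

test_that("bipartite projection counts pairwise co-expression", {
  # one climber with every feature: all off-diagonal entries are 1
  P <- matrix(1, nrow = 1, ncol = 6, dimnames = list("a", personal_feature_names))
  I <- project_features(P)
  expect_true(all(I[upper.tri(I)] == 1))
  expect_true(all(diag(I) == 0))

  # disjoint feature sets never co-occur
  P2 <- rbind(c(1, 1, 0, 0, 0, 0), c(0, 0, 1, 1, 1, 1))
  I2 <- project_features(P2)
  expect_equal(sum(I2) - I2[1, 2] - I2[2, 1], sum(project_features(P2[2, , drop = FALSE])))
  expect_equal(I2[1, 3], 0)

  # random binary matrix against an explicit double loop
  withr::with_seed(29, {
    P3 <- matrix(rbinom(20 * 6, 1, 0.5), nrow = 20)
  })
  I3 <- project_features(P3)
  expect_equal(I3, t(I3))
  for (f in 1:6) {
    for (g in 1:6) {
      if (f == g) next
      manual <- sum(P3[, f] == 1 & P3[, g] == 1)
      expect_equal(I3[f, g], manual)
    }
  }
})

test_that("eigenvector centrality matches closed forms and a dense solver", {
  # complete graph: symmetry forces uniform centrality
  K <- matrix(1, 4, 4) - diag(4)
  expect_equal(unname(eigenvector_centrality(K)), rep(0.5, 4), tolerance = 1e-9)

  # star with 4 leaves: center 1/sqrt(2), each leaf 1/(2*sqrt(2))
  S <- matrix(0, 5, 5)
  S[1, 2:5] <- 1
  S[2:5, 1] <- 1
  v <- eigenvector_centrality(S)
  expect_equal(unname(v[1]), 1 / sqrt(2), tolerance = 1e-8)
  expect_equal(unname(v[2:5]), rep(1 / (2 * sqrt(2)), 4), tolerance = 1e-8)

  # random PSD-ish co-occurrence matrix against eigen()
  withr::with_seed(29, {
    P <- matrix(rbinom(30 * 6, 1, 0.5), nrow = 30)
  })
  I <- project_features(P)
  v2 <- eigenvector_centrality(I)
  ref <- eigen(I, symmetric = TRUE)$vectors[, 1]
  ref <- ref * sign(sum(ref))
  expect_equal(unname(v2), ref, tolerance = 1e-8)

  # permutation equivariance
  perm <- c(3, 1, 2, 6, 5, 4)
  vp <- eigenvector_centrality(I[perm, perm])
  expect_equal(unname(vp), unname(v2[perm]), tolerance = 1e-8)

  # zero matrix: uniform with a degenerate flag
  z <- eigenvector_centrality(matrix(0, 3, 3))
  expect_equal(as.numeric(z), rep(1 / sqrt(3), 3))
  expect_true(attr(z, "degenerate"))
})

test_that("identical groups give zero centrality differences", {
  rosters <- list(sprintf("m%02d", 1:12))
  exps <- make_expeditions(rosters)
  recs <- make_records(exps, outcomes = list(
    e001 = setNames(
      as.list(rep("summit_success", 6)), sprintf("m%02d", 1:6)
    )
  ))
  # all helper records share identical features, so both groups project to
  # the same network
  fm <- build_feature_matrix(recs, exps, min_members = 12)
  cc <- suppressWarnings(centrality_comparison(fm))
  expect_true(all(abs(cc$difference) < 1e-9))
  # single contributing expedition: standard errors undefined
  expect_true(all(is.na(cc$se_success)))
})

test_that("a planted feature effect surfaces in the centrality ranking", {
  hits <- 0L
  for (seed in 1:10) {
    coh <- generate_cohort(generator_config(
      n_climbers = 250, n_expeditions = 60,
      expedition_size_range = c(12, 16),
      group_persistence = 0.3, influence_effect = 0,
      feature_effects = c(0, 0, 0, 0, 1.5, 0), # oxygen_ascent
      rng_seed = seed
    ))
    fm <- build_feature_matrix(coh$records, coh$expeditions, min_members = 12)
    cc <- centrality_comparison(fm)
    rank_ox <- which(rev(cc$feature) == "oxygen_ascent")
    if (rank_ox <= 2) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})

test_that("factor correlations recover planted signs and degeneracies", {
  # success rate decreasing in days_to_summit plus noise: negative PCC
  withr::with_seed(5, {
    n <- 60
    exps <- make_expeditions(replicate(n, c("a", "b"), simplify = FALSE))
    exps$expedition_id <- sprintf("e%03d", 1:n)
    exps$days_to_summit <- as.integer(30 + sample(0:30, n, replace = TRUE))
    rate <- pmin(pmax(1 - 0.02 * (exps$days_to_summit - 30) +
      rnorm(n, 0, 0.05), 0), 1)
  })
  rates <- tibble::tibble(
    expedition_id = exps$expedition_id, n_members = 2L, success_rate = rate
  )
  fc <- factor_correlations(exps, rates)
  expect_lt(fc$estimate[fc$factor == "days_to_summit"], -0.5)

  # constant factor: undefined marker
  expect_true(fc$degenerate[fc$factor == "n_camps"])

  # members-to-hired ratio undefined when nothing is hired
  expect_true(fc$degenerate[fc$factor == "members_to_hired_ratio"])

  # permuted factors: no spurious correlation
  withr::with_seed(6, {
    n <- 200
    exps2 <- make_expeditions(replicate(n, c("a", "b"), simplify = FALSE))
    exps2$expedition_id <- sprintf("e%03d", 1:n)
    exps2$days_to_summit <- as.integer(sample(20:60, n, replace = TRUE))
    exps2$n_camps <- sample(2:6, n, replace = TRUE)
    exps2$n_members <- sample(2:10, n, replace = TRUE)
    exps2$n_hired <- sample(1:5, n, replace = TRUE)
    rates2 <- tibble::tibble(
      expedition_id = exps2$expedition_id,
      n_members = 2L,
      success_rate = runif(n)
    )
  })
  fc2 <- factor_correlations(exps2, rates2)
  expect_true(all(abs(fc2$estimate) < 0.2, na.rm = TRUE))
})
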