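test_that("repeated joint expeditions become a weighted simplex", {
  # three climbers with exactly four previous joint expeditions: the
  # triangle {i,j,k} carries weight 4 and persists up to threshold 4
  exps <- make_expeditions(list(
    c("i", "j", "k", "p"), c("i", "j", "k", "q"),
    c("i", "j", "k", "r"), c("i", "j", "k", "s"),
    c("i", "j", "k", "z")
  ))
  cx <- build_complex(exps, "e005", tau = 1)
  tri <- cx[cx$simplex == "i|j|k", ]
  expect_equal(tri$dimension, 2L)
  expect_equal(tri$weight, 4L)
  expect_true(tri$is_maximal)
  # closure: both edges and vertices of the triangle are present
  expect_true(all(c("i|j", "i|k", "j|k") %in% cx$simplex))

  sweep <- filtration_sweep(exps, "e005", 1:5)
  present <- vapply(sweep, function(s) "i|j|k" %in% s$simplex, logical(1))
  expect_equal(unname(present), c(TRUE, TRUE, TRUE, TRUE, FALSE))
})

test_that("influence is the dimension of the largest containing simplex", {
  # previous joint expeditions intersecting the roster in subgroups of
  # sizes 3, 5, 7 (climber included) give influence 6
  roster <- c("c", sprintf("m%d", 1:6), "x")
  exps <- make_expeditions(list(
    c("c", "m1", "m2", "out1"),
    c("c", sprintf("m%d", 1:4), "out2"),
    c("c", sprintf("m%d", 1:6), "out3"),
    roster
  ))
  cx <- build_complex(exps, "e004", tau = 1)
  expect_equal(influence(cx, "c"), 6L)
  expect_equal(influence(cx, "m5"), 6L)
  expect_equal(influence(cx, "x"), 0L)
  expect_error(influence(cx, "stranger"), "not in the roster")
})

test_that("empty history yields only vertices", {
  exps <- make_expeditions(list(c("a", "b", "c")))
  cx <- build_complex(exps, "e001", tau = 1)
  expect_equal(nrow(cx), 3)
  expect_equal(attr(cx, "max_dimension"), 0L)
  expect_equal(cx$weight, rep(0L, 3))
  expect_equal(co_influence(cx), 0)
  census <- simplex_census(cx)
  expect_equal(census$count, 3L)
})

test_that("census arithmetic matches closure of a filled triangle", {
  exps <- make_expeditions(list(c("a", "b", "c"), c("a", "b", "c")))
  cx <- build_complex(exps, "e002", tau = 1)
  census <- simplex_census(cx)
  expect_equal(census$dimension, 0:2)
  expect_equal(census$count, c(3L, 3L, 1L))
})

test_that("co-influence averages member influences", {
  exps <- make_expeditions(list(c("a", "b", "c"), c("a", "b", "c")))
  cx <- build_complex(exps, "e002", tau = 1)
  expect_equal(co_influence(cx), 2)
})

test_that("tau below 1 and non-ascending sweeps are rejected", {
  exps <- make_expeditions(list(c("a", "b")))
  expect_error(build_complex(exps, "e001", tau = 0), "integer >= 1")
  expect_error(filtration_sweep(exps, "e001", c(2, 1)), "ascending")
})

test_that("complex matches exhaustive subset enumeration on random instances", {
  for (seed in c(3, 11, 27)) {
    inst <- random_instance(seed)
    exps <- instance_expeditions(inst)
    for (tau in 1:3) {
      orc <- oracle_complex(inst$history, inst$roster, tau)
      cx <- build_complex(exps, current_id_of(exps), tau = tau)
      expect_identical(complex_keys(cx), oracle_keys(orc))
      hi <- cx[cx$dimension >= 1, ]
      orc_wt <- setNames(
        orc$weights,
        vapply(orc$simplices, paste, character(1), collapse = "|")
      )
      expect_equal(hi$weight, unname(orc_wt[hi$simplex]))
      expect_equal(attr(cx, "max_dimension"), orc$max_dimension)
      for (m in orc$roster) {
        expect_equal(influence(cx, m), orc$zeta[[m]])
      }
      v <- cx[cx$dimension == 0, ]
      expect_equal(
        v$weight[match(orc$roster, v$simplex)],
        unname(orc$vertex_weight)
      )
    }
  }
})

test_that("filtration is nested with monotone weights and dimensions", {
  for (seed in c(3, 8, 15)) {
    inst <- random_instance(seed)
    exps <- instance_expeditions(inst)
    sweep <- filtration_sweep(exps, current_id_of(exps), 1:4)
    keys <- lapply(sweep, complex_keys)
    dims <- vapply(sweep, attr, integer(1), "max_dimension")
    for (j in 1:3) {
      expect_true(all(keys[[j + 1]] %in% keys[[j]]))
    }
    expect_true(all(diff(dims) <= 0))

    # face weight >= simplex weight, for every face of every simplex
    cx <- sweep[[1]]
    wt <- setNames(cx$weight, cx$simplex)
    for (i in which(cx$dimension >= 2)) {
      verts <- cx$vertices[[i]]
      for (k in 2:(length(verts) - 1)) {
        for (f in utils::combn(verts, k, simplify = FALSE)) {
          expect_gte(wt[[paste(f, collapse = "|")]], cx$weight[i])
        }
      }
    }

    # influence never exceeds the complex dimension
    for (s in sweep) {
      zs <- vapply(attr(s, "roster"), function(m) influence(s, m), numeric(1))
      expect_true(all(zs <= attr(s, "max_dimension")))
    }
  }
})

test_that("cohort influence table agrees with per-expedition complexes", {
  coh <- generate_cohort(generator_config(
    n_climbers = 25, n_expeditions = 20, rng_seed = 5
  ))
  for (tau in c(1L, 2L)) {
    it <- influence_table(coh$expeditions, tau = tau)
    for (eid in utils::tail(coh$expeditions$expedition_id, 5)) {
      cx <- build_complex(coh$expeditions, eid, tau = tau)
      for (m in attr(cx, "roster")) {
        expect_equal(
          it$influence[it$expedition_id == eid & it$climber_id == m],
          influence(cx, m)
        )
      }
    }
  }
})
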