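# fixture builders and independent oracles, all generated in code

# expedition table from a list of character rosters, in temporal order
make_expeditions <- function(rosters, peak_height = 8849) {
  tibble::tibble(
    expedition_id = sprintf("e%03d", seq_along(rosters)),
    peak_id = "P1",
    peak_height = peak_height,
    time_index = seq_along(rosters),
    roster = vapply(rosters, function(r) paste(sort(r), collapse = "|"), character(1)),
    days_to_summit = 40L,
    n_camps = 4L,
    n_members = lengths(rosters),
    n_hired = 0L
  )
}

# records for every roster member; outcomes given per expedition as a named
# list climber_id -> outcome, default no_summit/altitude
make_records <- function(expeditions, outcomes = list()) {
  rows <- lapply(seq_len(nrow(expeditions)), function(i) {
    roster <- strsplit(expeditions$roster[i], "|", fixed = TRUE)[[1]]
    eid <- expeditions$expedition_id[i]
    oc <- vapply(roster, function(m) {
      outcomes[[eid]][[m]] %||% "no_summit"
    }, character(1))
    tibble::tibble(
      climber_id = roster,
      expedition_id = eid,
      age = 35L,
      sex = "male",
      nationality = "USA",
      is_hired = FALSE,
      oxygen_ascent = TRUE,
      oxygen_descent = FALSE,
      experience_8000m = 0L,
      outcome = oc,
      failure_cause = ifelse(oc == "summit_success", "none", "altitude")
    )
  })
  dplyr::bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- subset-enumeration oracle for the simplicial core ----------------------
# enumerates every subset of the current roster with >= 2 members and counts
# its support directly against the history rosters
oracle_complex <- function(history_rosters, current_roster, tau) {
  roster <- sort(current_roster)
  subsets <- list()
  for (k in 2:max(2, length(roster))) {
    if (k > length(roster)) break
    subsets <- c(subsets, utils::combn(roster, k, simplify = FALSE))
  }
  support <- vapply(subsets, function(s) {
    sum(vapply(history_rosters, function(h) all(s %in% h), logical(1)))
  }, numeric(1))
  keep <- support >= tau
  simplices <- subsets[keep]
  weights <- support[keep]
  zeta <- vapply(roster, function(m) {
    sizes <- lengths(simplices)[vapply(simplices, function(s) m %in% s, logical(1))]
    if (length(sizes) == 0) 0L else max(sizes) - 1L
  }, integer(1))
  vertex_weight <- vapply(roster, function(m) {
    sum(vapply(history_rosters, function(h) {
      m %in% h && length(intersect(h, roster)) >= 2
    }, logical(1)))
  }, integer(1))
  census <- table(factor(c(rep(0L, length(roster)), lengths(simplices) - 1L)))
  list(
    roster = roster,
    simplices = simplices,
    weights = as.integer(weights),
    zeta = zeta,
    vertex_weight = vertex_weight,
    max_dimension = if (length(simplices)) max(lengths(simplices)) - 1L else 0L,
    census = census
  )
}

# random oracle instance: roster of 3..8 climbers, up to 10 history
# expeditions drawn from a slightly larger pool
random_instance <- function(seed) {
  withr::with_seed(seed, {
    pool <- sprintf("c%02d", 1:12)
    n_roster <- sample(3:8, 1)
    roster <- sort(sample(pool, n_roster))
    n_hist <- sample(0:10, 1)
    history <- lapply(seq_len(n_hist), function(i) {
      sort(sample(pool, sample(2:8, 1)))
    })
    list(roster = roster, history = history)
  })
}

# expedition tables for an oracle instance (history first, current last)
instance_expeditions <- function(inst) {
  make_expeditions(c(inst$history, list(inst$roster)))
}

current_id_of <- function(exps) exps$expedition_id[nrow(exps)]

# sorted simplex keys of all rows with dimension >= 1
complex_keys <- function(cx) {
  sort(cx$simplex[cx$dimension >= 1])
}

oracle_keys <- function(orc) {
  sort(vapply(orc$simplices, paste, character(1), collapse = "|"))
}

# ---- brute-force Mann-Whitney oracle ----------------------------------------
oracle_mwu_u <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

oracle_mwu_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  mu <- n1 * length(b) / 2
  obs <- oracle_mwu_u(a, b)
  picks <- utils::combn(length(pooled), n1, simplify = FALSE)
  us <- vapply(picks, function(ix) {
    oracle_mwu_u(pooled[ix], pooled[-ix])
  }, numeric(1))
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}
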