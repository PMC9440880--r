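# ---- internal machinery -----------------------------------------------------
#
# A climber's relationships inside one expedition are determined by the
# intersections of earlier rosters with the current roster. Everything the
# analyses need (simplex weights, influence, filtrations) is a function of
# that family of intersection sets A_1..A_m:
#
#   support(s) = #{ i : s is a subset of A_i }
#
# and a subset s of the roster with |s| >= 2 is a simplex at threshold tau
# iff support(s) >= tau, with weight support(s). Support is monotone
# non-increasing under taking supersets, so the thresholded simplex set is
# automatically closed under inclusion. We never enumerate all 2^|roster|
# subsets: every maximal simplex is an intersection of some subfamily of the
# A_i, so the intersection-closure of the family (with supports) carries the
# complete structure.

# order expeditions by time_index and code rosters as integer vectors
cohort_index <- function(expeditions) {
  ord <- order(expeditions$time_index)
  exp_id <- expeditions$expedition_id[ord]
  climbers <- sort(unique(unlist(split_roster(expeditions$roster))))
  rosters <- lapply(split_roster(expeditions$roster)[ord], function(r) {
    sort(match(r, climbers))
  })
  list(
    exp_id = exp_id,
    time_index = expeditions$time_index[ord],
    rosters = rosters,
    climbers = climbers
  )
}

# for every expedition (chronological positions), the intersections of each
# strictly earlier roster with the current one, kept when they have >= 2
# members; single pass using per-climber expedition logs
cohort_intersections <- function(idx) {
  n_exp <- length(idx$rosters)
  logs <- vector("list", length(idx$climbers))
  out <- vector("list", n_exp)
  for (e in seq_len(n_exp)) {
    r <- idx$rosters[[e]]
    prior <- unlist(logs[r], use.names = FALSE)
    if (length(prior) > 0) {
      tab <- tabulate(prior, nbins = e - 1L)
      rel <- which(tab >= 2L)
      out[[e]] <- lapply(rel, function(i) r[r %in% idx$rosters[[i]]])
    } else {
      out[[e]] <- list()
    }
    for (m in r) logs[[m]] <- c(logs[[m]], e)
  }
  out
}

set_key <- function(s) paste(s, collapse = "|")

# intersection-closure of a family of integer sets, with supports; sets of
# size < 2 are dropped (intersections only shrink, so this loses nothing)
closure_family <- function(A) {
  sets <- list()
  keys <- character()
  for (a in A) {
    cand <- c(list(a), lapply(sets, function(s) s[s %in% a]))
    for (s in cand) {
      if (length(s) < 2L) next
      k <- set_key(s)
      if (!(k %in% keys)) {
        sets[[length(sets) + 1L]] <- s
        keys <- c(keys, k)
      }
    }
  }
  support <- vapply(
    sets,
    function(s) sum(vapply(A, function(a) all(s %in% a), logical(1))),
    numeric(1)
  )
  list(sets = sets, support = as.integer(support))
}

# maximal elements of a list of integer sets (no strict superset present)
maximal_sets <- function(sets) {
  n <- length(sets)
  if (n == 0) return(logical(0))
  keep <- rep(TRUE, n)
  sz <- lengths(sets)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && sz[j] > sz[i] && all(sets[[i]] %in% sets[[j]])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  keep
}

# everything one expedition's analyses need at one threshold
complex_core <- function(A, roster, tau) {
  fam <- closure_family(A)
  keep <- fam$support >= tau
  sets <- fam$sets[keep]
  supp <- fam$support[keep]
  is_max <- maximal_sets(sets)

  zeta <- setNames(integer(length(roster)), as.character(roster))
  for (i in seq_along(sets)) {
    d <- length(sets[[i]]) - 1L
    for (m in sets[[i]]) {
      key <- as.character(m)
      if (d > zeta[[key]]) zeta[[key]] <- d
    }
  }
  max_dim <- if (length(sets) > 0) max(lengths(sets)) - 1L else 0L
  largest <- unique(unlist(sets[lengths(sets) == max_dim + 1L]))

  vertex_weight <- vapply(
    roster,
    function(m) sum(vapply(A, function(a) m %in% a, logical(1))),
    numeric(1)
  )

  list(
    sets = sets, support = supp, is_maximal = is_max,
    zeta = unname(zeta), max_dimension = max_dim,
    largest_vertices = largest,
    vertex_weight = as.integer(vertex_weight)
  )
}

# resolve `current` (id string or one-row tibble) against an expedition table
resolve_current <- function(expeditions, current) {
  if (is.character(current) && length(current) == 1) {
    row <- expeditions[expeditions$expedition_id == current, ]
    if (nrow(row) == 0) abort(sprintf("expedition '%s' not found", current))
  } else if (is.data.frame(current) && nrow(current) == 1) {
    row <- current
  } else {
    abort("`current` must be an expedition_id or a one-row expedition tibble")
  }
  row
}

# intersection family for one expedition against strictly earlier history,
# in climber-id (character) space
current_intersections <- function(expeditions, current) {
  row <- resolve_current(expeditions, current)
  roster <- sort(split_roster(row$roster)[[1]])
  earlier <- expeditions[expeditions$time_index < row$time_index &
    expeditions$expedition_id != row$expedition_id, ]
  A <- lapply(split_roster(earlier$roster), function(h) roster[roster %in% h])
  A <- A[lengths(A) >= 2L]
  list(row = row, roster = roster, A = A)
}

# ---- user-facing operations -------------------------------------------------

#' Build the weighted simplicial complex of one expedition
#'
#' Every previous joint expedition among members of the current roster is a
#' simplex: a subset `s` of the roster (with at least two members) is a
#' simplex iff at least `tau` strictly earlier expeditions contained all of
#' `s`, and its weight is that count of supporting expeditions. Because the
#' count can only fall when `s` grows, the resulting simplex set is closed
#' under inclusion. All roster members are present as 0-simplices; a
#' vertex's weight is its count of earlier expeditions shared with at least
#' one other roster member (0 allowed for vertices only).
#'
#' @param expeditions Expedition tibble (the history is every row with
#'   `time_index` strictly smaller than the current expedition's).
#' @param current Expedition id present in `expeditions`, or a one-row
#'   expedition tibble.
#' @param tau Integer weight threshold, >= 1. At `tau = 1` the complex is
#'   unthresholded.
#' @return A tibble of class `expedition_complex` with one row per simplex:
#'   `expedition_id`, `tau`, `simplex` (sorted climber ids joined by `|`),
#'   `vertices` (list-column), `dimension`, `weight`, `is_maximal`.
#'   Attributes: `roster`, `max_dimension`, `tau`, `expedition_id`.
#' @seealso [influence()], [co_influence()], [filtration_sweep()],
#'   [simplex_census()]
#' @export
#' @examples
#' # three climbers with four previous joint expeditions form a 2-simplex
#' # of weight 4
#' exps <- tibble::tibble(
#'   expedition_id = paste0("e", 1:5),
#'   peak_id = "P1", peak_height = 8849,
#'   time_index = 1:5,
#'   roster = c(rep("i|j|k|x", 4), "i|j|k|y"),
#'   days_to_summit = 40L, n_camps = 4L, n_members = 3L, n_hired = 1L
#' )
#' cx <- build_complex(exps, "e5", tau = 1)
#' cx[cx$simplex == "i|j|k", c("dimension", "weight")]
build_complex <- function(expeditions, current, tau = 1) {
  if (!is.numeric(tau) || length(tau) != 1 || tau < 1 || tau != round(tau)) {
    abort("`tau` must be a single integer >= 1")
  }
  tau <- as.integer(tau)
  ci <- current_intersections(expeditions, current)
  roster_codes <- seq_along(ci$roster)
  A <- lapply(ci$A, function(a) match(a, ci$roster))
  core <- complex_core(A, roster_codes, tau)

  faces <- enumerate_faces(core$sets, core$support)
  vertex_rows <- tibble::tibble(
    vertices = as.list(ci$roster),
    dimension = 0L,
    weight = core$vertex_weight,
    is_maximal = core$zeta == 0L
  )
  face_rows <- tibble::tibble(
    vertices = lapply(faces$sets, function(s) ci$roster[s]),
    dimension = lengths(faces$sets) - 1L,
    weight = faces$weight,
    is_maximal = faces$is_maximal
  )
  out <- dplyr::bind_rows(vertex_rows, face_rows)
  out <- tibble::tibble(
    expedition_id = ci$row$expedition_id,
    tau = tau,
    simplex = vapply(out$vertices, paste, character(1), collapse = "|"),
    vertices = out$vertices,
    dimension = out$dimension,
    weight = out$weight,
    is_maximal = out$is_maximal
  )
  out <- out[order(out$dimension, out$simplex), ]
  structure(
    out,
    roster = ci$roster,
    max_dimension = core$max_dimension,
    tau = tau,
    expedition_id = ci$row$expedition_id,
    class = c("expedition_complex", class(tibble::tibble()))
  )
}

# enumerate all faces (size >= 2) of the kept simplices, deduplicated, with
# weight(face) = support(face) = max support over kept closed supersets
enumerate_faces <- function(sets, support, guard = 2^18) {
  if (length(sets) == 0) {
    return(list(sets = list(), weight = integer(), is_maximal = logical()))
  }
  keep_max <- maximal_sets(sets)
  n_faces <- sum(2^lengths(sets[keep_max]))
  if (n_faces > guard) {
    abort(sprintf(
      "complex would enumerate > %d faces; reduce roster or raise tau", guard
    ))
  }
  seen <- new.env(parent = emptyenv(), hash = TRUE)
  for (s in sets[keep_max]) {
    for (k in 2:length(s)) {
      sub <- combn(s, k, simplify = FALSE)
      for (f in sub) assign(set_key(f), f, envir = seen)
    }
  }
  faces <- as.list(seen)
  faces <- unname(lapply(faces, identity))
  weight <- vapply(faces, function(f) {
    max(support[vapply(sets, function(s) all(f %in% s), logical(1))])
  }, numeric(1))
  max_keys <- vapply(sets[keep_max], set_key, character(1))
  is_max <- vapply(faces, function(f) set_key(f) %in% max_keys, logical(1))
  list(sets = faces, weight = as.integer(weight), is_maximal = is_max)
}

#' Influence of a climber within an expedition complex
#'
#' The influence of a climber is the dimension of the largest simplex
#' containing them: the largest number of current roster members (minus
#' one) that jointly took part in a previous expedition with the climber.
#' A climber with no previous joint expeditions has influence 0.
#'
#' @param complex An [build_complex()] result.
#' @param climber_id A single climber id present in the complex's roster.
#' @return Integer influence, 0 or more.
#' @export
influence <- function(complex, climber_id) {
  roster <- attr(complex, "roster")
  if (!(climber_id %in% roster)) {
    abort(sprintf("climber '%s' is not in the roster", climber_id))
  }
  has <- vapply(complex$vertices, function(v) climber_id %in% v, logical(1))
  max(complex$dimension[has])
}

#' Co-influence of an expedition
#'
#' The arithmetic mean influence over all roster members of the expedition,
#' at the complex's threshold.
#'
#' @inheritParams influence
#' @return A single number in \[0, `max_dimension`\].
#' @export
co_influence <- function(complex) {
  roster <- attr(complex, "roster")
  if (length(roster) == 0) abort("empty roster")
  mean(vapply(roster, function(m) influence(complex, m), numeric(1)))
}

#' Sweep the weight filtration of an expedition
#'
#' Builds the expedition's complex at each threshold in `tau_values`. The
#' complexes are nested: every simplex present at a larger threshold is
#' present at every smaller one, so maximal dimension is non-increasing in
#' `tau`.
#'
#' @inheritParams build_complex
#' @param tau_values Strictly ascending integer thresholds, minimum >= 1.
#' @return Named list of `expedition_complex` objects (`"tau_1"`, ...).
#' @export
filtration_sweep <- function(expeditions, current, tau_values = 1:4) {
  if (any(diff(tau_values) <= 0) || tau_values[1] < 1) {
    abort("`tau_values` must be strictly ascending with minimum >= 1")
  }
  out <- lapply(tau_values, function(t) build_complex(expeditions, current, t))
  names(out) <- paste0("tau_", tau_values)
  out
}

#' Census of simplices by dimension
#'
#' Counts the `k`-simplices of the complex for every dimension `k`,
#' including the 0-simplices (roster members).
#'
#' @inheritParams influence
#' @return Tibble with `dimension` and `count`; the counts sum to the total
#'   number of simplices in the complex.
#' @export
simplex_census <- function(complex) {
  complex |>
    dplyr::count(.data$dimension, name = "count") |>
    dplyr::arrange(.data$dimension)
}

#' Influence of every climber in every expedition of a cohort
#'
#' Computes, for each (climber, expedition) pair, the influence (maximal
#' simplicial dimension) at threshold `tau`, using each expedition's
#' strictly earlier history. This is the cohort-scale companion of
#' [influence()] and avoids enumerating faces.
#'
#' @param expeditions Expedition tibble.
#' @param tau Integer weight threshold >= 1.
#' @return Tibble with `expedition_id`, `climber_id`, `influence`.
#' @export
influence_table <- function(expeditions, tau = 1) {
  stats <- cohort_complex_stats(expeditions, tau_values = tau)
  dplyr::select(
    stats$influence[stats$influence$tau == tau, ],
    "expedition_id", "climber_id", "influence"
  )
}

# cohort-wide per-expedition, per-threshold statistics, computing the
# intersection structure once per expedition and thresholding cheaply
cohort_complex_stats <- function(expeditions, tau_values = 1:4) {
  idx <- cohort_index(expeditions)
  inter <- cohort_intersections(idx)
  n_exp <- length(idx$rosters)

  exp_rows <- vector("list", n_exp * length(tau_values))
  inf_rows <- vector("list", n_exp * length(tau_values))
  max_rows <- vector("list", n_exp * length(tau_values))
  k <- 0L
  for (e in seq_len(n_exp)) {
    roster <- idx$rosters[[e]]
    fam <- closure_family(inter[[e]])
    for (t in tau_values) {
      keep <- fam$support >= t
      sets <- fam$sets[keep]
      supp <- fam$support[keep]
      is_max <- maximal_sets(sets)
      max_dim <- if (length(sets) > 0) max(lengths(sets)) - 1L else 0L
      largest <- unique(unlist(sets[lengths(sets) == max_dim + 1L]))

      zeta <- integer(length(roster))
      for (i in seq_along(sets)) {
        d <- length(sets[[i]]) - 1L
        pos <- match(sets[[i]], roster)
        zeta[pos] <- pmax(zeta[pos], d)
      }
      mean_max_dim <- if (any(is_max)) {
        mean(lengths(sets[is_max]) - 1)
      } else {
        NA_real_
      }

      k <- k + 1L
      exp_rows[[k]] <- tibble::tibble(
        expedition_id = idx$exp_id[e],
        tau = t,
        max_dimension = max_dim,
        n_maximal = sum(is_max),
        mean_max_simplex_dim = mean_max_dim
      )
      inf_rows[[k]] <- tibble::tibble(
        expedition_id = idx$exp_id[e],
        tau = t,
        climber_id = idx$climbers[roster],
        influence = zeta,
        in_largest = roster %in% largest & max_dim > 0L
      )
      if (any(is_max)) {
        max_rows[[k]] <- tibble::tibble(
          expedition_id = idx$exp_id[e],
          tau = t,
          simplex = vapply(
            sets[is_max],
            function(s) paste(idx$climbers[s], collapse = "|"), character(1)
          ),
          dimension = lengths(sets[is_max]) - 1L,
          weight = supp[is_max]
        )
      }
    }
  }
  list(
    by_expedition = dplyr::bind_rows(exp_rows),
    influence = dplyr::bind_rows(inf_rows),
    maximal = dplyr::bind_rows(max_rows)
  )
}
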