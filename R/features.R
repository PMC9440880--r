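#' Names of the six binary personal features
#' @export
personal_feature_names <- c(
  "age_below_median", "sex_male", "hired_block",
  "experience_8000m", "oxygen_ascent", "oxygen_descent"
)

#' Binary personal-feature incidence of every record
#'
#' Encodes each climber-expedition record as six binary features: age
#' below the cohort median, male, membership in the hired/sherpa identity
#' block (the discriminative nationality axis), any prior expedition on a
#' peak of at least 8000 m (recomputed from the logged history, not
#' trusted from the input column), oxygen use while ascending, and while
#' descending.
#'
#' @param records Climber-expedition record tibble.
#' @param expeditions Expedition tibble (for peak heights and temporal
#'   order of the experience recomputation).
#' @param median_age Age split point; default the median age over the
#'   records analyzed.
#' @return Tibble with `climber_id`, `expedition_id`, `success` (outcome
#'   `summit_success`), and the six 0/1 feature columns.
#' @export
feature_incidence <- function(records, expeditions, median_age = NULL) {
  median_age <- median_age %||% median(records$age)
  idx <- cohort_index(expeditions)
  heights <- expeditions$peak_height[
    match(idx$exp_id, expeditions$expedition_id)
  ]
  high_count <- integer(length(idx$climbers))
  rows <- vector("list", length(idx$rosters))
  for (e in seq_along(idx$rosters)) {
    roster <- idx$rosters[[e]]
    rows[[e]] <- tibble::tibble(
      climber_id = idx$climbers[roster],
      expedition_id = idx$exp_id[e],
      prior_8000m = high_count[roster]
    )
    if (heights[e] >= 8000) high_count[roster] <- high_count[roster] + 1L
  }
  prior_high <- dplyr::bind_rows(rows)

  records |>
    dplyr::left_join(prior_high, by = c("climber_id", "expedition_id")) |>
    dplyr::transmute(
      climber_id = .data$climber_id,
      expedition_id = .data$expedition_id,
      success = .data$outcome == "summit_success",
      age_below_median = as.integer(.data$age < median_age),
      sex_male = as.integer(.data$sex == "male"),
      hired_block = as.integer(.data$is_hired),
      experience_8000m = as.integer(.data$prior_8000m > 0),
      oxygen_ascent = as.integer(.data$oxygen_ascent),
      oxygen_descent = as.integer(.data$oxygen_descent)
    )
}

#' Per-expedition bipartite climber-feature matrices
#'
#' Builds, for every expedition with at least `min_members` climbers, the
#' binary climber-by-feature incidence matrices of its successful and
#' unsuccessful members (success meaning summit without death; the safe
#' descent criterion of the feature analysis).
#'
#' @inheritParams feature_incidence
#' @param min_members Expeditions with fewer climbers are excluded
#'   (default 12).
#' @return Tibble with one row per retained expedition: `expedition_id`,
#'   `n_members`, `n_success`, `n_failure`, and list-columns `P_success`,
#'   `P_failure` holding the binary matrices (possibly with zero rows).
#'   Attributes: `median_age`, `skipped` (ids of excluded expeditions).
#' @export
build_feature_matrix <- function(records, expeditions, min_members = 12,
                                 median_age = NULL) {
  inc <- feature_incidence(records, expeditions, median_age = median_age)
  sizes <- inc |> dplyr::count(.data$expedition_id, name = "n_members")
  keep <- sizes$expedition_id[sizes$n_members >= min_members]
  skipped <- setdiff(sizes$expedition_id, keep)

  as_matrix <- function(d) {
    m <- as.matrix(d[, personal_feature_names])
    rownames(m) <- d$climber_id
    m
  }
  rows <- lapply(keep, function(eid) {
    d <- inc[inc$expedition_id == eid, ]
    tibble::tibble(
      expedition_id = eid,
      n_members = nrow(d),
      n_success = sum(d$success),
      n_failure = sum(!d$success),
      P_success = list(as_matrix(d[d$success, ])),
      P_failure = list(as_matrix(d[!d$success, ]))
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "median_age") <- median_age %||% median(records$age)
  attr(out, "skipped") <- skipped
  out
}

#' Project a bipartite climber-feature matrix into feature space
#'
#' Computes the feature co-occurrence matrix `I = t(P) %*% P`: the entry
#' `(f, g)` counts the climbers expressing both features. The diagonal
#' (feature self-counts) is zeroed so that prevalence alone cannot
#' dominate the centrality computed downstream.
#'
#' @param P Binary climbers-by-features matrix.
#' @return Symmetric `d x d` numeric matrix with zero diagonal.
#' @export
project_features <- function(P) {
  P <- as.matrix(P)
  I <- crossprod(P)
  diag(I) <- 0
  I
}

#' Eigenvector centrality of a nonnegative symmetric matrix
#'
#' Dominant eigenvector by power iteration started from the uniform
#' positive vector, with a positive diagonal shift (which leaves the
#' eigenvectors unchanged) so the iteration also converges on bipartite
#' graphs whose spectrum is symmetric. Convergence when successive
#' iterates differ by less than `tol` in Euclidean norm; the result is
#' nonnegative with unit Euclidean norm.
#'
#' @param I Symmetric nonnegative matrix.
#' @param tol Convergence tolerance (default 1e-10).
#' @param max_iter Iteration cap (default 1e5).
#' @return Numeric vector of centralities (named after `I`'s columns).
#'   When `I` is the zero matrix the uniform unit vector is returned with
#'   attribute `degenerate = TRUE`.
#' @export
eigenvector_centrality <- function(I, tol = 1e-10, max_iter = 1e5) {
  I <- as.matrix(I)
  if (any(I < 0)) abort("`I` must be nonnegative")
  if (max(abs(I - t(I))) > 1e-8) abort("`I` must be symmetric")
  d <- nrow(I)
  v <- rep(1 / sqrt(d), d)
  if (all(I == 0)) {
    return(structure(setNames(v, colnames(I)), degenerate = TRUE))
  }
  shift <- max(rowSums(I)) # Gershgorin bound: I + shift * Id is PSD
  for (iter in seq_len(max_iter)) {
    w <- drop(I %*% v) + shift * v
    w <- w / sqrt(sum(w^2))
    if (sqrt(sum((w - v)^2)) < tol) {
      v <- w
      break
    }
    v <- w
  }
  v <- pmax(v, 0)
  v <- v / sqrt(sum(v^2))
  setNames(v, colnames(I))
}

#' Compare feature centralities of successful and unsuccessful climbers
#'
#' For every retained expedition, projects the success-group and
#' failure-group bipartite matrices into feature space and computes their
#' eigenvector centralities; then reports per-feature means and standard
#' errors across expeditions for each group, ordered by increasing
#' difference (success minus no-success). Large positive differences mark
#' features overrepresented among successful climbers.
#'
#' @param feature_matrices A [build_feature_matrix()] result.
#' @return Tibble of class `centrality_comparison`: `feature`,
#'   `mean_success`, `se_success`, `mean_no_success`, `se_no_success`,
#'   `difference`, sorted by increasing difference. Expeditions with an
#'   empty group contribute only to the other group's statistics.
#' @export
centrality_comparison <- function(feature_matrices) {
  if (nrow(feature_matrices) < 2) {
    warn("fewer than 2 expeditions contribute; standard errors undefined")
  }
  cent <- function(P) {
    if (nrow(P) == 0) {
      return(NULL)
    }
    eigenvector_centrality(project_features(P))
  }
  suc <- do.call(rbind, lapply(feature_matrices$P_success, cent))
  fail <- do.call(rbind, lapply(feature_matrices$P_failure, cent))
  col_se <- function(m) {
    if (is.null(m) || nrow(m) < 2) {
      return(rep(NA_real_, length(personal_feature_names)))
    }
    apply(m, 2, sd) / sqrt(nrow(m))
  }
  col_mean <- function(m) {
    if (is.null(m)) {
      return(rep(NA_real_, length(personal_feature_names)))
    }
    colMeans(m)
  }
  out <- tibble::tibble(
    feature = personal_feature_names,
    mean_success = unname(col_mean(suc)),
    se_success = unname(col_se(suc)),
    mean_no_success = unname(col_mean(fail)),
    se_no_success = unname(col_se(fail)),
    difference = unname(col_mean(suc)) - unname(col_mean(fail))
  ) |>
    dplyr::arrange(.data$difference)
  structure(
    out,
    n_expeditions = nrow(feature_matrices),
    class = c("centrality_comparison", class(tibble::tibble()))
  )
}

#' Correlate expedition-wide factors with success rate
#'
#' The four expedition-wide factors are the number of days from base camp
#' to summit, the number of camps above base camp, the expedition size
#' (members plus hired personnel), and the ratio of paying members to
#' hired personnel (undefined when no personnel were hired). Each is
#' correlated with the expedition success rate via [pearson_cor()].
#'
#' @param expeditions Expedition tibble.
#' @param success_rates An [expedition_success_rates()] result.
#' @return Tibble `factor`, `estimate`, `p_value`, `n`, `degenerate`.
#' @export
factor_correlations <- function(expeditions, success_rates) {
  dat <- dplyr::left_join(
    expeditions,
    dplyr::select(success_rates, "expedition_id", "success_rate"),
    by = "expedition_id"
  )
  if (nrow(dat) < 3) abort("at least 3 expeditions required")
  factors <- list(
    days_to_summit = dat$days_to_summit,
    n_camps = dat$n_camps,
    expedition_size = dat$n_members + dat$n_hired,
    members_to_hired_ratio = ifelse(
      dat$n_hired > 0, dat$n_members / dat$n_hired, NA_real_
    )
  )
  purrr::imap(factors, function(x, nm) {
    dplyr::mutate(pearson_cor(x, dat$success_rate), factor = nm, .before = 1)
  }) |>
    dplyr::bind_rows()
}
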