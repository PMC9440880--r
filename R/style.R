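#' Pearson correlation with its t-based p-value
#'
#' Thin wrapper over the product-moment correlation with the usual two-sided
#' p-value from the t transform on `n - 2` degrees of freedom, returning an
#' explicit undefined marker instead of failing on degenerate input.
#'
#' @param x,y Equal-length numeric vectors; pairs with missing values are
#'   dropped.
#' @return One-row tibble `estimate`, `p_value`, `n`, `degenerate`
#'   (`TRUE` when fewer than 3 complete pairs or zero variance, in which
#'   case the estimate is `NA`).
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3 || sd(x) == 0 || sd(y) == 0) {
    return(tibble::tibble(
      estimate = NA_real_, p_value = NA_real_,
      n = length(x), degenerate = TRUE
    ))
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(
    estimate = unname(ct$estimate), p_value = ct$p.value,
    n = length(x), degenerate = FALSE
  )
}

#' Success rate of climbers outside the largest simplex
#'
#' Outsiders are the roster members not contained in any simplex attaining
#' the complex's maximal dimension (under ties, the union of all
#' maximum-dimension simplices is excluded). The rate is the fraction of
#' outsiders whose outcome is `summit_success`.
#'
#' @param complex An [build_complex()] result.
#' @param records Climber-expedition records covering the expedition.
#' @return A fraction in \[0, 1\], or `NA` when there are no outsiders.
#' @export
outsider_success_rate <- function(complex, records) {
  roster <- attr(complex, "roster")
  max_dim <- attr(complex, "max_dimension")
  largest <- unique(unlist(
    complex$vertices[complex$dimension == max_dim & complex$dimension > 0]
  ))
  outsiders <- setdiff(roster, largest)
  if (max_dim == 0 || length(outsiders) == 0) {
    return(NA_real_)
  }
  rec <- records[records$expedition_id == attr(complex, "expedition_id"), ]
  mean(rec$outcome[rec$climber_id %in% outsiders] == "summit_success")
}

#' Expedition-style curves across the weight filtration
#'
#' Classifies expeditions on the polarized-to-cooperative spectrum: for
#' every threshold it computes each expedition's maximal simplicial
#' dimension, the mean dimension of its maximal simplices, its overall
#' success rate, and the success rate of members outside the largest
#' simplex; per dimension it averages outsider success (with standard
#' errors); and per threshold it correlates expedition success rate with
#' mean maximal-simplex dimension. Expeditions with no simplex of dimension
#' greater than zero are excluded. A cooperative cohort shows outsider
#' success rising with maximal dimension and a strong low-threshold
#' correlation; a polarized cohort shows flat-to-falling outsider success.
#'
#' @param records Climber-expedition record tibble.
#' @param expeditions Expedition tibble.
#' @param tau_values Ascending integer thresholds (default 1:4).
#' @param min_expeditions Minimum expeditions at a threshold for the
#'   correlation to be reported (default 3).
#' @return List of class `style_curves`: `by_expedition` (per expedition
#'   and threshold), `by_dimension` (outsider success by maximal dimension,
#'   with standard errors), `by_tau` (mean maximal dimension and the
#'   success-rate correlation per threshold).
#' @export
style_curves <- function(records, expeditions, tau_values = 1:4,
                         min_expeditions = 3) {
  stats <- cohort_complex_stats(expeditions, tau_values = tau_values)
  rates <- expedition_success_rates(records, expeditions)
  outcomes <- dplyr::select(records, "climber_id", "expedition_id", "outcome")

  outsider <- stats$influence |>
    dplyr::inner_join(outcomes, by = c("climber_id", "expedition_id")) |>
    dplyr::group_by(.data$expedition_id, .data$tau) |>
    dplyr::summarise(
      n_outsiders = sum(!.data$in_largest),
      outsider_success_rate = ifelse(
        sum(!.data$in_largest) > 0,
        mean(.data$outcome[!.data$in_largest] == "summit_success"),
        NA_real_
      ),
      .groups = "drop"
    )

  by_expedition <- stats$by_expedition |>
    dplyr::filter(.data$max_dimension > 0) |>
    dplyr::left_join(outsider, by = c("expedition_id", "tau")) |>
    dplyr::left_join(
      dplyr::select(rates, "expedition_id", "success_rate"),
      by = "expedition_id"
    )

  by_dimension <- by_expedition |>
    dplyr::filter(!is.na(.data$outsider_success_rate)) |>
    dplyr::group_by(.data$tau, .data$max_dimension) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_outsider_success = mean(.data$outsider_success_rate),
      se_outsider_success = ifelse(
        dplyr::n() > 1,
        sd(.data$outsider_success_rate) / sqrt(dplyr::n()), NA_real_
      ),
      .groups = "drop"
    )

  by_tau <- by_expedition |>
    dplyr::group_by(.data$tau) |>
    dplyr::summarise(
      n_expeditions = dplyr::n(),
      mean_max_dimension = mean(.data$max_dimension),
      pcc = list(
        if (dplyr::n() >= min_expeditions) {
          pearson_cor(.data$success_rate, .data$mean_max_simplex_dim)
        } else {
          tibble::tibble(
            estimate = NA_real_, p_value = NA_real_,
            n = dplyr::n(), degenerate = TRUE
          )
        }
      ),
      .groups = "drop"
    ) |>
    tidyr::unnest("pcc") |>
    dplyr::rename(pcc_r = "estimate", pcc_p = "p_value") |>
    dplyr::select(
      "tau", "n_expeditions", "mean_max_dimension",
      "pcc_r", "pcc_p", "degenerate"
    )

  structure(
    list(
      by_expedition = by_expedition,
      by_dimension = by_dimension,
      by_tau = by_tau
    ),
    class = "style_curves"
  )
}

#' @export
print.style_curves <- function(x, ...) {
  cat("<style_curves>\n")
  print(x$by_tau)
  invisible(x)
}

#' @method tidy style_curves
#' @export
tidy.style_curves <- function(x, ...) x$by_tau

#' @method glance style_curves
#' @export
glance.style_curves <- function(x, ...) {
  tibble::tibble(
    n_tau = nrow(x$by_tau),
    n_expeditions_tau1 = x$by_tau$n_expeditions[x$by_tau$tau == min(x$by_tau$tau)],
    pcc_r_tau1 = x$by_tau$pcc_r[x$by_tau$tau == min(x$by_tau$tau)]
  )
}
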