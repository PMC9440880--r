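#' Domain vocabularies
#'
#' Levels of the categorical fields carried by climber-expedition records:
#' the three outcomes of a climb, the four failure-cause categories (plus
#' `"none"`, reserved for successful records), and sex.
#'
#' @format Character vectors.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
outcome_levels <- c("summit_success", "no_summit", "death")

#' @rdname vocabularies
#' @export
failure_cause_levels <- c("altitude", "logistics", "fatigue", "accident", "none")

#' @rdname vocabularies
#' @export
sex_levels <- c("male", "female")

# column -> readr collector, shared by the reader and the validator
climber_schema <- function() {
  readr::cols(
    climber_id = readr::col_character(),
    expedition_id = readr::col_character(),
    age = readr::col_integer(),
    sex = readr::col_character(),
    nationality = readr::col_character(),
    is_hired = readr::col_logical(),
    oxygen_ascent = readr::col_logical(),
    oxygen_descent = readr::col_logical(),
    experience_8000m = readr::col_integer(),
    outcome = readr::col_character(),
    failure_cause = readr::col_character()
  )
}

expedition_schema <- function() {
  readr::cols(
    expedition_id = readr::col_character(),
    peak_id = readr::col_character(),
    peak_height = readr::col_double(),
    time_index = readr::col_integer(),
    roster = readr::col_character(),
    days_to_summit = readr::col_integer(),
    n_camps = readr::col_integer(),
    n_members = readr::col_integer(),
    n_hired = readr::col_integer()
  )
}

sniff_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

read_table_checked <- function(path, schema, what) {
  if (!file.exists(path)) {
    abort(sprintf("%s file not found: %s", what, path))
  }
  delim <- sniff_delim(path)
  have <- strsplit(readLines(path, n = 1L), delim, fixed = TRUE)[[1]]
  need <- names(schema$cols)
  missing <- setdiff(need, have)
  if (length(missing) > 0) {
    abort(sprintf(
      "%s table is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  readr::read_delim(
    path,
    delim = delim, col_types = schema,
    locale = readr::locale(encoding = "UTF-8"), progress = FALSE
  )
}

check_enum <- function(x, levels, column) {
  bad <- which(!(x %in% levels) | is.na(x))
  if (length(bad) > 0) {
    abort(sprintf(
      "unknown %s token '%s' at row %d (allowed: %s)",
      column, as.character(x[bad[1]]), bad[1], paste(levels, collapse = ", ")
    ))
  }
  invisible(x)
}

split_roster <- function(roster) strsplit(roster, "|", fixed = TRUE)

#' Validate a climber/expedition table pair
#'
#' Checks enum tokens, record uniqueness, referential integrity
#' (every record's `expedition_id` exists in the expedition table), roster
#' consistency between the two tables, and the coupling between `outcome`
#' and `failure_cause` (`"none"` iff `summit_success`).
#'
#' @param records Climber-expedition record tibble.
#' @param expeditions Expedition tibble.
#' @return Invisibly, `list(records, expeditions)`; errors describe the
#'   offending column or row otherwise.
#' @export
validate_cohort <- function(records, expeditions) {
  check_enum(records$outcome, outcome_levels, "outcome")
  check_enum(records$failure_cause, failure_cause_levels, "failure_cause")
  check_enum(records$sex, sex_levels, "sex")
  if (any(records$age < 0, na.rm = TRUE)) abort("age must be >= 0")
  if (any(records$experience_8000m < 0, na.rm = TRUE)) {
    abort("experience_8000m must be >= 0")
  }

  key <- paste(records$climber_id, records$expedition_id, sep = "\r")
  if (anyDuplicated(key)) {
    abort(sprintf(
      "duplicate (climber_id, expedition_id) pair at row %d",
      which(duplicated(key))[1]
    ))
  }

  dangling <- which(!(records$expedition_id %in% expeditions$expedition_id))
  if (length(dangling) > 0) {
    abort(sprintf(
      "record row %d references unknown expedition_id '%s'",
      dangling[1], records$expedition_id[dangling[1]]
    ))
  }

  bad_cause <- which(
    (records$outcome == "summit_success") != (records$failure_cause == "none")
  )
  if (length(bad_cause) > 0) {
    abort(sprintf(
      "failure_cause must be 'none' iff outcome is 'summit_success' (row %d)",
      bad_cause[1]
    ))
  }

  if (anyDuplicated(expeditions$expedition_id)) {
    abort("duplicate expedition_id in expedition table")
  }
  if (anyDuplicated(expeditions$time_index)) {
    abort("time_index must be unique per expedition (a strict total order)")
  }
  rosters <- split_roster(expeditions$roster)
  if (any(lengths(rosters) == 0)) abort("every expedition roster must be nonempty")

  rec_sets <- split(records$climber_id, records$expedition_id)
  for (i in seq_len(nrow(expeditions))) {
    eid <- expeditions$expedition_id[i]
    got <- sort(rec_sets[[eid]] %||% character())
    if (!identical(sort(rosters[[i]]), got)) {
      abort(sprintf(
        "roster of expedition '%s' does not match its climber records", eid
      ))
    }
  }
  invisible(list(records = records, expeditions = expeditions))
}

#' Read a climber/expedition cohort from delimited files
#'
#' Reads the two flat tables of a cohort (climber-expedition records and
#' expedition records) from CSV or TSV (delimiter sniffed from the header
#' line), types and validates them, and cross-references rosters.
#'
#' @param path_climbers Path to the climber-expedition record table.
#' @param path_expeditions Path to the expedition table.
#' @return `list(records, expeditions)` of validated tibbles.
#' @seealso [write_cohort()], [validate_cohort()]
#' @export
#' @examples
#' cohort <- generate_cohort(generator_config(
#'   n_climbers = 20, n_expeditions = 10, rng_seed = 1
#' ))
#' dir <- tempfile(); dir.create(dir)
#' paths <- write_cohort(cohort$records, cohort$expeditions, dir)
#' back <- read_cohort(paths$climbers, paths$expeditions)
#' nrow(back$records)
read_cohort <- function(path_climbers, path_expeditions) {
  records <- read_table_checked(path_climbers, climber_schema(), "climber record")
  expeditions <- read_table_checked(path_expeditions, expedition_schema(), "expedition")
  validate_cohort(records, expeditions)
  list(records = records, expeditions = expeditions)
}

#' Write a cohort to CSV
#'
#' @param records,expeditions Tibbles as returned by [generate_cohort()] or
#'   [read_cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, `list(climbers =, expeditions =)` file paths.
#' @export
write_cohort <- function(records, expeditions, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pc <- file.path(dir, "records.csv")
  pe <- file.path(dir, "expeditions.csv")
  readr::write_csv(records, pc, progress = FALSE)
  readr::write_csv(expeditions, pe, progress = FALSE)
  invisible(list(climbers = pc, expeditions = pe))
}

#' Per-expedition summit success rates
#'
#' The success rate of an expedition is the fraction of its roster whose
#' outcome is `summit_success`.
#'
#' @param records Climber-expedition record tibble.
#' @param expeditions Expedition tibble.
#' @return Tibble with `expedition_id`, `n_members`, `success_rate` in
#'   \[0, 1\], one row per expedition.
#' @export
expedition_success_rates <- function(records, expeditions) {
  rosters <- split_roster(expeditions$roster)
  if (any(lengths(rosters) == 0)) abort("empty roster")
  out <- records |>
    dplyr::group_by(.data$expedition_id) |>
    dplyr::summarise(
      n_members = dplyr::n(),
      success_rate = mean(.data$outcome == "summit_success"),
      .groups = "drop"
    )
  missing <- setdiff(expeditions$expedition_id, out$expedition_id)
  if (length(missing) > 0) {
    abort(sprintf(
      "no climber records for expedition '%s'; records must cover all rosters",
      missing[1]
    ))
  }
  dplyr::left_join(
    dplyr::select(expeditions, "expedition_id"), out, by = "expedition_id"
  )
}
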