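#' @name behaviour-qc
#' @title Valid wear-day quality control for thigh-worn accelerometer days
#'
#' @description
#' Day-level activPAL-style summaries are screened with the standard
#' valid-waking-wear criteria before participant averaging: at least 10 h
#' (600 min) of waking wear, at least 500 step events (one event = two
#' steps), and no single behaviour occupying more than 95% of wear time.
#' Participants contribute only their valid days, and need a minimum
#' number of them (default 4) to be included at all.
NULL

#' Screen day records against the valid wear-day criteria
#'
#' @param days data frame with columns `wear_min`, `step_events`,
#'   `sit_min`, `stand_min`, `step_min` (plus any id columns, which are
#'   carried through).
#' @param min_wear_min minimum waking wear, minutes (default 600 = 10 h).
#' @param min_step_events minimum activPAL step events (default 500,
#'   i.e. 1000 steps).
#' @param max_single_behaviour maximum fraction of the denominator any one
#'   behaviour may occupy (default 0.95).
#' @param denominator denominator of the single-behaviour rule:
#'   `"wear"` (default) uses `wear_min`, `"behaviour"` uses
#'   `sit + stand + step`.
#' @return `days` with two added columns: logical `valid`, and character
#'   `reasons` (`""` for valid days, otherwise `;`-separated codes from
#'   `wear<600min`, `events<500`, `monobehaviour>95%`). A day with zero
#'   wear is invalid, never an error.
#' @examples
#' d <- data.frame(wear_min = c(720, 540), step_events = c(800, 800),
#'                 sit_min = c(500, 300), stand_min = c(150, 180),
#'                 step_min = c(70, 60))
#' is_valid_day(d)
#' @export
is_valid_day <- function(days,
                         min_wear_min = 600,
                         min_step_events = 500,
                         max_single_behaviour = 0.95,
                         denominator = c("wear", "behaviour")) {
  denominator <- match.arg(denominator)
  need <- c("wear_min", "step_events", "sit_min", "stand_min", "step_min")
  miss <- setdiff(need, names(days))
  if (length(miss)) {
    stop("day table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(days[need] < 0, na.rm = TRUE)) {
    stop("day records must be nonnegative", call. = FALSE)
  }
  denom <- if (denominator == "wear") days$wear_min else {
    days$sit_min + days$stand_min + days$step_min
  }
  max_part <- pmax(days$sit_min, days$stand_min, days$step_min)
  short_wear <- days$wear_min < min_wear_min
  low_steps <- days$step_events < min_step_events
  # zero-wear days count as monobehaviour failures only if wear itself fails
  mono <- ifelse(denom > 0, max_part / denom > max_single_behaviour, FALSE)
  reasons <- character(nrow(days))
  code <- function(flag, txt) ifelse(flag, txt, NA_character_)
  tags <- cbind(code(short_wear, sprintf("wear<%gmin", min_wear_min)),
                code(low_steps, sprintf("events<%g", min_step_events)),
                code(mono, sprintf("monobehaviour>%g%%", 100 * max_single_behaviour)))
  reasons <- apply(tags, 1L, function(r) paste(r[!is.na(r)], collapse = ";"))
  out <- tibble::as_tibble(days)
  out$valid <- !(short_wear | low_steps | mono)
  out$reasons <- reasons
  out
}

#' Average valid days into a participant-level composition
#'
#' Arithmetic mean of each behaviour and of wear time over a participant's
#' valid days. Participants with fewer than `min_valid_days` valid days
#' are kept in the output but flagged `included = FALSE`; an empty group
#' yields an excluded record, not an error.
#'
#' @param days data frame of day records with a `participant_id` column
#'   and the columns required by [is_valid_day()].
#' @param min_valid_days minimum valid days for inclusion (default 4).
#' @inheritParams is_valid_day
#' @return Tibble with one row per participant: `participant_id`,
#'   `sit_min`, `stand_min`, `step_min`, `total_min` (sum of the three
#'   behaviour means), `wear_min`, `n_days`, `n_valid_days`, `included`.
#' @export
participant_average <- function(days, min_valid_days = 4,
                                min_wear_min = 600,
                                min_step_events = 500,
                                max_single_behaviour = 0.95,
                                denominator = c("wear", "behaviour")) {
  if (!"participant_id" %in% names(days)) {
    stop("day table needs a participant_id column", call. = FALSE)
  }
  flagged <- is_valid_day(days,
                          min_wear_min = min_wear_min,
                          min_step_events = min_step_events,
                          max_single_behaviour = max_single_behaviour,
                          denominator = denominator)
  out <- flagged |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      sit_min = mean(.data$sit_min[.data$valid]),
      stand_min = mean(.data$stand_min[.data$valid]),
      step_min = mean(.data$step_min[.data$valid]),
      wear_min = mean(.data$wear_min[.data$valid]),
      n_days = dplyr::n(),
      n_valid_days = sum(.data$valid),
      .groups = "drop") |>
    dplyr::mutate(
      total_min = .data$sit_min + .data$stand_min + .data$step_min,
      included = .data$n_valid_days >= min_valid_days) |>
    dplyr::relocate("total_min", .after = "step_min")
  out
}

#' Read a day-level CSV
#'
#' Expects header columns `participant_id, date, wear_min, sit_min,
#' stand_min, step_min, step_events`.
#' @param path file path.
#' @return Tibble of day records.
#' @export
read_day_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write participant-level averages and an exclusion log
#'
#' @param participants output of [participant_average()].
#' @param path CSV path for included participants.
#' @param exclusion_path optional CSV path for the excluded participants
#'   (with valid-day counts).
#' @return `participants`, invisibly.
#' @export
write_participant_csv <- function(participants, path, exclusion_path = NULL) {
  utils::write.csv(participants[participants$included, , drop = FALSE],
                   path, row.names = FALSE)
  if (!is.null(exclusion_path)) {
    excl <- participants[!participants$included,
                         c("participant_id", "n_days", "n_valid_days")]
    utils::write.csv(excl, exclusion_path, row.names = FALSE)
  }
  invisible(participants)
}
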