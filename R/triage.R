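#' @title Triage accuracy and scenario-standardized speed
#' @description
#' Triage performance is scored from per-participant event logs: tables
#' with columns `participant_id`, `scenario_id`, `patient_id`,
#' `assigned_color`, `t_ms`. Accuracy is the proportion of roster patients
#' assigned their true colour (untriaged patients count as incorrect; when
#' a patient is re-triaged the last assignment wins). Speed is the time to
#' the last triage event, standardized by the cohort mean of the same
#' scenario so that scenarios of different length contribute equally.
#' @name triage
NULL

#' Accuracy of one scenario log
#'
#' @param log Event log rows for a single participant and scenario.
#' @param scenario The matching `mci_scenario` (nonempty roster).
#' @return Proportion correct in `[0, 1]`.
#' @export
scenario_accuracy <- function(log, scenario) {
  roster <- scenario$roster
  if (!nrow(roster)) stop_input("scenario roster is empty")
  unknown <- setdiff(unique(log$patient_id), roster$patient_id)
  if (length(unknown)) {
    stop_input(paste0(
      "event log references unknown patient id(s): ",
      paste(unknown, collapse = ", ")
    ))
  }
  if (!nrow(log)) return(0)
  last <- log |>
    dplyr::arrange(.data$t_ms) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::slice_tail(n = 1) |>
    dplyr::ungroup()
  joined <- dplyr::left_join(
    roster[, c("patient_id", "true_color")], last[, c("patient_id", "assigned_color")],
    by = "patient_id"
  )
  correct <- !is.na(joined$assigned_color) &
    as.character(joined$assigned_color) == as.character(joined$true_color)
  sum(correct) / nrow(roster)
}

#' Participant-level accuracy
#'
#' Unweighted mean of the per-scenario accuracies. By default a missing
#' scenario makes the participant's accuracy missing (per-measure
#' exclusion); set `na_rm = TRUE` to average the available scenarios
#' instead.
#'
#' @param per_scenario Numeric vector of per-scenario proportions.
#' @param na_rm Average over non-missing scenarios instead of propagating.
#' @return Proportion in `[0, 1]` (or `NA`).
#' @export
participant_accuracy <- function(per_scenario, na_rm = FALSE) {
  mean(per_scenario, na.rm = na_rm)
}

#' Triage completion time of one scenario log
#'
#' Time from scenario start to the completion of triaging the last
#' patient, in seconds.
#'
#' @param log Event log rows for one participant and scenario.
#' @return Seconds, or `NA` with a warning for an empty log.
#' @export
triage_time <- function(log) {
  if (!nrow(log)) {
    warn("empty triage log: completion time is missing")
    return(NA_real_)
  }
  max(log$t_ms) / 1000
}

#' Scenario-standardized triage speed
#'
#' Each completion time is divided by the cohort mean time of the same
#' scenario (computed over the non-missing cells of that scenario,
#' including the participant's own), and the standardized values are then
#' averaged per participant. Values below 1 mean faster than the cohort
#' average. After standardization every scenario column has mean exactly 1,
#' and rescaling all raw times by a constant leaves the result unchanged.
#'
#' @param times Tibble with columns `participant_id`, `scenario_id`,
#'   `time_s` (missing cells may be absent or `NA`).
#' @param na_rm Average a participant's available scenarios when some are
#'   missing, instead of propagating `NA` (default propagates, mirroring
#'   per-measure exclusion).
#' @return Tibble with `participant_id` and `std_speed`.
#' @export
standardize_speed <- function(times, na_rm = FALSE) {
  all_missing <- times |>
    dplyr::group_by(.data$scenario_id) |>
    dplyr::summarise(gone = all(is.na(.data$time_s)), .groups = "drop")
  if (any(all_missing$gone)) {
    warn(paste0(
      "dropping scenario column(s) with no observed times: ",
      paste(all_missing$scenario_id[all_missing$gone], collapse = ", ")
    ))
    times <- dplyr::anti_join(
      times, dplyr::filter(all_missing, .data$gone),
      by = "scenario_id"
    )
  }
  counts <- times |>
    dplyr::group_by(.data$scenario_id) |>
    dplyr::summarise(n = sum(!is.na(.data$time_s)), .groups = "drop")
  if (any(counts$n < 2)) {
    stop_input("each scenario needs at least 2 observed times to standardize")
  }
  times |>
    dplyr::group_by(.data$scenario_id) |>
    dplyr::mutate(rel = .data$time_s / mean(.data$time_s, na.rm = TRUE)) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(std_speed = mean(.data$rel, na.rm = na_rm), .groups = "drop")
}

#' Score triage logs for a whole cohort
#'
#' Computes per-scenario accuracy and completion time for every
#' participant, then the participant-level accuracy mean and the
#' scenario-standardized speed.
#'
#' @param events Event-log tibble for the cohort.
#' @param scenarios Scenario list (default the bundled set).
#' @param na_rm Passed to [participant_accuracy()] and
#'   [standardize_speed()].
#' @return List with `per_scenario` (participant x scenario accuracy and
#'   time) and `participants` (`participant_id`, `accuracy`, `std_speed`).
#' @export
triage_scores <- function(events, scenarios = default_scenarios(), na_rm = FALSE) {
  training_ids <- setdiff(names(scenarios), "familiarization")
  roster_tbl <- purrr::map_dfr(scenarios[training_ids], function(sc) {
    tibble(
      scenario_id = sc$id,
      patient_id = sc$roster$patient_id,
      true_color = as.character(sc$roster$true_color),
      n_patients = nrow(sc$roster)
    )
  })
  unknown <- dplyr::anti_join(
    events, roster_tbl, by = c("scenario_id", "patient_id")
  )
  if (nrow(unknown)) {
    stop_input(paste0(
      "event log references unknown patient id(s): ",
      paste(utils::head(unique(paste0(
        unknown$scenario_id, "/", unknown$patient_id
      )), 5), collapse = ", ")
    ))
  }
  grid <- tidyr::expand_grid(
    participant_id = unique(events$participant_id),
    scenario_id = training_ids
  )
  # last assignment per patient wins
  last <- events |>
    dplyr::arrange(dplyr::desc(.data$t_ms)) |>
    dplyr::distinct(.data$participant_id, .data$scenario_id, .data$patient_id,
                    .keep_all = TRUE) |>
    dplyr::left_join(roster_tbl, by = c("scenario_id", "patient_id"))
  per_scenario <- grid |>
    dplyr::left_join(
      last |>
        dplyr::group_by(.data$participant_id, .data$scenario_id) |>
        dplyr::summarise(
          n_correct = sum(.data$assigned_color == .data$true_color),
          n_patients = .data$n_patients[1],
          time_s = max(.data$t_ms) / 1000,
          .groups = "drop"
        ),
      by = c("participant_id", "scenario_id")
    ) |>
    dplyr::mutate(
      accuracy = dplyr::if_else(
        is.na(.data$n_correct), NA_real_,
        .data$n_correct / .data$n_patients
      )
    ) |>
    dplyr::select("participant_id", "scenario_id", "accuracy", "time_s")
  acc <- per_scenario |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      # an unrecorded scenario is missing (per-measure exclusion), not zero
      accuracy = participant_accuracy(.data$accuracy, na_rm = na_rm),
      .groups = "drop"
    )
  spd <- standardize_speed(
    per_scenario[, c("participant_id", "scenario_id", "time_s")],
    na_rm = na_rm
  )
  list(
    per_scenario = per_scenario,
    participants = dplyr::left_join(acc, spd, by = "participant_id")
  )
}
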