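#' Triage colour levels
#'
#' The four START triage categories, ordered by severity for reporting:
#' green (minor), yellow (delayed), red (immediate), black (dead or fatally
#' injured).
#'
#' @return Character vector of the four levels in severity order.
#' @export
triage_colors <- function() c("green", "yellow", "red", "black")

#' START decision thresholds
#'
#' Numeric cut-offs used by [start_classify()]. Defaults follow the
#' published START flowchart: respiration rate above 30 breaths/min or
#' capillary refill above 2 s mark a patient as immediate (red). Both are
#' configurable so that related variants (e.g. mSTART) can be expressed.
#'
#' @param rr_red_above Respiration rate (breaths/min) above which a
#'   breathing patient is classified red.
#' @param cap_refill_red_above_s Capillary refill time (seconds) above which
#'   perfusion is considered inadequate.
#' @return A list of class `start_thresholds`.
#' @export
start_thresholds <- function(rr_red_above = 30, cap_refill_red_above_s = 2) {
  if (!is.numeric(rr_red_above) || rr_red_above <= 0 ||
      !is.numeric(cap_refill_red_above_s) || cap_refill_red_above_s <= 0) {
    stop_input("START thresholds must be strictly positive numbers")
  }
  structure(
    list(
      rr_red_above = rr_red_above,
      cap_refill_red_above_s = cap_refill_red_above_s
    ),
    class = "start_thresholds"
  )
}

#' Build a patient assessment table
#'
#' A patient assessment collects the findings obtainable during triage:
#' whether the patient can walk, airway/breathing status, respiration rate,
#' capillary refill, radial pulse, response to simple commands, and heavy
#' bleeding. Vectorised: each argument may be length 1 or n.
#'
#' @param can_walk,airway_clear_after_reposition,breathing,radial_pulse_present,follows_commands,heavy_bleeding
#'   Logical findings.
#' @param respiration_rate Breaths per minute (non-negative integer-ish).
#' @param cap_refill_s Capillary refill time in seconds (non-negative).
#' @param injury_sites Optional list of character labels per patient.
#' @return A tibble with one row per patient.
#' @export
patient_assessment <- function(can_walk,
                               breathing = TRUE,
                               airway_clear_after_reposition = TRUE,
                               respiration_rate = 16,
                               cap_refill_s = 1,
                               radial_pulse_present = TRUE,
                               follows_commands = TRUE,
                               heavy_bleeding = FALSE,
                               injury_sites = NULL) {
  out <- tibble(
    can_walk = can_walk,
    breathing = breathing,
    airway_clear_after_reposition = airway_clear_after_reposition,
    respiration_rate = respiration_rate,
    cap_refill_s = cap_refill_s,
    radial_pulse_present = radial_pulse_present,
    follows_commands = follows_commands,
    heavy_bleeding = heavy_bleeding
  )
  if (any(out$respiration_rate < 0, na.rm = TRUE) ||
      any(out$cap_refill_s < 0, na.rm = TRUE)) {
    stop_input("respiration_rate and cap_refill_s must be non-negative")
  }
  # A patient with zero respiration rate cannot be breathing.
  bad <- !is.na(out$respiration_rate) & out$respiration_rate == 0 &
    !is.na(out$breathing) & out$breathing
  if (any(bad)) {
    stop_input("respiration_rate = 0 implies breathing = FALSE")
  }
  out$injury_sites <- injury_sites %||% rep(list(character()), nrow(out))
  out
}

assessment_fields <- c(
  "can_walk", "breathing", "airway_clear_after_reposition",
  "respiration_rate", "cap_refill_s", "radial_pulse_present",
  "follows_commands", "heavy_bleeding"
)

#' Classify patients with the START decision tree
#'
#' Applies the START (simple triage and rapid treatment) algorithm to each
#' row of an assessment table. The branches are evaluated in the standard
#' order: walking wounded are green; a patient not breathing after airway
#' repositioning is black, one who resumes breathing is red; then
#' respiration rate, perfusion (capillary refill / radial pulse) and
#' mentation (simple commands) are checked against the thresholds; everyone
#' else is yellow.
#'
#' @param assessment A data frame as produced by [patient_assessment()].
#' @param thresholds A [start_thresholds()] object.
#' @return Factor of triage colours with levels `triage_colors()`.
#' @examples
#' start_classify(patient_assessment(can_walk = TRUE))
#' @export
start_classify <- function(assessment, thresholds = start_thresholds()) {
  if (!inherits(thresholds, "start_thresholds")) {
    stop_input("`thresholds` must be created with start_thresholds()")
  }
  missing_cols <- setdiff(assessment_fields, names(assessment))
  if (length(missing_cols)) {
    stop_input(paste0(
      "assessment is missing required field(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  for (f in assessment_fields) {
    if (anyNA(assessment[[f]])) {
      stop_input(paste0("assessment field `", f, "` contains missing values"))
    }
  }
  a <- assessment
  n <- nrow(a)
  out <- rep(NA_character_, n)

  out[a$can_walk] <- "green"
  todo <- is.na(out)

  no_breath <- todo & !a$breathing
  out[no_breath & !a$airway_clear_after_reposition] <- "black"
  out[no_breath & a$airway_clear_after_reposition] <- "red"
  todo <- is.na(out)

  out[todo & a$respiration_rate > thresholds$rr_red_above] <- "red"
  todo <- is.na(out)

  poor_perfusion <- a$cap_refill_s > thresholds$cap_refill_red_above_s |
    !a$radial_pulse_present
  out[todo & poor_perfusion] <- "red"
  todo <- is.na(out)

  out[todo & !a$follows_commands] <- "red"
  out[is.na(out)] <- "yellow"

  factor(out, levels = triage_colors())
}

#' Score a triage knowledge test
#'
#' One point per correctly assigned colour over up to 20 patient vignettes;
#' unanswered items (missing values, or answers shorter than the test)
#' score zero.
#'
#' @param answers Character vector (or factor) of triage colours, at most
#'   one per test item.
#' @param test A knowledge test as returned by [default_knowledge_test()]:
#'   a tibble with a `key` column.
#' @return Integer score between 0 and the number of items.
#' @export
score_knowledge_test <- function(answers, test = default_knowledge_test()) {
  key <- as.character(test$key)
  answers <- as.character(answers)
  if (length(answers) > length(key)) {
    stop_input(paste0(
      "got ", length(answers), " answers for a ", length(key), "-item test"
    ))
  }
  answers <- c(answers, rep(NA_character_, length(key) - length(answers)))
  sum(!is.na(answers) & answers == key)
}

#' Default 20-item triage knowledge test
#'
#' Twenty patient vignettes spanning all four triage levels, with answer
#' keys derived from [start_classify()] under default thresholds. The study
#' instrument's items are not public, so the vignettes are constructed from
#' the same assessment fields the in-scenario patients expose.
#'
#' @return A tibble of 20 vignettes with columns `item`, the assessment
#'   fields, and `key`.
#' @export
default_knowledge_test <- function() {
  a <- patient_assessment(
    can_walk = c(
      TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
      TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE
    ),
    breathing = c(
      TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE,
      TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE
    ),
    airway_clear_after_reposition = c(
      TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
      TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE
    ),
    respiration_rate = c(
      16, 18, 0, 35, 14, 22, 0, 40, 17, 24,
      15, 32, 0, 20, 18, 19, 36, 0, 16, 21
    ),
    cap_refill_s = c(
      1, 1.5, 3, 1, 1, 1.9, 2.5, 1.5, 1, 1.8,
      1, 1.2, 4, 1, 1.1, 1.7, 1.4, 3.5, 1, 1.6
    ),
    radial_pulse_present = c(
      TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE,
      TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE
    ),
    follows_commands = c(
      TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE,
      TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE
    ),
    heavy_bleeding = c(
      FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE,
      FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE
    )
  )
  out <- dplyr::mutate(a, item = dplyr::row_number(), .before = 1)
  out$key <- start_classify(a)
  out
}
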