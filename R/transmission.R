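#' @title SSSS information-transmission scoring
#' @description
#' Radio messages are coded against the four categories of the SSSS scheme
#' (scene, safety, situation, support). Each category is worth at most one
#' point; the scene category earns half a point if only the accident itself
#' is mentioned and the full point when details (street type, vehicles) are
#' given; 0.3 points are deducted per error in a category, floored at zero.
#' For the situation category an error is a wrongly stated patient count,
#' waived in the two most complex scenarios (4 and 5) when the estimate is
#' within plus or minus two. The four category scores are summed (0-4) and
#' divided by the message word count to give the efficiency score, which is
#' finally averaged across scenarios.
#' @name transmission
NULL

ssss_categories <- function() c("scene", "safety", "situation", "support")

# An empty coded message (nothing mentioned).
empty_coding <- function() {
  tibble(
    scene_mentioned = FALSE, scene_detailed = FALSE, scene_errors = 0L,
    safety_mentioned = FALSE, safety_errors = 0L,
    situation_mentioned = FALSE, reported_patient_count = NA_integer_,
    support_mentioned = FALSE, support_errors = 0L
  )
}

validate_coding <- function(coded) {
  need <- names(empty_coding())
  miss <- setdiff(need, names(coded))
  if (length(miss)) {
    stop_input(paste0("coded message missing field(s): ", paste(miss, collapse = ", ")))
  }
  coded
}

#' Score one SSSS category of a coded message
#'
#' @param coded One-row coded-message tibble (fields as in
#'   [empty_coding()]).
#' @param category One of `"scene"`, `"safety"`, `"situation"`,
#'   `"support"`.
#' @param true_patient_count Roster size of the scenario (used for the
#'   situation category).
#' @param scenario_id Scenario id; the patient-count tolerance of +/-2
#'   applies in scenarios `"4"` and `"5"`.
#' @param penalty Points deducted per error.
#' @return Category points in `[0, 1]`.
#' @export
score_category <- function(coded, category, true_patient_count, scenario_id,
                           penalty = 0.3) {
  validate_coding(coded)
  category <- match.arg(category, ssss_categories())
  if (true_patient_count < 0) stop_input("true_patient_count must be >= 0")
  if (category == "situation") {
    if (!coded$situation_mentioned) return(0)
    base <- 1
    reported <- coded$reported_patient_count
    errors <- if (is.na(reported)) {
      1L # situation raised but no count stated counts as one error
    } else {
      delta <- abs(reported - true_patient_count)
      tol <- if (as.character(scenario_id) %in% c("4", "5")) 2 else 0
      as.integer(delta > tol)
    }
  } else {
    mentioned <- coded[[paste0(category, "_mentioned")]]
    if (!mentioned) return(0)
    base <- if (category == "scene" && !coded$scene_detailed) 0.5 else 1
    errors <- coded[[paste0(category, "_errors")]]
  }
  max(0, base - penalty * errors)
}

# Vectorised scoring of coded messages (same rules as score_category).
score_codings <- function(coded, word_count, true_patient_count, scenario_id,
                          penalty = 0.3) {
  floor0 <- function(x) pmax(0, x)
  scene <- ifelse(
    !coded$scene_mentioned, 0,
    floor0(ifelse(coded$scene_detailed, 1, 0.5) - penalty * coded$scene_errors)
  )
  safety <- ifelse(
    !coded$safety_mentioned, 0,
    floor0(1 - penalty * coded$safety_errors)
  )
  support <- ifelse(
    !coded$support_mentioned, 0,
    floor0(1 - penalty * coded$support_errors)
  )
  tol <- ifelse(as.character(scenario_id) %in% c("4", "5"), 2, 0)
  sit_err <- ifelse(
    is.na(coded$reported_patient_count), 1L,
    as.integer(abs(coded$reported_patient_count - true_patient_count) > tol)
  )
  situation <- ifelse(
    !coded$situation_mentioned, 0,
    floor0(1 - penalty * sit_err)
  )
  total <- scene + safety + situation + support
  no_words <- is.na(word_count) | word_count < 1
  if (any(no_words)) warn("message(s) with no words; efficiency is missing")
  tibble(
    scene = scene, safety = safety, situation = situation, support = support,
    total = total,
    efficiency = ifelse(no_words, NA_real_, total / word_count)
  )
}

#' Total score and efficiency of one coded message
#'
#' @param coded One-row coded-message tibble.
#' @param word_count Number of whitespace-delimited words in the message.
#' @param true_patient_count,scenario_id Passed to [score_category()].
#' @return One-row tibble with the four category points, `total` (0-4) and
#'   `efficiency` (`total / word_count`).
#' @export
message_total <- function(coded, word_count, true_patient_count, scenario_id) {
  validate_coding(coded)
  score_codings(coded, word_count, true_patient_count, scenario_id)
}

#' Participant-level transmission efficiency
#'
#' Unweighted mean of the per-scenario efficiencies. Missing scenario
#' messages are excluded from the mean (per-measure exclusion), mirroring
#' a recording failure for that scenario.
#'
#' @param per_scenario Numeric vector of per-scenario efficiencies.
#' @return Mean efficiency.
#' @export
participant_efficiency <- function(per_scenario) {
  if (all(is.na(per_scenario))) return(NA_real_)
  mean(per_scenario, na.rm = TRUE)
}

#' Count words in a transcript
#'
#' Whitespace tokenization after dropping punctuation-only tokens.
#'
#' @param text Character vector.
#' @return Integer word counts.
#' @export
count_words <- function(text) {
  tokens <- stringr::str_split(stringr::str_trim(text), "\\s+")
  vapply(
    tokens,
    function(tk) sum(stringr::str_detect(tk, "[[:alnum:]]")),
    integer(1)
  )
}

#' Interrater agreement between two sets of coded messages
#'
#' Categorization agreement is the percentage of mention/no-mention
#' decisions (4 per message) on which the coders agree. Correctness
#' agreement is the percentage of identical error judgements among the
#' categories both coders marked as mentioned (for the situation category
#' the reported patient counts are compared).
#'
#' @param coder_a,coder_b Coded-message tibbles of equal length, aligned
#'   row by row.
#' @return Tibble with `categorization_pct` and `correctness_pct`
#'   (`NA` if no category was jointly mentioned).
#' @export
interrater_agreement <- function(coder_a, coder_b) {
  if (nrow(coder_a) != nrow(coder_b)) {
    stop_input("coder_a and coder_b must have the same number of messages")
  }
  validate_coding(coder_a)
  validate_coding(coder_b)
  mention_cols <- paste0(ssss_categories(), "_mentioned")
  ma <- as.matrix(coder_a[mention_cols])
  mb <- as.matrix(coder_b[mention_cols])
  categorization <- 100 * mean(ma == mb)

  err_value <- function(coded, cat) {
    if (cat == "situation") coded$reported_patient_count else coded[[paste0(cat, "_errors")]]
  }
  agree <- c()
  for (cat in ssss_categories()) {
    both <- coder_a[[paste0(cat, "_mentioned")]] & coder_b[[paste0(cat, "_mentioned")]]
    if (any(both)) {
      va <- err_value(coder_a, cat)[both]
      vb <- err_value(coder_b, cat)[both]
      same <- (is.na(va) & is.na(vb)) | (!is.na(va) & !is.na(vb) & va == vb)
      agree <- c(agree, same)
    }
  }
  correctness <- if (length(agree)) 100 * mean(agree) else NA_real_
  tibble(categorization_pct = categorization, correctness_pct = correctness)
}

#' Score a cohort's transcripts end to end
#'
#' Runs the rule-based coder on every transcript, scores each coded
#' message, and averages efficiencies per participant.
#'
#' @param transcripts Tibble with `participant_id`, `scenario_id`, `text`.
#' @param scenarios Scenario list (for roster sizes).
#' @return List with `per_message` (coded + scored rows) and
#'   `participants` (`participant_id`, `transmission_total`,
#'   `efficiency`, `word_count`).
#' @export
transmission_scores <- function(transcripts, scenarios = default_scenarios()) {
  per_message <- transcripts |>
    dplyr::mutate(word_count = count_words(.data$text))
  coded <- auto_code_text(per_message$text)
  true_n <- vapply(scenarios, function(sc) nrow(sc$roster), integer(1))
  scored <- score_codings(
    coded, per_message$word_count,
    unname(true_n[per_message$scenario_id]),
    per_message$scenario_id
  )
  per_message <- dplyr::bind_cols(per_message, coded, scored)
  participants <- per_message |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      transmission_total = mean(.data$total, na.rm = TRUE),
      efficiency = participant_efficiency(.data$efficiency),
      word_count = mean(.data$word_count),
      .groups = "drop"
    )
  list(per_message = per_message, participants = participants)
}
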