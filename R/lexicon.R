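# Controlled radio-message lexicon.
#
# Synthetic transcripts are built exclusively from these phrases plus
# filler tokens, so the rule-based coder can recover the latent coding
# exactly. Keyword conventions: "accident" marks the scene category,
# "caution" safety, "injured" (with a preceding integer) the situation
# patient count, "send" the support request. Error phrases are factually
# wrong statements enumerated per category.

lexicon <- function() {
  list(
    scene_base = "traffic accident here",
    scene_detail = c(
      "on a country road",
      "on the motorway",
      "in the city center",
      "expressway three cars involved",
      "expressway bus and truck"
    ),
    scene_error = c(
      "possibly a railway crash",
      "a building collapsed nearby"
    ),
    safety_base = c(
      "caution spilled oil",
      "caution ongoing traffic",
      "caution broken glass"
    ),
    safety_error = c(
      "the site is fully secure",
      "there are surely zero hazards remaining"
    ),
    situation_count = "%d injured persons",
    situation_nocount = "injured persons present",
    support_base = "send more ambulances",
    support_error = c(
      "cancel all responding units",
      "dispatch the coast guard"
    ),
    filler = c(
      "uh", "over", "roger", "copy", "please", "confirm", "waiting", "for",
      "instructions", "responder", "reporting", "again", "i", "repeat",
      "stand", "by", "acknowledged"
    )
  )
}

lexicon_vocabulary <- function() {
  lx <- lexicon()
  phrases <- unlist(lx[setdiff(names(lx), "situation_count")])
  words <- unlist(stringr::str_split(phrases, "\\s+"))
  unique(c(words, "injured", "persons", "present"))
}

#' Rule-based SSSS coder for controlled-lexicon transcripts
#'
#' A deterministic stand-in for the study's human coders, applicable to
#' messages built from the package's controlled phrase lexicon. Category
#' mentions are detected from keyword phrases, error counts from the
#' enumerated wrong statements, and the reported patient count from the
#' integer preceding the word "injured". Text containing tokens outside the
#' lexicon is still coded from what matches, with a warning.
#'
#' @param transcripts Tibble with columns `participant_id`, `scenario_id`,
#'   `text` (or a character vector of messages).
#' @return Coded-message tibble, one row per transcript, with the fields of
#'   [empty_coding()].
#' @export
auto_code <- function(transcripts) {
  text <- if (is.character(transcripts)) transcripts else transcripts$text
  out <- auto_code_text(text)
  if (!is.character(transcripts)) {
    out <- dplyr::bind_cols(
      transcripts[, intersect(c("participant_id", "scenario_id"), names(transcripts))],
      out
    )
  }
  out
}

# Vectorised over a character vector of messages.
auto_code_text <- function(text) {
  lx <- lexicon()
  txt <- stringr::str_to_lower(text)
  all_tokens <- unique(unlist(stringr::str_split(stringr::str_trim(txt), "\\s+")))
  all_tokens <- all_tokens[nzchar(all_tokens)]
  unknown <- all_tokens[
    !(all_tokens %in% lexicon_vocabulary() |
        stringr::str_detect(all_tokens, "^[0-9]+$"))
  ]
  if (length(unknown)) {
    warn(paste0(
      "transcript(s) contain token(s) outside the controlled lexicon (",
      paste(utils::head(unknown, 3), collapse = ", "),
      "); coding may be incomplete"
    ))
  }
  count_phrases <- function(phrases) {
    counts <- rep(0L, length(txt))
    for (p in phrases) {
      counts <- counts + stringr::str_count(txt, stringr::fixed(p))
    }
    counts
  }
  scene_err <- count_phrases(lx$scene_error)
  safety_err <- count_phrases(lx$safety_error)
  support_err <- count_phrases(lx$support_error)

  reported <- suppressWarnings(
    as.integer(stringr::str_match(txt, "([0-9]+) injured")[, 2])
  )

  tibble(
    scene_mentioned = stringr::str_detect(txt, "\\baccident\\b") | scene_err > 0,
    scene_detailed = count_phrases(lx$scene_detail) > 0,
    scene_errors = as.integer(scene_err),
    safety_mentioned = stringr::str_detect(txt, "\\bcaution\\b") | safety_err > 0,
    safety_errors = as.integer(safety_err),
    situation_mentioned = stringr::str_detect(txt, "\\binjured\\b"),
    reported_patient_count = reported,
    support_mentioned = stringr::str_detect(txt, "\\bsend\\b") | support_err > 0,
    support_errors = as.integer(support_err)
  )
}
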