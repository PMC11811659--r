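coding_of <- function(...) {
  out <- mcitriage:::empty_coding()
  args <- list(...)
  out[names(args)] <- args
  out
}

test_that("category scoring implements the SSSS point rules", {
  # scene: half a point without detail, full point with it
  expect_equal(
    score_category(coding_of(scene_mentioned = TRUE), "scene", 4, "1"), 0.5
  )
  expect_equal(
    score_category(coding_of(scene_mentioned = TRUE, scene_detailed = TRUE),
                   "scene", 4, "1"), 1
  )
  # 0.3 deducted per error, floored at zero
  expect_equal(
    score_category(coding_of(safety_mentioned = TRUE, safety_errors = 2L),
                   "safety", 4, "1"), 0.4
  )
  expect_equal(
    score_category(coding_of(safety_mentioned = TRUE, safety_errors = 4L),
                   "safety", 4, "1"), 0
  )
  expect_equal(score_category(coding_of(), "support", 4, "1"), 0)
})

test_that("patient-count tolerance applies only in the complex scenarios", {
  sit <- function(reported, true, sid) {
    score_category(
      coding_of(situation_mentioned = TRUE,
                reported_patient_count = as.integer(reported)),
      "situation", true, sid
    )
  }
  # scenario 4 with 8 patients: 'almost 10' incurs no penalty
  expect_equal(sit(10, 8, "4"), 1)
  expect_equal(sit(6, 8, "5"), 1)
  expect_equal(sit(11, 8, "4"), 0.7) # off by 3
  expect_equal(sit(5, 4, "1"), 0.7)  # +-2 tolerance not granted early
  expect_equal(sit(4, 4, "1"), 1)
  # situation raised without any count counts as one error
  expect_equal(
    score_category(coding_of(situation_mentioned = TRUE), "situation", 4, "1"),
    0.7
  )
})

test_that("message totals and efficiency standardize by word count", {
  perfect <- coding_of(
    scene_mentioned = TRUE, scene_detailed = TRUE,
    safety_mentioned = TRUE, situation_mentioned = TRUE,
    reported_patient_count = 4L, support_mentioned = TRUE
  )
  out <- message_total(perfect, 40, 4, "1")
  expect_equal(out$total, 4)
  expect_equal(out$efficiency, 0.1)
  mixed <- coding_of(
    scene_mentioned = TRUE, scene_detailed = TRUE,
    safety_mentioned = TRUE, support_mentioned = TRUE,
    situation_mentioned = TRUE, reported_patient_count = 5L
  )
  out2 <- message_total(mixed, 37, 4, "1") # situation off by one: 0.7
  expect_equal(out2$total, 3.7)
  expect_equal(round(out2$efficiency, 2), 0.1)
  empty <- message_total(coding_of(), 25, 4, "1")
  expect_equal(empty$total, 0)
  expect_equal(empty$efficiency, 0)
  expect_warning(none <- message_total(perfect, 0, 4, "1"), "no words")
  expect_true(is.na(none$efficiency))
})

test_that("totals stay in [0, 4] and efficiency is monotone in word count", {
  withr::with_seed(11, {
    codings <- random_codings(400)
    scored <- mcitriage:::score_codings(
      codings, word_count = sample(5:80, 400, TRUE),
      true_patient_count = sample(0:20, 400, TRUE),
      scenario_id = sample(as.character(1:5), 400, TRUE)
    )
    expect_true(all(scored$total >= 0 & scored$total <= 4))
    # the vectorised scorer agrees with the per-category reference rules
    idx <- sample(400, 60)
    for (i in idx) {
      tn <- 6
      ref <- sum(vapply(
        mcitriage:::ssss_categories(),
        function(cat) score_category(codings[i, ], cat, tn, "2"),
        numeric(1)
      ))
      expect_equal(
        mcitriage:::score_codings(codings[i, ], 30, tn, "2")$total, ref
      )
    }
  })
  cod <- coding_of(scene_mentioned = TRUE, scene_detailed = TRUE,
                   safety_mentioned = TRUE)
  effs <- vapply(c(10, 20, 40, 80),
                 function(w) message_total(cod, w, 4, "1")$efficiency,
                 numeric(1))
  expect_true(all(diff(effs) < 0))
})

test_that("participant efficiency averages scenarios with per-measure exclusion", {
  expect_equal(participant_efficiency(rep(0.1, 5)), 0.1)
  expect_equal(participant_efficiency(c(0.1, NA, 0.2, NA, 0.3)), 0.2)
  expect_true(is.na(participant_efficiency(rep(NA_real_, 5))))
})

test_that("word counting tokenizes on whitespace, ignoring bare punctuation", {
  expect_equal(count_words("traffic accident here"), 3L)
  expect_equal(count_words("  uh   over  "), 2L)
  expect_equal(count_words(c("a b", "a - b", "")), c(2L, 2L, 0L))
  expect_equal(count_words("8 injured persons"), 3L)
})

test_that("rule-based coder recovers latent codings on generator output", {
  cfg <- generator_config(seed = 401)
  scenarios <- default_scenarios()
  withr::with_seed(402, {
    msgs <- purrr::map_dfr(1:1000, function(i) {
      sid <- sample(as.character(1:5), 1)
      g <- sample(c("mfr", "nonmfr"), 1)
      msg <- mcitriage:::gen_message(g, scenarios[[sid]], cfg)
      dplyr::bind_cols(tibble::tibble(text = msg$text), msg$coding)
    })
  })
  coded <- auto_code(msgs$text)
  latent_cols <- names(mcitriage:::empty_coding())
  expect_equal(as.data.frame(coded[latent_cols]),
               as.data.frame(msgs[latent_cols]))
})

test_that("out-of-lexicon text is coded partially with a warning", {
  expect_warning(
    coded <- auto_code("traffic accident here unbekanntes wort"),
    "outside the controlled lexicon"
  )
  expect_true(coded$scene_mentioned)
  expect_false(coded$support_mentioned)
})

test_that("interrater agreement separates categorization and correctness", {
  withr::with_seed(8, a <- random_codings(20))
  expect_equal(
    as.numeric(interrater_agreement(a, a)),
    c(100, 100)
  )
  b <- a
  # flip one of the 80 mention decisions (5 messages x 4 categories = 20
  # decisions per category set); flipping one scene mention on 20 messages
  # changes 1 of 80 decisions
  b$scene_mentioned[1] <- !b$scene_mentioned[1]
  b$scene_detailed[1] <- FALSE
  b$scene_errors[1] <- 0L
  out <- interrater_agreement(a, b)
  expect_equal(out$categorization_pct, 100 * 79 / 80)
  all_m <- coding_of(scene_mentioned = TRUE, safety_mentioned = TRUE,
                     situation_mentioned = TRUE, reported_patient_count = 4L,
                     support_mentioned = TRUE)
  out2 <- interrater_agreement(all_m, coding_of())
  expect_equal(out2$categorization_pct, 0)
  expect_true(is.na(out2$correctness_pct))
  expect_error(interrater_agreement(a, a[1:3, ]), "same number")
})
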