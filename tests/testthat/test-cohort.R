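test_that("default cohort has the study's group structure", {
  co <- generate_cohort(generator_config(seed = 1), include = "triage")
  expect_s3_class(co, "mci_cohort")
  expect_equal(nrow(co$participants), 76)
  expect_equal(sum(co$participants$group == "mfr"), 39)
  expect_equal(sum(co$participants$group == "nonmfr"), 37)
  expect_true(all(co$participants$age >= 18))
  expect_true(all(co$participants$knowledge_score >= 0 &
                    co$participants$knowledge_score <= 20))
  expect_true(all(co$participants$prior_mci_training_band %in% 1:8))
  expect_true(all(co$participants$prior_ivr_experience %in% 1:9))
})

test_that("identical seeds give identical bundles, different seeds differ", {
  cfg <- generator_config(seed = 55)
  a <- generate_cohort(cfg, include = c("triage", "transmission"))
  b <- generate_cohort(cfg, include = c("triage", "transmission"))
  expect_identical(a$participants, b$participants)
  expect_identical(a$triage_events, b$triage_events)
  expect_identical(a$transcripts, b$transcripts)
  c2 <- generate_cohort(generator_config(seed = 56), include = "triage")
  expect_false(identical(a$triage_events, c2$triage_events))
})

test_that("configuration validation rejects infeasible setups", {
  expect_error(generator_config(n_mfr = 0), "positive counts",
               class = "mcitriage_config_error")
  expect_error(generator_config(accuracy_p = c(mfr = 1.2, nonmfr = 0.7)),
               "probabilities", class = "mcitriage_config_error")
  expect_error(generator_config(knowledge_accuracy_rho = 0.97),
               "attainable", class = "mcitriage_config_error")
  g <- generator_config()$gaze
  g$rate_hz <- 0
  expect_error(generator_config(gaze = g), "sampling rate",
               class = "mcitriage_config_error")
  expect_error(
    generate_cohort(list(seed = 1)),
    "generator_config", class = "mcitriage_config_error"
  )
})

test_that("latent knowledge scores are realized exactly by the scorer", {
  co <- generate_cohort(generator_config(seed = 6), include = "triage")
  test <- default_knowledge_test()
  rescored <- vapply(co$participants$knowledge_answers,
                     score_knowledge_test, numeric(1), test = test)
  expect_equal(unname(rescored), as.numeric(co$participants$knowledge_score))
})

test_that("triage logs respect the event-log invariants", {
  co <- generate_cohort(generator_config(seed = 13), include = "triage")
  by_log <- split(co$triage_events$t_ms,
                  paste(co$triage_events$participant_id,
                        co$triage_events$scenario_id))
  expect_true(all(vapply(by_log, function(t) all(diff(t) > 0), logical(1))))
  dup <- co$triage_events |>
    dplyr::count(.data$participant_id, .data$scenario_id, .data$patient_id)
  expect_true(all(dup$n == 1))
})

test_that("gaze streams have the nominal rate and latent fixations match detection", {
  cfg <- generator_config(seed = 2)
  sc <- default_scenarios()[["2"]]
  gz <- generate_gaze_stream(sc, cfg, seed = 21)
  # 30 s at 200 Hz
  expect_equal(nrow(gz$stream), 6000)
  expect_equal(sort(unique(diff(gz$stream$t_ms))), 5)

  # noiseless stream: the detector recovers the latent fixation list
  # (boundaries may shift by a sample or two where a window absorbs the
  # first samples of a saccade sweep)
  g0 <- cfg$gaze
  g0$jitter_sd_deg <- 0
  cfg0 <- generator_config(seed = 2, gaze = g0)
  gz0 <- generate_gaze_stream(sc, cfg0, seed = 22)
  fx <- detect_fixations(gz0$stream, 1, 100)
  expect_equal(nrow(fx), nrow(gz0$fixations))
  expect_true(all(abs(fx$start_ms - gz0$fixations$start_ms) <= 15))

  # all dwell mass on patients: every detected fixation lies in a patients AOI
  g1 <- cfg$gaze
  g1$dwell <- c(patients = 1, safety = 0, vehicle_impact = 0, distractor = 0,
                background = 0)
  cfg1 <- generator_config(seed = 2, gaze = g1)
  gz1 <- generate_gaze_stream(sc, cfg1, seed = 23)
  fx1 <- assign_fixations(detect_fixations(gz1$stream), sc$aois)
  expect_true(all(fx1$category == "patients"))
})

test_that("radio messages realize their latent codings and word targets", {
  cfg <- generator_config(seed = 9)
  sc <- default_scenarios()[["4"]]
  msg <- generate_radio_message("mfr", sc, cfg, seed = 91)
  expect_equal(count_words(msg$text), msg$coding$word_count_target)
  coded <- auto_code(msg$text)
  for (col in names(mcitriage:::empty_coding())) {
    expect_equal(coded[[col]], msg$coding[[col]])
  }
  # a perfect latent coding scores the full 4 points
  perfect <- mcitriage:::empty_coding()
  perfect[c("scene_mentioned", "scene_detailed", "safety_mentioned",
            "situation_mentioned", "support_mentioned")] <- TRUE
  perfect$reported_patient_count <- nrow(sc$roster)
  expect_equal(message_total(perfect, 40, nrow(sc$roster), sc$id)$total, 4)
  # a reported count equal to the truth incurs no situation error
  expect_equal(
    score_category(perfect, "situation", nrow(sc$roster), sc$id), 1
  )
})

test_that("generated word counts match the configured filler distribution", {
  cfg <- generator_config(seed = 33)
  sc <- default_scenarios()[["3"]]
  withr::with_seed(34, {
    rows <- mcitriage:::gen_messages_df(
      pm = rep(cfg$mention_p[["mfr"]], 1000),
      meanlog = rep(cfg$filler_meanlog[["mfr"]], 1000),
      sdlog = sqrt(cfg$filler_sdlog_between^2 + cfg$filler_sdlog_within^2),
      scenario_id = rep("3", 1000), true_n = nrow(sc$roster), config = cfg
    )
  })
  wc <- count_words(rows$text)
  expect_equal(wc, rows$word_count_target)
  # oracle: mean word count = mean core length (reconstructed from the
  # latent codings) + analytic lognormal filler mean, within MC error
  core <- count_words(stringr::str_squish(stringr::str_remove_all(
    rows$text, "\\b(uh|over|roger|copy|please|confirm|waiting|for|instructions|responder|reporting|again|i|repeat|stand|by|acknowledged)\\b"
  )))
  s2 <- cfg$filler_sdlog_between^2 + cfg$filler_sdlog_within^2
  expected <- mean(core) + exp(cfg$filler_meanlog[["mfr"]] + s2 / 2)
  expect_lt(abs(mean(wc) - expected) / expected, 0.06)
})

test_that("missingness switches drop whole participants per indicator", {
  cfg <- generator_config(
    seed = 4,
    missingness = c(gaze = 0, triage = 2 / 76, transmission = 6 / 76)
  )
  co <- generate_cohort(cfg, include = c("triage", "transmission"))
  expect_equal(dplyr::n_distinct(co$triage_events$participant_id), 74)
  expect_equal(dplyr::n_distinct(co$transcripts$participant_id), 70)
})
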