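scenario_fixture <- function(id = "1") default_scenarios()[[id]]

log_for <- function(scenario, colors, t_ms = NULL) {
  n <- length(colors)
  tibble::tibble(
    patient_id = scenario$roster$patient_id[seq_len(n)],
    assigned_color = colors,
    t_ms = t_ms %||% seq(10000, by = 10000, length.out = n)
  )
}

test_that("scenario accuracy is correct assignments over roster size", {
  sc <- scenario_fixture("1") # 3 green + 1 yellow
  truth <- as.character(sc$roster$true_color)
  expect_equal(scenario_accuracy(log_for(sc, truth), sc), 1)
  off <- truth
  off[1] <- "red"
  expect_equal(scenario_accuracy(log_for(sc, off), sc), 0.75)
  # untriaged patients count as incorrect
  expect_equal(scenario_accuracy(log_for(sc, truth[1:2]), sc), 0.5)
  expect_equal(scenario_accuracy(log_for(sc, character(0)), sc), 0)
  sc3 <- scenario_fixture("3") # 6 patients
  truth3 <- as.character(sc3$roster$true_color)
  bad3 <- truth3
  bad3[6] <- "green"
  expect_equal(scenario_accuracy(log_for(sc3, bad3), sc3), 5 / 6)
  expect_error(
    scenario_accuracy(tibble::tibble(patient_id = "zz", assigned_color = "red",
                                     t_ms = 1), sc),
    "unknown patient"
  )
})

test_that("re-triage keeps the last assignment and order does not matter", {
  sc <- scenario_fixture("1")
  truth <- as.character(sc$roster$true_color)
  log <- log_for(sc, truth)
  # an early wrong call corrected later
  log2 <- dplyr::bind_rows(
    tibble::tibble(patient_id = sc$roster$patient_id[1],
                   assigned_color = "black", t_ms = 500),
    log
  )
  expect_equal(scenario_accuracy(log2, sc), 1)
  shuffled <- log2[sample(nrow(log2)), ]
  expect_equal(scenario_accuracy(shuffled, sc), 1)
  # adding a correct event for an untriaged patient never decreases accuracy
  partial <- log_for(sc, truth[1:3])
  more <- dplyr::bind_rows(partial, tibble::tibble(
    patient_id = sc$roster$patient_id[4], assigned_color = truth[4],
    t_ms = 99000
  ))
  expect_gte(scenario_accuracy(more, sc), scenario_accuracy(partial, sc))
})

test_that("participant accuracy averages the five scenarios", {
  expect_equal(participant_accuracy(rep(1, 5)), 1)
  expect_equal(
    round(participant_accuracy(c(1.0, 0.8, 0.8333, 0.875, 0.7222)), 4),
    0.8461
  )
  expect_true(is.na(participant_accuracy(c(1, 1, NA, 1, 1))))
  expect_equal(participant_accuracy(c(1, 1, NA, 1, 1), na_rm = TRUE), 1)
})

test_that("triage time is the last event timestamp in seconds", {
  expect_equal(triage_time(tibble::tibble(t_ms = c(5000, 199000))), 199)
  expect_equal(triage_time(tibble::tibble(t_ms = 60000)), 60)
  expect_warning(out <- triage_time(tibble::tibble(t_ms = numeric())), "empty")
  expect_true(is.na(out))
})

test_that("speed standardization divides by scenario means and row-averages", {
  times <- tibble::tibble(
    participant_id = rep(c("a", "b"), each = 2),
    scenario_id = rep(c("1", "2"), 2),
    time_s = c(60, 120, 60, 80) # scenario means 60 and 100
  )
  out <- standardize_speed(times)
  expect_equal(out$std_speed[out$participant_id == "a"], mean(c(1, 1.2)))
  # a participant exactly at every scenario mean scores 1
  times2 <- tibble::tibble(
    participant_id = rep(c("a", "b", "c"), each = 2),
    scenario_id = rep(c("1", "2"), 3),
    time_s = c(100, 200, 80, 150, 120, 250)
  )
  means <- tapply(times2$time_s, times2$scenario_id, mean)
  times3 <- dplyr::bind_rows(times2, tibble::tibble(
    participant_id = "d", scenario_id = c("1", "2"),
    time_s = NA_real_
  ))
  # after standardization each scenario column has mean exactly 1
  rel <- times2 |>
    dplyr::group_by(scenario_id) |>
    dplyr::mutate(rel = time_s / mean(time_s))
  expect_equal(as.numeric(tapply(rel$rel, rel$scenario_id, mean)), c(1, 1))
})

test_that("standardized speed is scale invariant and handles missing columns", {
  withr::with_seed(5, {
    times <- tidyr::expand_grid(
      participant_id = sprintf("p%d", 1:12),
      scenario_id = as.character(1:5)
    )
    times$time_s <- stats::rlnorm(nrow(times), 5, 0.4)
  })
  out1 <- standardize_speed(times)
  out2 <- standardize_speed(dplyr::mutate(times, time_s = time_s * 7.3))
  expect_equal(out1$std_speed, out2$std_speed)
  # per-scenario means of the standardized cells are exactly 1
  rel <- times |>
    dplyr::group_by(scenario_id) |>
    dplyr::summarise(m = mean(time_s / mean(time_s)))
  expect_equal(rel$m, rep(1, 5))
  gone <- dplyr::mutate(
    times, time_s = dplyr::if_else(scenario_id == "3", NA_real_, time_s)
  )
  expect_warning(out3 <- standardize_speed(gone), "dropping scenario")
  expect_equal(nrow(out3), 12)
})

test_that("cohort triage scoring matches the scalar operations", {
  cfg <- generator_config(seed = 77)
  co <- generate_cohort(cfg, include = "triage")
  ts <- triage_scores(co$triage_events, co$scenarios)
  # spot check five participants against scenario_accuracy/triage_time
  ids <- ts$participants$participant_id[c(1, 9, 20, 40, 76)]
  for (pid in ids) {
    per <- ts$per_scenario[ts$per_scenario$participant_id == pid, ]
    for (sid in c("1", "4")) {
      log <- co$triage_events[
        co$triage_events$participant_id == pid &
          co$triage_events$scenario_id == sid,
      ]
      expect_equal(
        per$accuracy[per$scenario_id == sid],
        scenario_accuracy(log, co$scenarios[[sid]])
      )
      expect_equal(per$time_s[per$scenario_id == sid], triage_time(log))
    }
    expect_equal(
      ts$participants$accuracy[ts$participants$participant_id == pid],
      participant_accuracy(per$accuracy)
    )
  }
})
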