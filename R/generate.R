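#' @title Synthetic study cohort generator
#' @description
#' Generates a complete synthetic iVR MCI study -- participants, triage
#' event logs, gaze streams, radio-message transcripts with latent SSSS
#' codings, and subjective ratings -- whose statistical structure is
#' calibrated to the published group-level moments: two expertise groups
#' (39 MFR / 37 non-MFR), knowledge scores of roughly 13.5 vs 10.9 points,
#' triage accuracy of 84% vs 77%, standardized speed of 0.95 vs 1.05,
#' transmission efficiency of 0.09 vs 0.06, and a knowledge-accuracy rank
#' correlation of about 0.40. Latent quantities (per-participant
#' correctness probabilities, fixation event lists, message codings) are
#' retained as ground truth for oracle tests.
#' @name synthetic-cohort
NULL

#' Generator configuration
#'
#' Defaults encode the emulated study conditions; see the methods vignette
#' for the provenance of each calibration. All parameters are validated.
#'
#' @param n_mfr,n_nonmfr Group sizes.
#' @param knowledge Per-group mean/SD of the latent knowledge score
#'   (points, truncated to 0-20).
#' @param accuracy_p Per-group mean per-patient correctness probability.
#' @param accuracy_knowledge_slope Increase in correctness probability per
#'   knowledge point (within group, centered at the group knowledge mean).
#' @param accuracy_participant_sd Per-group SD of the residual
#'   participant-level correctness probability.
#' @param knowledge_accuracy_rho Target population Spearman correlation
#'   between knowledge score and accuracy (documentation of the
#'   calibration; the slope and residual SDs realize it).
#' @param confusion_weights Weights for drawing a wrong triage colour at
#'   severity distance 1, 2, 3 from the true colour.
#' @param speed_factor_mean Per-group mean participant speed factor.
#' @param speed_factor_sd Between-participant SD of the speed factor.
#' @param scenario_time_sdlog Within-participant lognormal sigma of
#'   scenario completion times.
#' @param filler_meanlog Per-group lognormal location of the filler word
#'   count added to the informative core phrases; message length is
#'   core + filler, so longer-winded messages carry no extra information.
#' @param filler_sdlog_between,filler_sdlog_within Split of the filler
#'   log-variance into a stable participant trait and per-message noise;
#'   the split controls the cross-scenario reliability of the efficiency
#'   score.
#' @param mention_p Per-group probability that an SSSS category is
#'   mentioned.
#' @param mention_participant_sd Between-participant SD of the mention
#'   probability (clamped to `[0.05, 0.95]`).
#' @param scene_detail_p Probability that a mentioned scene is detailed.
#' @param category_error_p Probability of one error in a mentioned
#'   scene/safety/support category.
#' @param count_correct_p Probability the stated patient count is exact.
#' @param count_small_miss_p Given a miss, probability it is off by 1-2
#'   (otherwise 3-4).
#' @param count_missing_p Probability a mentioned situation states no
#'   count at all.
#' @param subjective_mean,subjective_sd Latent subjective-performance
#'   distribution on the 1-10 scale.
#' @param age Per-group mean/SD of age (years, truncated at 18).
#' @param female_p Per-group probability of female gender.
#' @param gaze List of gaze-stream parameters: `rate_hz`, `window_s`,
#'   `jitter_sd_deg`, `saccade_ms`, per-category fixation `duration_ms`
#'   means, `duration_sd_ms`, `duration_min_ms`, and AOI `dwell`
#'   proportions (including background).
#' @param missingness Completely-at-random per-indicator dropout rates
#'   (`gaze`, `triage`, `transmission`), emulating technical failures.
#' @param seed Integer seed; identical configurations and seeds give
#'   bit-identical cohorts.
#' @return A list of class `mci_generator_config`.
#' @export
generator_config <- function(
    n_mfr = 39, n_nonmfr = 37,
    knowledge = list(mfr = c(mean = 13.46, sd = 2.73),
                     nonmfr = c(mean = 10.89, sd = 3.70)),
    accuracy_p = c(mfr = 0.84, nonmfr = 0.77),
    accuracy_knowledge_slope = 0.017,
    accuracy_participant_sd = c(mfr = 0.087, nonmfr = 0.155),
    knowledge_accuracy_rho = 0.40,
    confusion_weights = c(0.80, 0.15, 0.05),
    speed_factor_mean = c(mfr = 0.95, nonmfr = 1.05),
    speed_factor_sd = 0.21,
    scenario_time_sdlog = 0.196,
    filler_meanlog = c(mfr = 2.60, nonmfr = 3.26),
    filler_sdlog_between = 0.44,
    filler_sdlog_within = 0.30,
    mention_p = c(mfr = 0.594, nonmfr = 0.572),
    mention_participant_sd = 0.18,
    scene_detail_p = 0.6,
    category_error_p = 0.15,
    count_correct_p = 0.75,
    count_small_miss_p = 0.9,
    count_missing_p = 0.03,
    subjective_mean = 6.77, subjective_sd = 1.13,
    age = list(mfr = c(mean = 27, sd = 7.15), nonmfr = c(mean = 24, sd = 4.07)),
    female_p = c(mfr = 0.28, nonmfr = 0.54),
    gaze = list(
      rate_hz = 200, window_s = 30, jitter_sd_deg = 0.05, saccade_ms = 40,
      duration_ms = c(patients = 400, safety = 320, vehicle_impact = 315,
                      distractor = 225, background = 300),
      duration_sd_ms = 90, duration_min_ms = 120,
      dwell = c(patients = 0.17, safety = 0.12, vehicle_impact = 0.12,
                distractor = 0.04, background = 0.55)
    ),
    missingness = c(gaze = 0, triage = 0, transmission = 0),
    seed = 1) {
  if (!is.numeric(n_mfr) || !is.numeric(n_nonmfr) || n_mfr < 1 || n_nonmfr < 1) {
    stop_config("group sizes n_mfr and n_nonmfr must be positive counts")
  }
  probs <- c(accuracy_p, mention_p, scene_detail_p, category_error_p,
             count_correct_p, count_small_miss_p, count_missing_p,
             female_p, missingness, gaze$dwell)
  if (any(probs < 0 | probs > 1)) {
    stop_config("all probabilities must lie in [0, 1]")
  }
  if (gaze$rate_hz <= 0) stop_config("gaze sampling rate must be positive")
  if (abs(knowledge_accuracy_rho) > 0.9) {
    stop_config("knowledge_accuracy_rho outside the attainable range for these marginals")
  }
  if (abs(sum(gaze$dwell) - 1) > 1e-8) {
    stop_config("gaze dwell proportions must sum to 1")
  }
  structure(
    list(
      n_mfr = n_mfr, n_nonmfr = n_nonmfr, knowledge = knowledge,
      accuracy_p = accuracy_p,
      accuracy_knowledge_slope = accuracy_knowledge_slope,
      accuracy_participant_sd = accuracy_participant_sd,
      knowledge_accuracy_rho = knowledge_accuracy_rho,
      confusion_weights = confusion_weights,
      speed_factor_mean = speed_factor_mean,
      speed_factor_sd = speed_factor_sd,
      scenario_time_sdlog = scenario_time_sdlog,
      filler_meanlog = filler_meanlog,
      filler_sdlog_between = filler_sdlog_between,
      filler_sdlog_within = filler_sdlog_within,
      mention_p = mention_p,
      mention_participant_sd = mention_participant_sd,
      scene_detail_p = scene_detail_p,
      category_error_p = category_error_p,
      count_correct_p = count_correct_p,
      count_small_miss_p = count_small_miss_p,
      count_missing_p = count_missing_p,
      subjective_mean = subjective_mean, subjective_sd = subjective_sd,
      age = age, female_p = female_p, gaze = gaze,
      missingness = missingness, seed = seed
    ),
    class = "mci_generator_config"
  )
}

group_value <- function(x, group) unname(x[[group]])

gen_participants <- function(config) {
  n <- config$n_mfr + config$n_nonmfr
  group <- rep(c("mfr", "nonmfr"), c(config$n_mfr, config$n_nonmfr))
  age <- vapply(group, function(g) {
    a <- config$age[[g]]
    round(rnorm_trunc(1, a[["mean"]], a[["sd"]], lo = 18, hi = 70))
  }, numeric(1))
  gender <- ifelse(
    stats::runif(n) < vapply(group, function(g) group_value(config$female_p, g), numeric(1)),
    "female", "male"
  )
  job_exp <- vapply(group, function(g) {
    if (g == "mfr") round(stats::rlnorm(1, 1.49, 0.88), 1) else round(stats::rlnorm(1, 0.04, 0.94), 1)
  }, numeric(1))
  band_probs <- list(
    mfr = c(3, 12, 7, 7, 2, 3, 2, 3) / 39,
    nonmfr = c(24, 11, 0, 1, 1, 0, 0, 0) / 37
  )
  training_band <- vapply(group, function(g) {
    sample.int(8, 1, prob = band_probs[[g]])
  }, integer(1))
  ivr_exp <- sample.int(9, n, replace = TRUE,
                        prob = c(45, 42, 6, 3, 2, 1, 0.5, 0.3, 0.2))

  # latent knowledge score and answers realizing it exactly
  test <- default_knowledge_test()
  key <- as.character(test$key)
  k_items <- length(key)
  knowledge_score <- unname(vapply(group, function(g) {
    kn <- config$knowledge[[g]]
    round(rnorm_trunc(1, kn[["mean"]], kn[["sd"]], lo = 0, hi = k_items))
  }, numeric(1)))
  answers <- purrr::map(knowledge_score, function(k) {
    ans <- key
    wrong_idx <- sample.int(k_items, k_items - k)
    for (i in wrong_idx) {
      ans[i] <- sample(setdiff(triage_colors(), key[i]), 1)
    }
    ans
  })

  mu_k <- vapply(group, function(g) config$knowledge[[g]][["mean"]], numeric(1))
  p_correct <- clamp(
    vapply(group, function(g) group_value(config$accuracy_p, g), numeric(1)) +
      config$accuracy_knowledge_slope * (knowledge_score - mu_k) +
      stats::rnorm(n, 0, vapply(group, function(g) group_value(config$accuracy_participant_sd, g), numeric(1))),
    0.02, 0.995
  )
  speed_factor <- rnorm_trunc(
    n,
    vapply(group, function(g) group_value(config$speed_factor_mean, g), numeric(1)),
    config$speed_factor_sd, lo = 0.35, hi = 2
  )
  # stable participant traits behind the radio messages
  word_offset <- stats::rnorm(n, 0, config$filler_sdlog_between)
  mention_prop <- clamp(
    vapply(group, function(g) group_value(config$mention_p, g), numeric(1)) +
      stats::rnorm(n, 0, config$mention_participant_sd),
    0.05, 0.95
  )
  tibble(
    participant_id = sprintf("P%03d", seq_len(n)),
    group = factor(group, levels = c("mfr", "nonmfr")),
    age = unname(age),
    gender = unname(gender),
    job_experience_years = unname(job_exp),
    prior_mci_training_band = unname(training_band),
    prior_ivr_experience = ivr_exp,
    knowledge_score = unname(as.integer(knowledge_score)),
    knowledge_answers = answers,
    latent_p_correct = unname(p_correct),
    latent_speed_factor = unname(speed_factor),
    latent_word_offset = word_offset,
    latent_mention_p = unname(mention_prop)
  )
}

wrong_color <- function(true, weights) {
  colors <- triage_colors()
  idx <- match(true, colors)
  others <- setdiff(seq_along(colors), idx)
  w <- weights[abs(others - idx)]
  others[sample.int(length(others), 1, prob = w)]
}

gen_triage_events <- function(participants, scenarios, config) {
  training <- scenarios[setdiff(names(scenarios), "familiarization")]
  n <- nrow(participants)
  colors <- triage_colors()
  purrr::map_dfr(training, function(sc) {
    roster <- sc$roster
    n_pat <- nrow(roster)
    total <- n * n_pat
    p_rep <- rep(participants$latent_p_correct, each = n_pat)
    true_idx <- rep(match(as.character(roster$true_color), colors), times = n)
    correct <- stats::runif(total) < p_rep
    assigned_idx <- true_idx
    wrong <- which(!correct)
    if (length(wrong)) {
      assigned_idx[wrong] <- vapply(
        true_idx[wrong],
        function(ti) wrong_color(colors[ti], config$confusion_weights),
        integer(1)
      )
    }
    total_s <- participants$latent_speed_factor * sc$mean_duration_min * 60 *
      stats::rlnorm(n, -config$scenario_time_sdlog^2 / 2, config$scenario_time_sdlog)
    frac <- matrix(stats::runif(n * (n_pat - 1), 0.08, 0.97), nrow = n)
    frac <- cbind(t(apply(frac, 1, sort)), 1)
    t_ms <- round(frac * total_s * 1000)
    # enforce strictly increasing timestamps within each log
    t_ms <- t_ms + t(apply(t_ms, 1, function(r) cumsum(c(0, as.integer(diff(r) <= 0)))))
    visit <- t(vapply(seq_len(n), function(i) sample.int(n_pat), integer(n_pat)))
    tibble(
      participant_id = rep(participants$participant_id, each = n_pat),
      scenario_id = sc$id,
      patient_id = roster$patient_id[as.vector(t(visit))],
      assigned_color = colors[assigned_idx[
        rep((seq_len(n) - 1) * n_pat, each = n_pat) + as.vector(t(visit))
      ]],
      t_ms = as.vector(t(t_ms))
    )
  })
}

#' Generate one synthetic radio message
#'
#' Draws a latent SSSS coding (category mentions, scene detail, errors and
#' the reported patient count) from the group's calibration, then realizes
#' it as a transcript built from the controlled phrase lexicon, padded with
#' filler tokens to the drawn word count.
#'
#' @param group `"mfr"` or `"nonmfr"`.
#' @param scenario An `mci_scenario` (for the true patient count).
#' @param config A [generator_config()].
#' @param seed Optional seed for a standalone, reproducible draw.
#' @return List with `text` and the one-row `coding` tibble (including
#'   `word_count_target`).
#' @export
generate_radio_message <- function(group, scenario, config = generator_config(),
                                   seed = NULL) {
  run <- function() gen_message(group, scenario, config)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# Vectorised message generator: one row per (participant, scenario).
# `pm` is the per-message mention probability, `meanlog`/`sdlog` the
# per-message lognormal filler-word parameters (participant traits already
# folded in by the caller); total length is core phrases plus filler.
gen_messages_df <- function(pm, meanlog, sdlog, scenario_id, true_n, config) {
  lx <- lexicon()
  n <- length(pm)
  scene_m <- stats::runif(n) < pm
  safety_m <- stats::runif(n) < pm
  situation_m <- stats::runif(n) < pm
  support_m <- stats::runif(n) < pm
  scene_detailed <- scene_m & stats::runif(n) < config$scene_detail_p
  scene_err <- as.integer(scene_m & stats::runif(n) < config$category_error_p)
  safety_err <- as.integer(safety_m & stats::runif(n) < config$category_error_p)
  support_err <- as.integer(support_m & stats::runif(n) < config$category_error_p)

  count_present <- situation_m & stats::runif(n) >= config$count_missing_p
  count_exact <- stats::runif(n) < config$count_correct_p
  mag <- ifelse(stats::runif(n) < config$count_small_miss_p,
                sample(1:2, n, replace = TRUE), sample(3:4, n, replace = TRUE))
  sgn <- sample(c(-1L, 1L), n, replace = TRUE)
  reported <- ifelse(
    !count_present, NA_integer_,
    ifelse(count_exact, true_n, pmax(0L, true_n + sgn * mag))
  )

  scen_idx <- match(scenario_id, as.character(1:5))
  scen_idx[is.na(scen_idx)] <- 1L
  piece <- function(cond, txt) ifelse(cond, txt, "")
  core <- paste(
    piece(scene_m, lx$scene_base),
    piece(scene_detailed, lx$scene_detail[scen_idx]),
    piece(scene_err > 0, lx$scene_error[1]),
    piece(safety_m, lx$safety_base[1 + scen_idx %% 3]),
    piece(safety_err > 0, lx$safety_error[1]),
    ifelse(!situation_m, "",
           ifelse(count_present, sprintf(lx$situation_count, reported),
                  lx$situation_nocount)),
    piece(support_m, lx$support_base),
    piece(support_err > 0, lx$support_error[1])
  )
  core <- stringr::str_squish(core)
  core_n <- count_words(core)
  target <- pmax(core_n + round(stats::rlnorm(n, meanlog, sdlog)), core_n, 3L)
  n_fill <- target - core_n
  fill <- vapply(n_fill, function(k) {
    if (k <= 0) "" else paste(sample(lx$filler, k, replace = TRUE), collapse = " ")
  }, character(1))
  text <- stringr::str_squish(paste(core, fill))
  tibble(
    text = text,
    scene_mentioned = scene_m, scene_detailed = scene_detailed,
    scene_errors = scene_err,
    safety_mentioned = safety_m, safety_errors = safety_err,
    situation_mentioned = situation_m,
    reported_patient_count = as.integer(reported),
    support_mentioned = support_m, support_errors = support_err,
    word_count_target = as.integer(target)
  )
}

gen_message <- function(group, scenario, config) {
  row <- gen_messages_df(
    pm = group_value(config$mention_p, group),
    meanlog = group_value(config$filler_meanlog, group),
    sdlog = sqrt(config$filler_sdlog_between^2 + config$filler_sdlog_within^2),
    scenario$id, nrow(scenario$roster), config
  )
  list(text = row$text, coding = row[, setdiff(names(row), "text")])
}

gen_transcripts <- function(participants, scenarios, config) {
  training <- scenarios[setdiff(names(scenarios), "familiarization")]
  grid <- tidyr::expand_grid(
    i = seq_len(nrow(participants)),
    scenario_id = names(training)
  )
  true_n <- vapply(training, function(sc) nrow(sc$roster), integer(1))
  group <- as.character(participants$group)[grid$i]
  rows <- dplyr::bind_cols(
    tibble(
      participant_id = participants$participant_id[grid$i],
      scenario_id = grid$scenario_id
    ),
    gen_messages_df(
      pm = participants$latent_mention_p[grid$i],
      meanlog = unname(unlist(config$filler_meanlog)[group]) +
        participants$latent_word_offset[grid$i],
      sdlog = config$filler_sdlog_within,
      grid$scenario_id,
      unname(true_n[grid$scenario_id]),
      config
    )
  )
  list(
    transcripts = rows[, c("participant_id", "scenario_id", "text")],
    latent_codings = rows[, setdiff(names(rows), "text")]
  )
}

gen_subjective <- function(participants, scenarios, config) {
  training_ids <- setdiff(names(scenarios), "familiarization")
  n <- nrow(participants)
  # Split the subjective variance into a stable participant component and
  # per-scenario item noise so that the composite's cross-participant SD
  # matches `subjective_sd` while the 5-scenario internal consistency sits
  # near the observed standardized alpha of ~0.86 (between share 0.55 of
  # the per-scenario variance).
  b <- config$subjective_sd * 0.928
  item_noise <- b * 0.903 * sqrt(2)
  purrr::map_dfr(seq_len(n), function(i) {
    latent <- stats::rnorm(1, config$subjective_mean, b)
    item1 <- round(clamp(latent + stats::rnorm(length(training_ids), 0, item_noise), 1, 10))
    g_target <- clamp(latent + stats::rnorm(length(training_ids), 0, item_noise), 1, 10)
    grade <- round(clamp((10 - g_target) / 1.8 + 1, 1, 6))
    tibble(
      participant_id = participants$participant_id[i],
      scenario_id = training_ids,
      item_rating = item1,
      grade = grade
    )
  })
}

#' Generate one synthetic gaze stream
#'
#' Builds an orientation-window gaze stream as a latent sequence of
#' fixations (dwells at points sampled inside AOI polygons or in the
#' background, with small isotropic jitter) joined by short saccade
#' sweeps. Consecutive fixation centres are kept at least two dispersion
#' thresholds apart so that, with zero jitter, the I-DT detector recovers
#' the latent fixation list exactly.
#'
#' @param scenario An `mci_scenario` with AOI geometry.
#' @param config A [generator_config()].
#' @param seed Optional seed for a standalone draw.
#' @return List with `stream` (tibble `t_ms`, `x_deg`, `y_deg`, `valid`)
#'   and `fixations` (latent event list with `category`).
#' @export
generate_gaze_stream <- function(scenario, config = generator_config(),
                                 seed = NULL) {
  run <- function() gen_gaze(scenario, config)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

gen_gaze <- function(scenario, config) {
  g <- config$gaze
  aois <- scenario$aois
  window_ms <- g$window_s * 1000
  step_ms <- 1000 / g$rate_hz
  present <- intersect(names(g$dwell), c(unique(aois$category), "background"))
  dwell <- g$dwell[present]
  dwell <- dwell / sum(dwell)

  sample_point <- function(category, prev) {
    for (try in 1:40) {
      if (category == "background") {
        pt <- c(stats::runif(1, -175, 175), stats::runif(1, -38, 38))
        inside_any <- nrow(aois) > 0 && any(vapply(
          aois$vertices, function(v) mgcv::in.out(v, rbind(pt)), logical(1)
        ))
        if (inside_any) next
      } else {
        polys <- which(aois$category == category)
        k <- polys[sample.int(length(polys), 1)]
        v <- aois$vertices[[k]]
        repeat {
          pt <- c(stats::runif(1, min(v[, 1]), max(v[, 1])),
                  stats::runif(1, min(v[, 2]), max(v[, 2])))
          # keep a 1 degree margin so jitter and window-boundary effects
          # cannot push the detected centroid outside the polygon
          probe <- rbind(pt, pt + c(1, 0), pt - c(1, 0),
                         pt + c(0, 1), pt - c(0, 1))
          if (all(mgcv::in.out(v, probe))) break
        }
      }
      if (is.null(prev) || sqrt(sum((pt - prev)^2)) > 2.5) return(pt)
    }
    pt
  }

  # the timeline advances on the sampling grid: fixations and saccade
  # sweeps occupy whole numbers of samples
  n_total <- round(g$window_s * g$rate_hz)
  n_sac <- max(2L, round(g$saccade_ms / step_ms))
  i <- 0L # next free sample index
  prev <- NULL
  ts_l <- list(); x_l <- list(); y_l <- list()
  f_start <- numeric(); f_end <- numeric(); f_x <- numeric(); f_y <- numeric()
  f_cat <- character()
  k <- 0L
  while (i < n_total) {
    category <- sample(names(dwell), 1, prob = dwell)
    centre <- sample_point(category, prev)
    if (!is.null(prev)) {
      idx <- i + seq_len(n_sac) - 1L
      idx <- idx[idx < n_total]
      if (length(idx)) {
        frac <- seq_along(idx) / (n_sac + 1)
        k <- k + 1L
        ts_l[[k]] <- idx * step_ms
        x_l[[k]] <- prev[1] + frac * (centre[1] - prev[1])
        y_l[[k]] <- prev[2] + frac * (centre[2] - prev[2])
      }
      i <- i + n_sac
      if (i >= n_total) break
    }
    dur <- rnorm_trunc(1, g$duration_ms[[category]], g$duration_sd_ms,
                       lo = g$duration_min_ms, hi = 1500)
    n_fix <- min(max(2L, round(dur / step_ms)), n_total - i)
    idx <- i + seq_len(n_fix) - 1L
    ts <- idx * step_ms
    k <- k + 1L
    ts_l[[k]] <- ts
    x_l[[k]] <- centre[1] + stats::rnorm(n_fix, 0, g$jitter_sd_deg)
    y_l[[k]] <- centre[2] + stats::rnorm(n_fix, 0, g$jitter_sd_deg)
    realized <- ts[n_fix] - ts[1]
    if (realized >= g$duration_min_ms) {
      f_start <- c(f_start, ts[1]); f_end <- c(f_end, ts[n_fix])
      f_x <- c(f_x, centre[1]); f_y <- c(f_y, centre[2])
      f_cat <- c(f_cat, category)
    }
    prev <- centre
    i <- i + n_fix
  }
  stream <- tibble(
    t_ms = unlist(ts_l), x_deg = unlist(x_l), y_deg = unlist(y_l),
    valid = TRUE
  )
  fixations <- tibble(
    start_ms = f_start, end_ms = f_end, duration_ms = f_end - f_start,
    x_deg = f_x, y_deg = f_y, category = f_cat
  )
  list(stream = stream, fixations = fixations)
}

gen_gaze_all <- function(participants, scenarios, config) {
  training <- scenarios[setdiff(names(scenarios), "familiarization")]
  purrr::map_dfr(participants$participant_id, function(pid) {
    purrr::map_dfr(training, function(sc) {
      gz <- gen_gaze(sc, config)
      tibble(
        participant_id = pid,
        scenario_id = sc$id,
        stream = list(gz$stream),
        latent_fixations = list(gz$fixations)
      )
    })
  })
}

#' Generate a synthetic study cohort
#'
#' Produces the full bundle deterministically from the configuration seed:
#' a participant table, triage event logs, radio-message transcripts with
#' their latent codings, subjective ratings, and gaze streams with latent
#' fixation lists. Components can be switched off via `include` when only
#' part of the study is needed.
#'
#' @param config A [generator_config()].
#' @param include Character subset of
#'   `c("triage", "transmission", "subjective", "gaze")`; the participant
#'   table (with knowledge scores) is always generated.
#' @param scenarios Scenario list (default [default_scenarios()]).
#' @return A list of class `mci_cohort`.
#' @export
generate_cohort <- function(config = generator_config(),
                            include = c("triage", "transmission",
                                        "subjective", "gaze"),
                            scenarios = default_scenarios()) {
  if (!inherits(config, "mci_generator_config")) {
    stop_config("`config` must be created with generator_config()")
  }
  if (length(include)) {
    include <- match.arg(include, several.ok = TRUE)
  } else {
    include <- character()
  }
  withr::with_seed(config$seed, {
    participants <- gen_participants(config)
    out <- list(
      participants = participants,
      scenarios = scenarios,
      config = config
    )
    if ("triage" %in% include) {
      out$triage_events <- gen_triage_events(participants, scenarios, config)
    }
    if ("transmission" %in% include) {
      tr <- gen_transcripts(participants, scenarios, config)
      out$transcripts <- tr$transcripts
      out$latent_codings <- tr$latent_codings
    }
    if ("subjective" %in% include) {
      out$subjective <- gen_subjective(participants, scenarios, config)
    }
    if ("gaze" %in% include) {
      out$gaze <- gen_gaze_all(participants, scenarios, config)
    }
    out <- apply_missingness(out, config)
    structure(out, class = "mci_cohort")
  })
}

# Completely-at-random per-indicator dropout.
apply_missingness <- function(out, config) {
  m <- config$missingness
  ids <- out$participants$participant_id
  drop_ids <- function(rate) {
    n_drop <- round(rate * length(ids))
    if (n_drop == 0) character() else sample(ids, n_drop)
  }
  if (!is.null(out$triage_events) && m[["triage"]] > 0) {
    gone <- drop_ids(m[["triage"]])
    out$triage_events <- dplyr::filter(out$triage_events, !.data$participant_id %in% gone)
  }
  if (!is.null(out$transcripts) && m[["transmission"]] > 0) {
    gone <- drop_ids(m[["transmission"]])
    out$transcripts <- dplyr::filter(out$transcripts, !.data$participant_id %in% gone)
    out$latent_codings <- dplyr::filter(out$latent_codings, !.data$participant_id %in% gone)
  }
  if (!is.null(out$gaze) && m[["gaze"]] > 0) {
    gone <- drop_ids(m[["gaze"]])
    out$gaze <- dplyr::filter(out$gaze, !.data$participant_id %in% gone)
  }
  out
}

#' @export
print.mci_cohort <- function(x, ...) {
  cat(
    "<mci_cohort> ", nrow(x$participants), " participants (",
    sum(x$participants$group == "mfr"), " MFR / ",
    sum(x$participants$group == "nonmfr"), " non-MFR), components: ",
    paste(intersect(
      c("triage_events", "transcripts", "subjective", "gaze"), names(x)
    ), collapse = ", "), "\n",
    sep = ""
  )
  invisible(x)
}
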