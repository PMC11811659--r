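#' @title Known-groups validation battery
#' @description
#' Orchestrates the full inference battery over the participant-level
#' indicator table: winsorization, assumption gates (Levene variance test
#' deciding Welch vs Student, Shapiro-Wilk recorded), MANOVAs for the two
#' gaze indicator families, directional t tests for accuracy, speed and
#' efficiency with Holm correction over the three tests, the knowledge
#' known-groups test, Spearman correlations of the knowledge score and the
#' subjective composite with the indicators, the centered bootstrap
#' regression of accuracy on knowledge, and per-indicator standardized
#' Cronbach's alpha.
#' @name battery
NULL

#' Battery configuration
#'
#' @param winsorize Clamp outliers at mean +/- `k` SD before testing.
#' @param k Winsorization width in SDs.
#' @param tail `"one"` (directional hypotheses for accuracy, speed and
#'   efficiency: MFRs better) or `"two"`.
#' @param levene_alpha Significance level of the Levene gate that switches
#'   a test from Student to Welch.
#' @param n_boot Bootstrap draws for the regression CI.
#' @param seed Seed for the bootstrap.
#' @return List of class `mci_battery_config`.
#' @export
battery_config <- function(winsorize = TRUE, k = 3, tail = c("one", "two"),
                           levene_alpha = 0.05, n_boot = 5000, seed = 1) {
  tail <- match.arg(tail)
  structure(
    list(winsorize = winsorize, k = k, tail = tail,
         levene_alpha = levene_alpha, n_boot = n_boot, seed = seed),
    class = "mci_battery_config"
  )
}

battery_indicators <- function(indicators) {
  grep("^(accuracy|std_speed|efficiency|subjective|doaf_|fc_)",
       names(indicators), value = TRUE)
}

#' Run the known-groups validation battery
#'
#' @param indicators Participant-level indicator tibble with columns
#'   `participant_id`, `group` (`"mfr"`/`"nonmfr"`), `knowledge_score`,
#'   `accuracy`, `std_speed`, `efficiency`, `subjective`, and optionally
#'   `age`, `gender`, `doaf_*` and `fc_*` columns.
#' @param per_scenario Optional tibble with `participant_id`,
#'   `scenario_id` and per-scenario indicator columns, used for the
#'   standardized Cronbach's alpha block.
#' @param config A [battery_config()].
#' @return List of class `mci_battery` with blocks `t_tests` (the three
#'   Holm-corrected hypothesis tests), `knowledge_test`, `manova`,
#'   `spearman`, `regression`, `alphas`, `assumptions` and `ns`.
#' @export
run_battery <- function(indicators, per_scenario = NULL,
                        config = battery_config()) {
  required <- c("participant_id", "group", "knowledge_score", "accuracy",
                "std_speed", "efficiency", "subjective")
  missing <- setdiff(required, names(indicators))
  if (length(missing)) {
    stop_input(paste0(
      "indicator table is missing column(s): ", paste(missing, collapse = ", ")
    ))
  }
  ind <- indicators
  ind$group <- factor(ind$group, levels = c("mfr", "nonmfr"))
  cols <- battery_indicators(ind)
  if (config$winsorize) {
    ind[cols] <- lapply(ind[cols], winsorize, k = config$k)
  }

  # assumption gates per univariate hypothesis indicator
  hyp <- tibble(
    indicator = c("accuracy", "std_speed", "efficiency"),
    # directional expectations: MFRs more accurate, faster (smaller
    # standardized speed), more efficient
    alternative = c("greater", "less", "greater")
  )
  assumptions <- purrr::map_dfr(c(hyp$indicator, "knowledge_score"), function(v) {
    d <- ind[!is.na(ind[[v]]), c(v, "group")]
    lev <- car::leveneTest(d[[v]] ~ d$group)
    sw <- d |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(p = stats::shapiro.test(.data[[v]])$p.value, .groups = "drop")
    tibble(
      indicator = v,
      levene_p = lev[["Pr(>F)"]][1],
      shapiro_p_mfr = sw$p[sw$group == "mfr"],
      shapiro_p_nonmfr = sw$p[sw$group == "nonmfr"]
    )
  })

  run_one <- function(v, alternative) {
    d <- ind[!is.na(ind[[v]]), c(v, "group")]
    x <- d[[v]][d$group == "mfr"]
    y <- d[[v]][d$group == "nonmfr"]
    lev_p <- assumptions$levene_p[assumptions$indicator == v]
    variant <- if (lev_p < config$levene_alpha) "welch" else "student"
    tt <- group_t_test(x, y, variant = variant, tail = config$tail,
                       alternative = alternative)
    dplyr::bind_cols(
      tibble(indicator = v, n_mfr = length(x), n_nonmfr = length(y)),
      tt,
      tibble(cohen_d = cohen_d_from_t(tt$statistic, length(x), length(y)))
    )
  }
  t_tests <- purrr::map2_dfr(hyp$indicator, hyp$alternative, run_one)
  t_tests$p_holm <- holm_adjust(t_tests$p_value)

  kx <- ind$knowledge_score[ind$group == "mfr"]
  ky <- ind$knowledge_score[ind$group == "nonmfr"]
  ktt <- group_t_test(kx, ky, variant = "welch", tail = "two")
  knowledge_test <- dplyr::bind_cols(
    tibble(indicator = "knowledge_score", n_mfr = length(kx), n_nonmfr = length(ky)),
    ktt,
    tibble(cohen_d = cohen_d_from_t(ktt$statistic, length(kx), length(ky)))
  )

  # MANOVAs over the gaze indicator families (complete cases per family)
  manova_block <- purrr::map_dfr(c("doaf", "fc"), function(fam) {
    fam_cols <- grep(paste0("^", fam, "_"), names(ind), value = TRUE)
    fam_cols <- setdiff(fam_cols, paste0(fam, "_background"))
    if (!length(fam_cols)) return(tibble())
    cc <- stats::complete.cases(ind[fam_cols])
    res <- manova_pillai(ind[cc, fam_cols], ind$group[cc])
    dplyr::bind_cols(tibble(family = fam), res)
  })

  # Spearman tables: knowledge vs indicators, subjective vs objective
  objective <- setdiff(cols, "subjective")
  spearman <- dplyr::bind_rows(
    purrr::map_dfr(objective, function(v) {
      dplyr::bind_cols(
        tibble(x = "knowledge_score", y = v),
        spearman_rho(ind$knowledge_score, ind[[v]])
      )
    }),
    purrr::map_dfr(objective, function(v) {
      dplyr::bind_cols(
        tibble(x = "subjective", y = v),
        spearman_rho(ind$subjective, ind[[v]])
      )
    })
  )

  regression <- NULL
  if (all(c("age", "gender") %in% names(ind))) {
    regression <- regression_accuracy(ind, n_boot = config$n_boot,
                                      seed = config$seed)
  }

  alphas <- NULL
  if (!is.null(per_scenario)) {
    alpha_cols <- setdiff(names(per_scenario), c("participant_id", "scenario_id"))
    alphas <- purrr::map_dfr(alpha_cols, function(v) {
      wide <- per_scenario |>
        dplyr::select("participant_id", "scenario_id", dplyr::all_of(v)) |>
        tidyr::pivot_wider(names_from = "scenario_id", values_from = dplyr::all_of(v))
      tibble(
        indicator = v,
        alpha = cronbach_alpha_standardized(wide[, -1])
      )
    })
  }

  structure(
    list(
      t_tests = t_tests,
      knowledge_test = knowledge_test,
      manova = manova_block,
      spearman = spearman,
      regression = regression,
      alphas = alphas,
      assumptions = assumptions,
      ns = purrr::map_int(stats::setNames(cols, cols), ~ sum(!is.na(ind[[.x]]))),
      config = config
    ),
    class = "mci_battery"
  )
}

#' @export
print.mci_battery <- function(x, ...) {
  cat("<mci_battery> known-groups validation report\n\n")
  cat("Holm-corrected hypothesis tests (MFR vs non-MFR):\n")
  print(as.data.frame(x$t_tests[, c("indicator", "variant", "statistic", "df",
                                    "p_value", "p_holm", "cohen_d")]),
        digits = 3, row.names = FALSE)
  cat("\nKnowledge-score known-groups test:\n")
  print(as.data.frame(x$knowledge_test[, c("statistic", "df", "p_value", "cohen_d")]),
        digits = 3, row.names = FALSE)
  if (nrow(x$manova)) {
    cat("\nGaze MANOVAs (Pillai):\n")
    print(as.data.frame(x$manova), digits = 3, row.names = FALSE)
  }
  if (!is.null(x$alphas)) {
    cat("\nStandardized Cronbach alpha:\n")
    print(as.data.frame(x$alphas), digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' Score a synthetic (or imported) cohort into the indicator table
#'
#' Runs all scoring pipelines present in the cohort bundle: knowledge-test
#' scoring, triage accuracy and standardized speed, transmission coding
#' and efficiency, the subjective composite, and the gaze indicators.
#'
#' @param cohort An `mci_cohort` bundle.
#' @param gaze Set `FALSE` to skip the (comparatively slow) gaze scoring
#'   even when streams are present.
#' @return List with `indicators` (one row per participant) and
#'   `per_scenario` (per-scenario accuracy, time, efficiency, subjective
#'   composite, for the reliability block).
#' @export
score_cohort <- function(cohort, gaze = TRUE) {
  participants <- cohort$participants
  test <- default_knowledge_test()
  indicators <- participants |>
    dplyr::mutate(
      knowledge_score = purrr::map_int(
        .data$knowledge_answers, ~ as.integer(score_knowledge_test(.x, test))
      )
    ) |>
    dplyr::select(
      "participant_id", "group", "age", "gender", "knowledge_score"
    )
  per_scenario <- tibble(
    participant_id = rep(participants$participant_id,
                         each = length(cohort$scenarios) - 1),
    scenario_id = rep(setdiff(names(cohort$scenarios), "familiarization"),
                      nrow(participants))
  )
  if (!is.null(cohort$triage_events)) {
    ts <- triage_scores(cohort$triage_events, cohort$scenarios)
    indicators <- dplyr::left_join(indicators, ts$participants,
                                   by = "participant_id")
    per_scenario <- dplyr::left_join(
      per_scenario,
      ts$per_scenario[, c("participant_id", "scenario_id", "accuracy", "time_s")],
      by = c("participant_id", "scenario_id")
    )
  }
  if (!is.null(cohort$transcripts)) {
    tr <- transmission_scores(cohort$transcripts, cohort$scenarios)
    indicators <- dplyr::left_join(
      indicators,
      tr$participants[, c("participant_id", "transmission_total", "efficiency",
                          "word_count")],
      by = "participant_id"
    )
    per_scenario <- dplyr::left_join(
      per_scenario,
      tr$per_message[, c("participant_id", "scenario_id", "efficiency")] |>
        dplyr::rename(efficiency_scenario = "efficiency"),
      by = c("participant_id", "scenario_id")
    )
  }
  if (!is.null(cohort$subjective)) {
    subj <- cohort$subjective |>
      dplyr::mutate(composite = subjective_composite(.data$item_rating, .data$grade))
    indicators <- dplyr::left_join(
      indicators,
      subj |>
        dplyr::group_by(.data$participant_id) |>
        dplyr::summarise(subjective = mean(.data$composite), .groups = "drop"),
      by = "participant_id"
    )
    per_scenario <- dplyr::left_join(
      per_scenario,
      subj[, c("participant_id", "scenario_id", "composite")] |>
        dplyr::rename(subjective_scenario = "composite"),
      by = c("participant_id", "scenario_id")
    )
  }
  if (isTRUE(gaze) && !is.null(cohort$gaze)) {
    gz <- cohort$gaze |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::group_modify(~ gaze_indicators(.x, cohort$scenarios)) |>
      dplyr::ungroup()
    indicators <- dplyr::left_join(indicators, gz, by = "participant_id")
  }
  list(indicators = indicators, per_scenario = per_scenario)
}
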