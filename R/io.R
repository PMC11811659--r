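#' @title Study directory I/O
#' @description
#' A simulated study is materialized as a self-contained directory of
#' plain-text files: `participants.csv`, `triage_events.csv`,
#' `transcripts.jsonl`, `subjective.csv`, per-participant gaze CSVs under
#' `gaze/`, the scenario JSONs under `scenarios/`, and a `manifest.json`
#' recording the seed, the configuration hash and the package version.
#' The same formats are read back by the scoring entry points, so the
#' full pipeline (simulate, score, analyze) round-trips through disk.
#' @name study-io
NULL

config_hash <- function(config) rlang::hash(unclass(config))

#' Write a cohort bundle to a study directory
#'
#' @param cohort An `mci_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop_input(paste0("cannot create study directory: ", dir))
  p <- cohort$participants
  p$knowledge_answers <- vapply(p$knowledge_answers, paste, character(1), collapse = ";")
  utils::write.csv(p, file.path(dir, "participants.csv"), row.names = FALSE)
  if (!is.null(cohort$triage_events)) {
    utils::write.csv(cohort$triage_events, file.path(dir, "triage_events.csv"),
                     row.names = FALSE)
  }
  if (!is.null(cohort$transcripts)) {
    con <- file(file.path(dir, "transcripts.jsonl"), "w")
    for (i in seq_len(nrow(cohort$transcripts))) {
      writeLines(jsonlite::toJSON(as.list(cohort$transcripts[i, ]),
                                  auto_unbox = TRUE), con)
    }
    close(con)
  }
  if (!is.null(cohort$subjective)) {
    utils::write.csv(cohort$subjective, file.path(dir, "subjective.csv"),
                     row.names = FALSE)
  }
  if (!is.null(cohort$gaze)) {
    gdir <- file.path(dir, "gaze")
    dir.create(gdir, showWarnings = FALSE)
    purrr::pwalk(
      list(cohort$gaze$participant_id, cohort$gaze$scenario_id,
           cohort$gaze$stream),
      function(pid, sid, st) {
        utils::write.csv(
          st, file.path(gdir, paste0(pid, "_scenario-", sid, ".csv")),
          row.names = FALSE
        )
      }
    )
  }
  sdir <- file.path(dir, "scenarios")
  dir.create(sdir, showWarnings = FALSE)
  purrr::walk(cohort$scenarios, function(sc) {
    write_scenario_json(sc, file.path(sdir, paste0("scenario-", sc$id, ".json")))
  })
  manifest <- list(
    package = "mcitriage",
    version = as.character(utils::packageVersion("mcitriage")),
    seed = cohort$config$seed,
    config_hash = config_hash(cohort$config),
    n_participants = nrow(cohort$participants)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a study directory back into a cohort bundle
#'
#' Partially complete directories are allowed: absent components simply
#' stay absent from the bundle, and missing gaze files for individual
#' participants yield missing gaze indicators downstream (per-measure
#' exclusion).
#'
#' @param dir Study directory written by [write_study()].
#' @return An `mci_cohort` (without latent generator state).
#' @export
read_study <- function(dir) {
  pfile <- file.path(dir, "participants.csv")
  if (!file.exists(pfile)) {
    stop_format(paste0(dir, ": not a study directory (no participants.csv)"))
  }
  p <- utils::read.csv(pfile, stringsAsFactors = FALSE)
  p$knowledge_answers <- lapply(strsplit(p$knowledge_answers, ";"), identity)
  p <- as_tibble(p)
  p$group <- factor(p$group, levels = c("mfr", "nonmfr"))
  sdir <- file.path(dir, "scenarios")
  scenarios <- if (dir.exists(sdir)) {
    files <- list.files(sdir, pattern = "^scenario-.*\\.json$", full.names = TRUE)
    sc <- purrr::map(files, load_scenario)
    names(sc) <- purrr::map_chr(sc, "id")
    sc[order(match(names(sc), c("familiarization", as.character(1:5))))]
  } else {
    default_scenarios()
  }
  out <- list(participants = p, scenarios = scenarios,
              config = list(seed = NA_integer_))
  ev <- file.path(dir, "triage_events.csv")
  if (file.exists(ev)) {
    out$triage_events <- as_tibble(utils::read.csv(ev, stringsAsFactors = FALSE)) |>
      dplyr::mutate(scenario_id = as.character(.data$scenario_id))
  }
  tj <- file.path(dir, "transcripts.jsonl")
  if (file.exists(tj)) {
    lines <- readLines(tj)
    out$transcripts <- purrr::map_dfr(seq_along(lines), function(i) {
      row <- tryCatch(
        jsonlite::fromJSON(lines[i]),
        error = function(e) stop_format(paste0(tj, " line ", i, ": invalid JSON"))
      )
      as_tibble(row[c("participant_id", "scenario_id", "text")])
    })
  }
  sj <- file.path(dir, "subjective.csv")
  if (file.exists(sj)) {
    out$subjective <- as_tibble(utils::read.csv(sj, stringsAsFactors = FALSE)) |>
      dplyr::mutate(scenario_id = as.character(.data$scenario_id))
  }
  gdir <- file.path(dir, "gaze")
  if (dir.exists(gdir)) {
    files <- list.files(gdir, pattern = "\\.csv$", full.names = TRUE)
    if (length(files)) {
      meta <- stringr::str_match(basename(files), "^(.*)_scenario-(.*)\\.csv$")
      out$gaze <- tibble(
        participant_id = meta[, 2],
        scenario_id = meta[, 3],
        stream = purrr::map(files, ~ as_tibble(utils::read.csv(.x)))
      )
    }
  }
  structure(out, class = "mci_cohort")
}

#' Simulate a study and write it to disk
#'
#' @param dir Output directory.
#' @param config A [generator_config()].
#' @param include Components to generate (see [generate_cohort()]).
#' @return The cohort bundle, invisibly.
#' @export
simulate_study <- function(dir, config = generator_config(),
                           include = c("triage", "transmission",
                                       "subjective", "gaze")) {
  cohort <- generate_cohort(config, include = include)
  write_study(cohort, dir)
  invisible(cohort)
}

#' Score a study directory into the indicator table
#'
#' @param dir Study directory.
#' @param out Optional path for an `indicators.csv` copy.
#' @return See [score_cohort()].
#' @export
score_study <- function(dir, out = NULL) {
  cohort <- read_study(dir)
  scores <- score_cohort(cohort)
  if (!is.null(out)) {
    utils::write.csv(scores$indicators, out, row.names = FALSE)
  }
  scores
}

#' Analyze an indicator table and serialize the report
#'
#' Runs [run_battery()] and optionally writes the report as JSON plus a
#' human-readable TSV of the hypothesis tests.
#'
#' @param scores Output of [score_cohort()]/[score_study()], or an
#'   indicator tibble.
#' @param config A [battery_config()].
#' @param out_json,out_tsv Optional output paths.
#' @return The `mci_battery` report.
#' @export
analyze_study <- function(scores, config = battery_config(),
                          out_json = NULL, out_tsv = NULL) {
  if (is.data.frame(scores)) scores <- list(indicators = scores, per_scenario = NULL)
  report <- run_battery(scores$indicators, scores$per_scenario, config)
  if (!is.null(out_json)) {
    serializable <- list(
      t_tests = report$t_tests,
      knowledge_test = report$knowledge_test,
      manova = report$manova,
      spearman = report$spearman,
      regression = if (!is.null(report$regression)) {
        list(
          coefficients = report$regression$coefficients,
          r_squared = report$regression$r_squared,
          adj_r_squared = report$regression$adj_r_squared,
          f_statistic = report$regression$f_statistic,
          df = report$regression$df, n = report$regression$n
        )
      },
      alphas = report$alphas,
      assumptions = report$assumptions,
      winsorized = config$winsorize,
      seed = config$seed
    )
    jsonlite::write_json(serializable, out_json, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  if (!is.null(out_tsv)) {
    utils::write.table(tidy(report), out_tsv, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  report
}
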