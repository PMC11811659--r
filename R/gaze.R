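#' @title Gaze pipeline: fixation detection and AOI attention metrics
#' @description
#' Raw gaze streams are timestamped (t_ms) angular gaze directions
#' (x_deg = yaw, y_deg = pitch) on a scenario-fixed panorama plane, sampled
#' nominally at 200 Hz. Fixations are detected with the dispersion-threshold
#' (I-DT) algorithm, assigned to AOI categories by centroid location, and
#' aggregated into the two attention indicators: duration of average
#' fixation (DOAF, ms) and fixation count (FC), each first computed per
#' scenario and then averaged across the scenarios in which the category
#' has an AOI.
#' @name gaze
NULL

#' Clip a gaze stream to the orientation window
#'
#' Keeps only the initial orientation phase of a scenario (by default the
#' first 30 s), during which participants stay at the starting position and
#' look around. Samples at or beyond the boundary are dropped, so fixations
#' straddling it are truncated there.
#'
#' @param stream Tibble with columns `t_ms`, `x_deg`, `y_deg` and
#'   optionally `valid`.
#' @param window_s Window length in seconds.
#' @return The clipped stream.
#' @export
clip_to_orientation_window <- function(stream, window_s = 30) {
  dplyr::filter(stream, .data$t_ms < window_s * 1000)
}

#' Detect fixations with the I-DT dispersion-threshold algorithm
#'
#' Scans the stream left to right for maximal windows whose dispersion --
#' the larger of the x-range and the y-range of the member samples -- stays
#' within `max_dispersion_deg` and whose duration reaches
#' `min_duration_ms`. Windows are non-overlapping; each is extended as far
#' right as the dispersion allows before being emitted. Invalid samples
#' (`valid == FALSE`) are discarded first.
#'
#' @param stream Tibble with `t_ms`, `x_deg`, `y_deg`, optional `valid`.
#' @param max_dispersion_deg Dispersion threshold in degrees.
#' @param min_duration_ms Minimum fixation duration in milliseconds.
#' @return Tibble of fixations: `start_ms`, `end_ms`, `duration_ms`,
#'   `centroid_x`, `centroid_y`, `n_samples`. Empty input gives an empty
#'   tibble.
#' @export
detect_fixations <- function(stream, max_dispersion_deg = 1,
                             min_duration_ms = 100) {
  empty <- tibble(
    start_ms = numeric(), end_ms = numeric(), duration_ms = numeric(),
    centroid_x = numeric(), centroid_y = numeric(), n_samples = integer()
  )
  if (!nrow(stream)) return(empty)
  if ("valid" %in% names(stream)) stream <- stream[stream$valid, , drop = FALSE]
  if (!nrow(stream)) return(empty)
  t <- stream$t_ms
  if (is.unsorted(t)) stop_input("gaze stream must be sorted by t_ms")
  x <- stream$x_deg
  y <- stream$y_deg
  n <- length(t)

  fix_start <- integer()
  fix_end <- integer()
  i <- 1L
  while (i <= n) {
    # grow the window while dispersion stays within threshold
    xmin <- x[i]; xmax <- x[i]; ymin <- y[i]; ymax <- y[i]
    j <- i
    while (j < n) {
      nxmin <- min(xmin, x[j + 1L]); nxmax <- max(xmax, x[j + 1L])
      nymin <- min(ymin, y[j + 1L]); nymax <- max(ymax, y[j + 1L])
      if (max(nxmax - nxmin, nymax - nymin) > max_dispersion_deg) break
      xmin <- nxmin; xmax <- nxmax; ymin <- nymin; ymax <- nymax
      j <- j + 1L
    }
    if (t[j] - t[i] >= min_duration_ms) {
      fix_start <- c(fix_start, i)
      fix_end <- c(fix_end, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(fix_start)) return(empty)
  tibble(
    start_ms = t[fix_start],
    end_ms = t[fix_end],
    duration_ms = t[fix_end] - t[fix_start],
    centroid_x = purrr::map2_dbl(fix_start, fix_end, ~ mean(x[.x:.y])),
    centroid_y = purrr::map2_dbl(fix_start, fix_end, ~ mean(y[.x:.y])),
    n_samples = fix_end - fix_start + 1L
  )
}

#' Assign fixations to AOI categories
#'
#' Each fixation is labelled with the category of the AOI polygon that
#' contains its centroid, or `"background"` if none does. When polygons
#' overlap, the smallest-area polygon wins (so a nested AOI takes
#' precedence over its container).
#'
#' @param fixations Tibble from [detect_fixations()].
#' @param aois AOI table of the same scenario (e.g. `scenario$aois`).
#' @return `fixations` with an added `category` factor (levels: the four
#'   AOI categories plus `"background"`).
#' @export
assign_fixations <- function(fixations, aois) {
  levels_out <- c(aoi_categories(), "background")
  if (!nrow(fixations)) {
    fixations$category <- factor(character(), levels = levels_out)
    return(fixations)
  }
  pts <- cbind(fixations$centroid_x, fixations$centroid_y)
  assigned <- rep(NA_character_, nrow(fixations))
  best_area <- rep(Inf, nrow(fixations))
  if (nrow(aois)) {
    ord <- order(aois$area) # smallest polygons claim points first
    for (k in ord) {
      inside <- mgcv::in.out(aois$vertices[[k]], pts)
      take <- inside & aois$area[k] < best_area
      assigned[take] <- aois$category[k]
      best_area[take] <- aois$area[k]
    }
  }
  assigned[is.na(assigned)] <- "background"
  fixations$category <- factor(assigned, levels = levels_out)
  fixations
}

# Which categories have at least one AOI in each scenario.
aoi_presence <- function(scenarios) {
  purrr::map_dfr(scenarios, function(sc) {
    tibble(
      scenario_id = sc$id,
      category = aoi_categories(),
      present = aoi_categories() %in% sc$aois$category
    )
  })
}

# Per-scenario, per-category aggregation shared by DOAF and FC.
aggregate_gaze <- function(fixations, scenarios, stat = c("doaf", "fc")) {
  stat <- match.arg(stat)
  presence <- aoi_presence(scenarios)
  presence <- presence[presence$present & presence$scenario_id != "familiarization", ]
  fx <- dplyr::filter(fixations, .data$category != "background")
  per_scenario <- fx |>
    dplyr::group_by(.data$scenario_id, .data$category) |>
    dplyr::summarise(
      value = if (stat == "doaf") mean(.data$duration_ms) else dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(category = as.character(.data$category))
  out <- presence |>
    dplyr::left_join(per_scenario, by = c("scenario_id", "category"))
  if (stat == "fc") {
    # a scenario with the AOI but no fixations contributes a count of zero
    out$value[is.na(out$value)] <- 0
  }
  out |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(
      value = if (all(is.na(.data$value))) NA_real_ else mean(.data$value, na.rm = TRUE),
      .groups = "drop"
    )
}

#' Duration of average fixation (DOAF) per AOI category
#'
#' Fixation duration is first averaged per scenario within each category,
#' then averaged (unweighted) across the scenarios in which the category
#' has an AOI. A scenario whose AOI attracted no fixations contributes a
#' missing value, not zero; a category with no fixations anywhere is
#' missing.
#'
#' @param fixations Tibble of assigned fixations for one participant with
#'   columns `scenario_id`, `category`, `duration_ms`.
#' @param scenarios Scenario list defining AOI presence
#'   (default [default_scenarios()]).
#' @return Tibble with `category` and `doaf_ms`.
#' @export
compute_doaf <- function(fixations, scenarios = default_scenarios()) {
  out <- aggregate_gaze(fixations, scenarios, "doaf")
  dplyr::rename(out, doaf_ms = "value")
}

#' Fixation count (FC) per AOI category
#'
#' Fixations are counted (summed) per scenario within each category, then
#' averaged across the scenarios in which the category has an AOI. Unlike
#' DOAF, a scenario with the AOI present but no fixations contributes a
#' count of zero.
#'
#' @inheritParams compute_doaf
#' @return Tibble with `category` and `fc`.
#' @export
compute_fc <- function(fixations, scenarios = default_scenarios()) {
  out <- aggregate_gaze(fixations, scenarios, "fc")
  dplyr::rename(out, fc = "value")
}

#' Full gaze indicator set for one participant
#'
#' Runs clipping, fixation detection and AOI assignment on each scenario
#' stream, then computes DOAF and FC per category.
#'
#' @param streams Tibble with columns `scenario_id` and `stream` (list
#'   column of gaze sample tibbles).
#' @param scenarios Scenario list supplying AOI geometry.
#' @param max_dispersion_deg,min_duration_ms I-DT parameters.
#' @param window_s Orientation window in seconds.
#' @return One-row tibble with `doaf_<category>` and `fc_<category>`
#'   columns.
#' @export
gaze_indicators <- function(streams, scenarios = default_scenarios(),
                            max_dispersion_deg = 1, min_duration_ms = 100,
                            window_s = 30) {
  fixations <- purrr::map2_dfr(
    streams$scenario_id, streams$stream,
    function(sid, st) {
      fx <- st |>
        clip_to_orientation_window(window_s) |>
        detect_fixations(max_dispersion_deg, min_duration_ms) |>
        assign_fixations(scenarios[[sid]]$aois)
      fx$scenario_id <- sid
      fx
    }
  )
  doaf <- compute_doaf(fixations, scenarios)
  fc <- compute_fc(fixations, scenarios)
  out <- dplyr::bind_cols(
    tidyr::pivot_wider(doaf,
      names_from = "category", values_from = "doaf_ms", names_prefix = "doaf_"
    ),
    tidyr::pivot_wider(fc,
      names_from = "category", values_from = "fc", names_prefix = "fc_"
    )
  )
  out
}
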