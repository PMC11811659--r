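#' @title MCI scenarios: rosters, AOI geometry, timing
#' @description
#' A scenario bundles the patient roster (with ground-truth triage colours
#' and the assessment findings a participant can elicit), the area-of-interest
#' (AOI) geometry used by the gaze pipeline, and the cohort timing statistics
#' used by the synthetic generator. Five training scenarios of increasing
#' difficulty plus an empty familiarization scenario are bundled.
#' @name scenarios
NULL

aoi_categories <- function() c("patients", "safety", "vehicle_impact", "distractor")

rect_poly <- function(x, y, w, h) {
  matrix(
    c(
      x, y,
      x + w, y,
      x + w, y + h,
      x, y + h
    ),
    ncol = 2, byrow = TRUE,
    dimnames = list(NULL, c("x", "y"))
  )
}

# Reject degenerate or self-intersecting AOI polygons.
validate_polygon <- function(verts, where = "aoi") {
  if (!is.matrix(verts) || ncol(verts) != 2 || nrow(verts) < 3) {
    stop_format(paste0(where, ": polygon needs at least 3 (x, y) vertices"))
  }
  if (anyNA(verts)) stop_format(paste0(where, ": polygon has missing vertices"))
  if (polygon_area(verts) <= 0) {
    stop_format(paste0(where, ": polygon has zero area"))
  }
  n <- nrow(verts)
  seg <- function(i) rbind(verts[i, ], verts[if (i == n) 1L else i + 1L, ])
  intersects <- function(p, q) {
    d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    d1 <- d(q[1, ], q[2, ], p[1, ]); d2 <- d(q[1, ], q[2, ], p[2, ])
    d3 <- d(p[1, ], p[2, ], q[1, ]); d4 <- d(p[1, ], p[2, ], q[2, ])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  if (n > 3) {
    for (i in seq_len(n - 2L)) {
      for (j in seq(i + 2L, n)) {
        if (i == 1L && j == n) next # adjacent via closure
        if (intersects(seg(i), seg(j))) {
          stop_format(paste0(where, ": polygon is self-intersecting"))
        }
      }
    }
  }
  invisible(verts)
}

make_aoi_table <- function(aoi_id, category, vertices) {
  stopifnot(length(aoi_id) == length(category), length(category) == length(vertices))
  bad <- !category %in% aoi_categories()
  if (any(bad)) {
    stop_format(paste0("unknown AOI category: ", paste(unique(category[bad]), collapse = ", ")))
  }
  purrr::walk2(vertices, aoi_id, ~ validate_polygon(.x, paste0("aoi ", .y)))
  tibble(
    aoi_id = aoi_id,
    category = category,
    vertices = vertices,
    area = purrr::map_dbl(vertices, polygon_area)
  )
}

# Deterministic assessments consistent with a target START colour.
roster_assessment <- function(colors) {
  n <- length(colors)
  red_variant <- cumsum(colors == "red") %% 3L # cycle through red causes
  purrr::map_dfr(seq_len(n), function(i) {
    col <- colors[i]
    v <- red_variant[i]
    switch(col,
      green = patient_assessment(
        can_walk = TRUE, respiration_rate = 16 + (i %% 3), cap_refill_s = 1
      ),
      yellow = patient_assessment(
        can_walk = FALSE, respiration_rate = 18 + 2 * (i %% 4),
        cap_refill_s = 1 + 0.2 * (i %% 3), heavy_bleeding = i %% 2 == 0
      ),
      red = switch(as.character(v),
        "0" = patient_assessment(
          can_walk = FALSE, respiration_rate = 34 + (i %% 4), cap_refill_s = 1.5
        ),
        "1" = patient_assessment(
          can_walk = FALSE, respiration_rate = 24, cap_refill_s = 3.2,
          radial_pulse_present = FALSE, heavy_bleeding = TRUE
        ),
        "2" = patient_assessment(
          can_walk = FALSE, respiration_rate = 22, cap_refill_s = 1.8,
          follows_commands = FALSE
        )
      ),
      black = patient_assessment(
        can_walk = FALSE, breathing = FALSE,
        airway_clear_after_reposition = FALSE, respiration_rate = 0,
        cap_refill_s = 5, radial_pulse_present = FALSE,
        follows_commands = FALSE
      ),
      stop_input(paste0("unknown triage colour: ", col))
    )
  })
}

make_scenario <- function(id, label, colors, aois, mean_duration_min,
                          sd_duration_min) {
  roster <- if (length(colors)) {
    assessment <- roster_assessment(colors)
    dplyr::bind_cols(
      tibble(
        patient_id = sprintf("p%02d", seq_along(colors)),
        true_color = factor(colors, levels = triage_colors())
      ),
      assessment
    )
  } else {
    tibble(patient_id = character(), true_color = factor(character(), levels = triage_colors()))
  }
  if (nrow(roster)) {
    implied <- start_classify(roster[assessment_fields])
    stopifnot(identical(as.character(implied), as.character(roster$true_color)))
  }
  structure(
    list(
      id = id,
      label = label,
      roster = roster,
      aois = aois,
      mean_duration_min = mean_duration_min,
      sd_duration_min = sd_duration_min
    ),
    class = "mci_scenario"
  )
}

#' @export
print.mci_scenario <- function(x, ...) {
  counts <- table(factor(x$roster$true_color, levels = triage_colors()))
  cat(
    "<mci_scenario> ", x$id, " (", x$label, "): ",
    nrow(x$roster), " patients [",
    paste(paste0(counts, " ", names(counts)), collapse = ", "),
    "], ", nrow(x$aois), " AOIs\n",
    sep = ""
  )
  invisible(x)
}

#' Bundled MCI scenarios
#'
#' The five training scenarios plus the familiarization scenario: patient
#' rosters (three green and one yellow patient in scenario 1, up to eighteen
#' patients across all four triage levels in scenario 5), AOI geometry on a
#' scenario-fixed angular panorama (degrees), and cohort mean/SD completion
#' times in minutes. The familiarization scenario has no patients.
#'
#' Safety and vehicle-impact AOIs exist in every training scenario
#' (scenarios 3 and 4 have two vehicle-impact zones); the distractor AOI (a
#' filming bystander) exists only in scenario 3.
#'
#' @return Named list of `mci_scenario` objects; names are the scenario ids
#'   `"familiarization"`, `"1"` ... `"5"`.
#' @export
default_scenarios <- function() {
  pat <- function(...) rect_poly(...)
  sc <- list(
    make_scenario(
      "familiarization", "quiet residential area, no accident",
      character(),
      make_aoi_table(character(), character(), list()),
      5.78, 1.71
    ),
    make_scenario(
      "1", "two-car accident on a countryside road",
      c("green", "green", "green", "yellow"),
      make_aoi_table(
        c("patients_a", "patients_b", "safety_oil", "vi_zone"),
        c("patients", "patients", "safety", "vehicle_impact"),
        list(
          pat(-60, -10, 25, 20), pat(10, -10, 25, 20),
          pat(-20, -30, 18, 12), pat(45, 5, 22, 18)
        )
      ),
      3.32, 1.03
    ),
    make_scenario(
      "2", "car, van and motorcyclist on a motorway",
      c("green", "yellow", "yellow", "yellow", "red"),
      make_aoi_table(
        c("patients_a", "patients_b", "safety_traffic", "vi_zone"),
        c("patients", "patients", "safety", "vehicle_impact"),
        list(
          pat(-70, -12, 28, 20), pat(5, -12, 30, 20),
          pat(-150, -5, 30, 15), pat(50, 0, 25, 18)
        )
      ),
      5.33, 1.37
    ),
    make_scenario(
      "3", "car and SUV in a busy inner-city area",
      c("green", "yellow", "yellow", "yellow", "red", "red"),
      make_aoi_table(
        c("patients_a", "patients_b", "safety_crowd", "vi_zone_1", "vi_zone_2",
          "distractor_filming"),
        c("patients", "patients", "safety", "vehicle_impact", "vehicle_impact",
          "distractor"),
        list(
          pat(-75, -12, 28, 22), pat(0, -15, 28, 22),
          pat(-160, -8, 28, 16), pat(40, -2, 20, 16), pat(70, -2, 20, 16),
          pat(120, -5, 16, 22)
        )
      ),
      5.06, 1.59
    ),
    make_scenario(
      "4", "expressway accident with three cars and a van",
      c("green", "yellow", "yellow", "yellow", "red", "red", "red", "black"),
      make_aoi_table(
        c("patients_a", "patients_b", "safety_traffic", "vi_zone_1", "vi_zone_2"),
        c("patients", "patients", "safety", "vehicle_impact", "vehicle_impact"),
        list(
          pat(-80, -14, 30, 24), pat(-10, -14, 30, 24),
          pat(-155, -6, 30, 15), pat(35, -4, 22, 18), pat(70, -4, 22, 18)
        )
      ),
      7.28, 1.97
    ),
    make_scenario(
      "5", "expressway accident involving a bus and a truck, night and fog",
      c(rep("green", 4), rep("yellow", 6), rep("red", 4), rep("black", 4)),
      make_aoi_table(
        c("patients_a", "patients_b", "patients_c", "safety_hazards", "vi_zone"),
        c("patients", "patients", "patients", "safety", "vehicle_impact"),
        list(
          pat(-95, -16, 32, 26), pat(-40, -16, 32, 26), pat(20, -16, 32, 26),
          pat(-160, -10, 30, 18), pat(65, -5, 26, 20)
        )
      ),
      10.66, 3.08
    )
  )
  names(sc) <- purrr::map_chr(sc, "id")
  sc
}

scenario_color_counts <- function(scenario) {
  tab <- table(factor(scenario$roster$true_color, levels = triage_colors()))
  as.integer(tab)
}

#' Write a scenario to JSON
#'
#' @param scenario An `mci_scenario` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scenario_json <- function(scenario, path) {
  counts <- scenario_color_counts(scenario)
  roster <- if (nrow(scenario$roster)) {
    purrr::map(seq_len(nrow(scenario$roster)), function(i) {
      r <- scenario$roster[i, ]
      list(
        patient_id = r$patient_id,
        true_color = as.character(r$true_color),
        assessment = as.list(r[assessment_fields])
      )
    })
  } else {
    list()
  }
  obj <- list(
    id = scenario$id,
    label = scenario$label,
    declared_counts = as.list(stats::setNames(counts, triage_colors())),
    mean_duration_min = scenario$mean_duration_min,
    sd_duration_min = scenario$sd_duration_min,
    roster = roster,
    aois = purrr::map(seq_len(nrow(scenario$aois)), function(i) {
      a <- scenario$aois[i, ]
      list(
        aoi_id = a$aoi_id,
        category = a$category,
        vertices = unname(apply(a$vertices[[1]], 1, as.list, simplify = FALSE))
      )
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load and validate a scenario JSON file
#'
#' Checks the schema, rebuilds the roster and AOI tables, validates each
#' polygon, and verifies that the roster colour counts match the file's
#' declared counts.
#'
#' @param path Path to a scenario JSON file (see
#'   `system.file("extdata", package = "mcitriage")` for the bundled ones).
#' @return An `mci_scenario` object.
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop_format(paste0("scenario file not found: ", path))
  obj <- tryCatch(
    jsonlite::read_json(path),
    error = function(e) stop_format(paste0(path, ": not valid JSON (", conditionMessage(e), ")"))
  )
  required <- c("id", "declared_counts", "mean_duration_min", "sd_duration_min",
                "roster", "aois")
  missing <- setdiff(required, names(obj))
  if (length(missing)) {
    stop_format(paste0(path, ": missing field(s) ", paste(missing, collapse = ", ")))
  }
  if (!obj$id %in% c("familiarization", as.character(1:5))) {
    stop_format(paste0(path, ": unknown scenario id `", obj$id, "`"))
  }
  colors <- purrr::map_chr(obj$roster, "true_color")
  if (length(colors) && !all(colors %in% triage_colors())) {
    stop_format(paste0(path, ": roster contains unknown triage colours"))
  }
  roster <- if (length(obj$roster)) {
    dplyr::bind_cols(
      tibble(
        patient_id = purrr::map_chr(obj$roster, "patient_id"),
        true_color = factor(colors, levels = triage_colors())
      ),
      purrr::map_dfr(obj$roster, function(p) {
        a <- p$assessment
        miss <- setdiff(assessment_fields, names(a))
        if (length(miss)) {
          stop_format(paste0(
            path, ": patient ", p$patient_id, " assessment missing ",
            paste(miss, collapse = ", ")
          ))
        }
        tibble::as_tibble(a[assessment_fields])
      })
    )
  } else {
    tibble(patient_id = character(), true_color = factor(character(), levels = triage_colors()))
  }
  declared <- unlist(obj$declared_counts[triage_colors()])
  actual <- table(factor(colors, levels = triage_colors()))
  if (!isTRUE(all.equal(as.integer(declared), as.integer(actual)))) {
    stop_format(paste0(
      path, ": declared colour counts (",
      paste(declared, collapse = "/"), ") do not match roster (",
      paste(as.integer(actual), collapse = "/"), ")"
    ))
  }
  aois <- make_aoi_table(
    purrr::map_chr(obj$aois, "aoi_id"),
    purrr::map_chr(obj$aois, "category"),
    purrr::map(obj$aois, function(a) {
      verts <- do.call(rbind, purrr::map(a$vertices, ~ unlist(.x)))
      colnames(verts) <- c("x", "y")
      verts
    })
  )
  if ("distractor" %in% aois$category && obj$id != "3") {
    stop_format(paste0(path, ": distractor AOI declared outside scenario 3"))
  }
  scenario <- structure(
    list(
      id = obj$id,
      label = obj$label %||% obj$id,
      roster = roster,
      aois = aois,
      mean_duration_min = obj$mean_duration_min,
      sd_duration_min = obj$sd_duration_min
    ),
    class = "mci_scenario"
  )
  scenario
}

#' Load the bundled scenario set
#'
#' Reads the six scenario JSON fixtures shipped with the package and
#' returns them keyed by scenario id.
#'
#' @return Named list of `mci_scenario` objects.
#' @export
bundled_scenarios <- function() {
  dir <- system.file("extdata", package = "mcitriage")
  files <- file.path(dir, paste0(
    "scenario-", c("familiarization", 1:5), ".json"
  ))
  sc <- purrr::map(files, load_scenario)
  names(sc) <- purrr::map_chr(sc, "id")
  sc
}
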