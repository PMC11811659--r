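# Independent oracles used across the suite. These re-derive expected
# results by brute force and must stay independent of the package's own
# implementation paths.

# Brute-force I-DT: O(n^2) window scan recomputing dispersion from scratch.
oracle_idt <- function(stream, max_dispersion = 1, min_duration = 100) {
  stream <- stream[if ("valid" %in% names(stream)) stream$valid else TRUE, ]
  t <- stream$t_ms; x <- stream$x_deg; y <- stream$y_deg
  n <- length(t)
  out <- list()
  i <- 1L
  while (i <= n) {
    j_max <- i
    for (j in i:n) {
      disp <- max(max(x[i:j]) - min(x[i:j]), max(y[i:j]) - min(y[i:j]))
      if (disp > max_dispersion) break
      j_max <- j
    }
    if (t[j_max] - t[i] >= min_duration) {
      out[[length(out) + 1]] <- c(start = t[i], end = t[j_max])
      i <- j_max + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(out)) {
    return(data.frame(start = numeric(), end = numeric()))
  }
  as.data.frame(do.call(rbind, out))
}

# Hand-evaluated Holm step-down (independent of stats::p.adjust).
oracle_holm <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj_sorted <- pmin(1, cummax((m - seq_len(m) + 1) * p[ord]))
  out <- numeric(m)
  out[ord] <- adj_sorted
  out
}

# A synthetic gaze stream with known structure for detector tests.
random_stream <- function(n, step_ms = 5, spread = 5) {
  tibble::tibble(
    t_ms = seq(0, by = step_ms, length.out = n),
    x_deg = cumsum(stats::rnorm(n, 0, spread / 10)),
    y_deg = cumsum(stats::rnorm(n, 0, spread / 10)),
    valid = TRUE
  )
}

# A stream holding fixed points for given durations, joined instantly.
piecewise_stream <- function(points, dur_ms, step_ms = 5) {
  rows <- purrr::map2_dfr(seq_len(nrow(points)), dur_ms, function(i, d) {
    ts <- seq(0, d, by = step_ms)
    tibble::tibble(t_rel = ts, x_deg = points[i, 1], y_deg = points[i, 2])
  })
  offs <- rep(cumsum(c(0, dur_ms[-length(dur_ms)] + step_ms)),
              times = vapply(dur_ms, function(d) length(seq(0, d, by = step_ms)), integer(1)))
  tibble::tibble(
    t_ms = rows$t_rel + offs, x_deg = rows$x_deg, y_deg = rows$y_deg,
    valid = TRUE
  )
}

# Random valid coded messages for property tests.
random_codings <- function(n) {
  tibble::tibble(
    scene_mentioned = sample(c(TRUE, FALSE), n, TRUE),
    scene_detailed = sample(c(TRUE, FALSE), n, TRUE),
    scene_errors = sample(0:4, n, TRUE),
    safety_mentioned = sample(c(TRUE, FALSE), n, TRUE),
    safety_errors = sample(0:4, n, TRUE),
    situation_mentioned = sample(c(TRUE, FALSE), n, TRUE),
    reported_patient_count = sample(c(NA, 0:20), n, TRUE),
    support_mentioned = sample(c(TRUE, FALSE), n, TRUE),
    support_errors = sample(0:4, n, TRUE)
  ) |>
    dplyr::mutate(
      scene_detailed = scene_detailed & scene_mentioned,
      scene_errors = ifelse(scene_mentioned, scene_errors, 0L),
      safety_errors = ifelse(safety_mentioned, safety_errors, 0L),
      support_errors = ifelse(support_mentioned, support_errors, 0L),
      reported_patient_count = ifelse(situation_mentioned,
                                      reported_patient_count, NA_integer_)
    )
}

# All permutations of 1:n as rows (n! x n matrix).
combinat_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- combinat_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}
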