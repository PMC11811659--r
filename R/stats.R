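#' @title Statistical primitives of the known-groups battery
#' @name battery-stats
#' @description
#' Winsorization, the subjective-performance composite, two-sample t tests
#' (raw-data and summary-statistic entry points), Holm correction, Cohen's
#' d, Spearman correlation, the centered bootstrap regression, MANOVA with
#' Pillai's trace, and standardized Cronbach's alpha.
NULL

#' Subjective performance composite
#'
#' Two post-scenario self-ratings are combined: a direct 1-10 performance
#' rating and a German school grade (1 = best ... 6 = worst). The grade is
#' inverted and rescaled linearly onto 1-10
#' (`10 - 1.8 * (grade - 1)`), and the two items are averaged.
#'
#' @param item1 Rating on the 1-10 scale.
#' @param grade School grade on the 1-6 scale.
#' @return Composite on the 1-10 scale.
#' @export
subjective_composite <- function(item1, grade) {
  if (any(item1 < 1 | item1 > 10, na.rm = TRUE)) {
    stop_input("item1 must lie in [1, 10]")
  }
  if (any(grade < 1 | grade > 6, na.rm = TRUE)) {
    stop_input("grade must lie in [1, 6]")
  }
  transformed <- 10 - 1.8 * (grade - 1)
  (item1 + transformed) / 2
}

#' Winsorize a vector at mean +/- k SD
#'
#' Values beyond `k` standard deviations from the mean are set to the
#' bound. Mean and SD are those of the original vector (single pass), so
#' re-winsorizing an already clamped vector can move the bounds; the
#' clamping itself is applied once.
#'
#' @param x Numeric vector (missing values are kept as missing).
#' @param k Number of SDs defining the bounds.
#' @return Winsorized vector.
#' @export
winsorize <- function(x, k = 3) {
  obs <- x[!is.na(x)]
  if (length(obs) < 2) return(x)
  m <- mean(obs)
  s <- stats::sd(obs)
  clamp(x, m - k * s, m + k * s)
}

#' Two-sample t test (raw data or summary statistics)
#'
#' Student or Welch two-sample t test comparing the MFR and non-MFR
#' groups, with a one- or two-tailed p-value. Either raw vectors or group
#' summary statistics (mean, SD, n) can be supplied, and both entry points
#' give identical results on the same data.
#'
#' @param x,y Numeric vectors for the two groups, or `NULL` when using
#'   summary statistics.
#' @param mean_x,sd_x,n_x,mean_y,sd_y,n_y Summary statistics, used when
#'   `x`/`y` are `NULL`.
#' @param variant `"welch"` (unequal variances) or `"student"` (pooled).
#' @param tail `"two"` or `"one"`. One-tailed p is for the alternative
#'   named in `alternative`.
#' @param alternative Direction for one-tailed tests: `"greater"` tests
#'   mean(x) > mean(y).
#' @return One-row tibble: `statistic`, `df`, `p_value`, `mean_diff`,
#'   `variant`, `tail`.
#' @export
group_t_test <- function(x = NULL, y = NULL,
                         mean_x = NULL, sd_x = NULL, n_x = NULL,
                         mean_y = NULL, sd_y = NULL, n_y = NULL,
                         variant = c("welch", "student"),
                         tail = c("two", "one"),
                         alternative = c("greater", "less")) {
  variant <- match.arg(variant)
  tail <- match.arg(tail)
  alternative <- match.arg(alternative)
  if (!is.null(x)) {
    x <- x[!is.na(x)]
    y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) stop_input("each group needs n >= 2")
    mean_x <- mean(x); sd_x <- stats::sd(x); n_x <- length(x)
    mean_y <- mean(y); sd_y <- stats::sd(y); n_y <- length(y)
  }
  if (is.null(mean_x) || is.null(mean_y)) {
    stop_input("supply either raw vectors or full summary statistics")
  }
  if (n_x < 2 || n_y < 2) stop_input("each group needs n >= 2")
  if (sd_x == 0 && sd_y == 0) {
    stop_degenerate("both groups have zero variance")
  }
  if (variant == "welch") {
    se2x <- sd_x^2 / n_x
    se2y <- sd_y^2 / n_y
    se <- sqrt(se2x + se2y)
    df <- (se2x + se2y)^2 / (se2x^2 / (n_x - 1) + se2y^2 / (n_y - 1))
  } else {
    sp2 <- ((n_x - 1) * sd_x^2 + (n_y - 1) * sd_y^2) / (n_x + n_y - 2)
    se <- sqrt(sp2 * (1 / n_x + 1 / n_y))
    df <- n_x + n_y - 2
  }
  stat <- (mean_x - mean_y) / se
  p <- if (tail == "two") {
    2 * stats::pt(-abs(stat), df)
  } else if (alternative == "greater") {
    stats::pt(stat, df, lower.tail = FALSE)
  } else {
    stats::pt(stat, df)
  }
  tibble(
    statistic = stat, df = df, p_value = p, mean_diff = mean_x - mean_y,
    variant = variant, tail = tail
  )
}

#' Holm (Bonferroni-Holm) step-down adjustment
#'
#' @param pvals Raw p-values in `(0, 1]`.
#' @return Adjusted p-values, in input order. Adjusted values are never
#'   below the raw ones and are monotone in raw-p order.
#' @export
holm_adjust <- function(pvals) {
  if (any(pvals <= 0 | pvals > 1, na.rm = TRUE)) {
    stop_input("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvals, method = "holm")
}

#' Cohen's d from group summary statistics (pooled SD)
#'
#' @param m1,s1,n1 Mean, SD and size of group 1.
#' @param m2,s2,n2 Mean, SD and size of group 2.
#' @return Standardized mean difference `(m2 - m1) / s_pooled`.
#' @export
cohen_d_pooled <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 2 || n2 < 2) stop_input("each group needs n >= 2")
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  if (sp == 0) stop_degenerate("pooled SD is zero")
  (m2 - m1) / sp
}

#' Cohen's d from a t statistic
#'
#' The independent-samples conversion `d = |t| * sqrt(1/n1 + 1/n2)`,
#' used to recompute printed effect sizes from printed t statistics.
#'
#' @param t t statistic.
#' @param n1,n2 Group sizes.
#' @return Cohen's d (non-negative).
#' @export
cohen_d_from_t <- function(t, n1, n2) {
  if (n1 < 2 || n2 < 2) stop_input("each group needs n >= 2")
  abs(t) * sqrt(1 / n1 + 1 / n2)
}

#' Spearman rank correlation with test
#'
#' Pearson correlation of midranks, with the two-sided p-value from
#' [stats::cor.test()] (exact for small untied samples, asymptotic
#' otherwise).
#'
#' @param x,y Paired numeric vectors (pairs with missing values dropped).
#' @return One-row tibble with `rho`, `p_value`, `n`.
#' @export
spearman_rho <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4) stop_input("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warn("constant vector: Spearman correlation undefined")
    return(tibble(rho = NA_real_, p_value = NA_real_, n = length(x)))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  tibble(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Regression of accuracy on triage knowledge with bootstrap CI
#'
#' OLS of triage accuracy on the knowledge-test score, controlling for age
#' and gender. Knowledge and age are mean-centered; gender is coded
#' -1 = female, 1 = male. Confidence intervals come from a nonparametric
#' case-resampling bootstrap (percentile method).
#'
#' @param data Tibble with columns `accuracy`, `knowledge_score`, `age`,
#'   `gender` (`"female"`/`"male"` or -1/1). Incomplete cases are dropped.
#' @param n_boot Bootstrap draws.
#' @param seed Seed for the bootstrap resampling.
#' @param conf Confidence level.
#' @return List of class `mci_regression` with `coefficients` (tibble with
#'   estimates, SEs, p-values and bootstrap CIs), `r_squared`,
#'   `adj_r_squared`, `f_statistic`, `df`, `n`, and the underlying `fit`.
#' @export
regression_accuracy <- function(data, n_boot = 5000, seed = 1, conf = 0.95) {
  gender_num <- if (is.numeric(data$gender)) {
    data$gender
  } else {
    ifelse(data$gender == "male", 1, -1)
  }
  d <- tibble(
    accuracy = data$accuracy,
    knowledge = data$knowledge_score,
    age = data$age,
    gender = gender_num
  )
  d <- d[stats::complete.cases(d), ]
  d$knowledge_c <- d$knowledge - mean(d$knowledge)
  d$age_c <- d$age - mean(d$age)
  fit <- stats::lm(accuracy ~ knowledge_c + age_c + gender, data = d)
  qrf <- qr(stats::model.matrix(fit))
  if (qrf$rank < ncol(stats::model.matrix(fit))) {
    keep <- qrf$pivot[seq_len(qrf$rank)]
    dropped <- colnames(stats::model.matrix(fit))[-keep]
    stop_degenerate(paste0(
      "design matrix is rank deficient; collinear column(s): ",
      paste(dropped, collapse = ", ")
    ))
  }
  sm <- summary(fit)
  boot_stat <- function(dat, idx) {
    db <- dat[idx, ]
    db$knowledge_c <- db$knowledge - mean(db$knowledge)
    db$age_c <- db$age - mean(db$age)
    stats::coef(stats::lm(accuracy ~ knowledge_c + age_c + gender, data = db))
  }
  bt <- withr::with_seed(seed, boot::boot(d, boot_stat, R = n_boot))
  alpha <- (1 - conf) / 2
  ci <- t(apply(bt$t, 2, stats::quantile, probs = c(alpha, 1 - alpha)))
  coefs <- tibble(
    term = names(stats::coef(fit)),
    estimate = unname(stats::coef(fit)),
    std_error = unname(sm$coefficients[, "Std. Error"]),
    p_value = unname(sm$coefficients[, "Pr(>|t|)"]),
    ci_lower = ci[, 1],
    ci_upper = ci[, 2]
  )
  structure(
    list(
      coefficients = coefs,
      r_squared = sm$r.squared,
      adj_r_squared = sm$adj.r.squared,
      f_statistic = unname(sm$fstatistic["value"]),
      df = unname(sm$fstatistic[c("numdf", "dendf")]),
      n = nrow(d),
      n_boot = n_boot,
      fit = fit
    ),
    class = "mci_regression"
  )
}

#' MANOVA with Pillai's trace
#'
#' Multivariate comparison of a set of indicator columns between the two
#' expertise groups, summarized by Pillai's trace and its F
#' approximation.
#'
#' @param Y Numeric matrix or data frame of responses (complete cases
#'   required).
#' @param group Grouping factor/vector of the same length.
#' @return One-row tibble: `pillai`, `f`, `df1`, `df2`, `p_value`, `n`.
#' @export
manova_pillai <- function(Y, group) {
  Y <- as.matrix(Y)
  if (anyNA(Y) || anyNA(group)) stop_input("manova_pillai requires complete cases")
  group <- factor(group)
  if (nrow(Y) < ncol(Y) + nlevels(group) + 1) {
    stop_input("too few rows for the number of response variables")
  }
  fit <- tryCatch(
    summary(stats::manova(Y ~ group), test = "Pillai"),
    error = function(e) stop_degenerate(paste0("MANOVA failed: ", conditionMessage(e)))
  )
  row <- fit$stats["group", ]
  tibble(
    pillai = unname(row["Pillai"]),
    f = unname(row["approx F"]),
    df1 = unname(row["num Df"]),
    df2 = unname(row["den Df"]),
    p_value = unname(row["Pr(>F)"]),
    n = nrow(Y)
  )
}

#' Standardized Cronbach's alpha
#'
#' Internal-consistency reliability from the average pairwise Pearson
#' correlation: `alpha = k * rbar / (1 + (k - 1) * rbar)` for `k` items.
#' Used on the participant x scenario matrices of the per-scenario
#' indicators.
#'
#' @param items Numeric matrix or data frame, participants in rows, items
#'   (scenarios) in columns. Rows with missing values are dropped.
#' @return Alpha, or `NA` with a warning if any item is constant.
#' @export
cronbach_alpha_standardized <- function(items) {
  items <- as.matrix(items)
  items <- items[stats::complete.cases(items), , drop = FALSE]
  k <- ncol(items)
  if (k < 2 || nrow(items) < 3) {
    stop_input("need at least 2 items and 3 participants")
  }
  if (any(apply(items, 2, stats::sd) == 0)) {
    warn("constant item: standardized alpha undefined")
    return(NA_real_)
  }
  r <- stats::cor(items)
  rbar <- mean(r[lower.tri(r)])
  k * rbar / (1 + (k - 1) * rbar)
}
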