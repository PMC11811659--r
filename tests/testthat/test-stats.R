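test_that("subjective composite maps grades onto the 1-10 scale linearly", {
  expect_equal(subjective_composite(10, 1), 10)
  expect_equal(subjective_composite(1, 6), 1)
  expect_equal(subjective_composite(8, 2), 8.1)
  expect_error(subjective_composite(11, 2), "item1")
  expect_error(subjective_composite(5, 0.5), "grade")
})

test_that("winsorization clamps at mean +/- 3 SD of the original vector", {
  x <- seq(-2, 2, length.out = 30)
  expect_equal(winsorize(x), x)
  y <- c(rep(0, 20), 50)
  bound <- mean(y) + 3 * sd(y)
  got <- winsorize(y)
  expect_equal(got[21], bound)
  expect_equal(got[1:20], rep(0, 20))
  # direct recomputation: bounds always come from the vector passed in
  z <- c(-40, rep(1, 30), 35)
  expect_equal(winsorize(z), pmin(pmax(z, mean(z) - 3 * sd(z)),
                                  mean(z) + 3 * sd(z)))
  zc <- winsorize(z)
  expect_equal(winsorize(zc), pmin(pmax(zc, mean(zc) - 3 * sd(zc)),
                                   mean(zc) + 3 * sd(zc)))
  # missing values pass through
  expect_true(is.na(winsorize(c(NA, y))[1]))
})

test_that("t tests reproduce the printed knowledge-test comparison", {
  out <- group_t_test(
    mean_x = 13.46, sd_x = 2.73, n_x = 39,
    mean_y = 10.89, sd_y = 3.70, n_y = 37,
    variant = "welch", tail = "two"
  )
  expect_equal(round(abs(out$statistic), 2), 3.43)
  # the printed df comes from unrounded group SDs; rounded summaries land
  # within a tenth
  expect_lt(abs(out$df - 66.17), 0.2)
  expect_lt(out$p_value, 0.0015)
})

test_that("raw-data and summary-statistic t tests agree", {
  withr::with_seed(3, {
    x <- rnorm(20, 1, 2)
    y <- rnorm(25, 0, 3)
  })
  for (variant in c("welch", "student")) {
    raw <- group_t_test(x, y, variant = variant)
    summ <- group_t_test(
      mean_x = mean(x), sd_x = sd(x), n_x = 20,
      mean_y = mean(y), sd_y = sd(y), n_y = 25,
      variant = variant
    )
    expect_equal(raw$statistic, summ$statistic)
    expect_equal(raw$df, summ$df)
    expect_equal(raw$p_value, summ$p_value)
    # and with the base implementation on raw data
    ref <- stats::t.test(x, y, var.equal = variant == "student")
    expect_equal(raw$statistic, unname(ref$statistic))
    expect_equal(raw$p_value, ref$p.value)
  }
  same <- group_t_test(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(group_t_test(rep(1, 5), rep(1, 5)), "zero variance",
               class = "mcitriage_degenerate_error")
})

test_that("t test p-value is consistent with an exhaustive permutation test", {
  withr::with_seed(9, z <- rnorm(10))
  x <- z[1:5]
  y <- z[6:10]
  combs <- utils::combn(10, 5)
  obs <- abs(mean(x) - mean(y))
  perm <- apply(combs, 2, function(idx) {
    abs(mean(z[idx]) - mean(z[-idx]))
  })
  p_perm <- mean(perm >= obs - 1e-12)
  p_t <- group_t_test(x, y, variant = "student")$p_value
  expect_lt(abs(p_perm - p_t), 0.06)
})

test_that("Holm adjustment matches the hand-evaluated step-down", {
  got <- holm_adjust(c(0.0004, 0.0226, 0.0449))
  expect_equal(round(got, 4), c(0.0012, 0.0452, 0.0452))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(rep(0.01, 3)), rep(0.03, 3))
  withr::with_seed(21, {
    for (i in 1:20) {
      p <- runif(sample(2:8, 1))
      adj <- holm_adjust(p)
      expect_equal(adj, oracle_holm(p))
      expect_true(all(adj >= p))
      ord <- order(p)
      expect_true(all(diff(adj[ord]) >= -1e-12))
    }
  })
  expect_error(holm_adjust(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("Cohen's d conversions agree with each other and the printed values", {
  expect_equal(cohen_d_pooled(5, 1, 20, 5, 1, 20), 0)
  expect_equal(round(cohen_d_from_t(3.43, 39, 37), 2), 0.79)
  withr::with_seed(14, {
    x <- rnorm(30, 0.3, 1)
    y <- rnorm(30, 0, 1)
  })
  tt <- group_t_test(x, y, variant = "student")
  d_t <- cohen_d_from_t(tt$statistic, 30, 30)
  d_p <- abs(cohen_d_pooled(mean(x), sd(x), 30, mean(y), sd(y), 30))
  expect_equal(d_t, d_p, tolerance = 1e-10)
  expect_error(cohen_d_pooled(1, 0, 10, 1, 0, 10), "pooled SD",
               class = "mcitriage_degenerate_error")
})

test_that("Spearman correlation handles monotone transforms and small-n exact p", {
  x <- c(3, 9, 1, 5, 7, 2)
  expect_equal(spearman_rho(x, exp(x))$rho, 1)
  expect_equal(spearman_rho(x, -x^3)$rho, -1)
  withr::with_seed(31, {
    x6 <- rnorm(6)
    y6 <- rnorm(6)
  })
  got <- spearman_rho(x6, y6)
  # enumerate all 720 pairings for the exact two-sided p
  perms <- combinat_perms(6)
  rho_obs <- cor(rank(x6), rank(y6))
  rho_all <- apply(perms, 1, function(p) cor(rank(x6), rank(y6[p])))
  p_exact <- mean(abs(rho_all) >= abs(rho_obs) - 1e-12)
  expect_equal(got$rho, rho_obs)
  expect_equal(got$p_value, p_exact, tolerance = 1e-10)
  expect_warning(cst <- spearman_rho(rep(1, 10), rnorm(10)), "constant")
  expect_true(is.na(cst$rho))
  expect_error(spearman_rho(1:3, 1:3), "at least 4")
})

test_that("MANOVA Pillai trace matches the Hotelling T^2 identity", {
  withr::with_seed(19, {
    n1 <- 25; n2 <- 22
    Y <- rbind(
      matrix(rnorm(n1 * 4), n1) + rep(c(0.4, 0, 0.2, 0), each = n1),
      matrix(rnorm(n2 * 4), n2)
    )
  })
  g <- rep(c("a", "b"), c(n1, n2))
  out <- manova_pillai(Y, g)
  # two-group identity: V = T^2 / (T^2 + n - 2)
  m1 <- colMeans(Y[1:n1, ]); m2 <- colMeans(Y[-(1:n1), ])
  S <- ((n1 - 1) * cov(Y[1:n1, ]) + (n2 - 1) * cov(Y[-(1:n1), ])) / (n1 + n2 - 2)
  T2 <- (n1 * n2 / (n1 + n2)) *
    drop(t(m1 - m2) %*% solve(S) %*% (m1 - m2))
  expect_equal(out$pillai, T2 / (T2 + n1 + n2 - 2), tolerance = 1e-8)
  expect_equal(out$df1, 4)
  expect_equal(out$df2, n1 + n2 - 5)
  # identical group means give a trace near zero
  null <- manova_pillai(rbind(Y, Y), rep(c("a", "b"), each = nrow(Y)))
  expect_lt(null$pillai, 1e-10)
  expect_error(manova_pillai(Y[1:5, ], g[1:5]), "too few rows")
})

test_that("standardized alpha follows the mean-intercorrelation formula", {
  # construct items whose sample correlation matrix is exactly
  # equicorrelated at r = 0.4
  withr::with_seed(23, X <- matrix(rnorm(200 * 5), 200))
  X <- qr.Q(qr(scale(X, scale = FALSE)))[, 1:5] # exactly orthonormal columns
  R <- matrix(0.4, 5, 5); diag(R) <- 1
  Y <- X %*% chol(R)
  expect_equal(cronbach_alpha_standardized(Y), 2 / 2.6, tolerance = 1e-10)
  # perfectly correlated items
  base <- rnorm(40)
  perf <- cbind(base, base * 2 + 1, base * 0.5 - 3)
  expect_equal(cronbach_alpha_standardized(perf), 1)
  # invariance under per-item linear rescaling
  withr::with_seed(24, M <- matrix(rnorm(60 * 4), 60) + rnorm(60))
  M2 <- sweep(sweep(M, 2, c(2, 0.1, 5, 1), `*`), 2, c(1, -3, 0, 7), `+`)
  expect_equal(cronbach_alpha_standardized(M),
               cronbach_alpha_standardized(M2))
  expect_warning(
    out <- cronbach_alpha_standardized(cbind(rep(1, 10), rnorm(10), rnorm(10))),
    "constant"
  )
  expect_true(is.na(out))
  expect_error(cronbach_alpha_standardized(matrix(1:4, 2)), "at least 2 items")
})

test_that("accuracy regression recovers a null effect and is reproducible", {
  withr::with_seed(40, {
    d <- tibble::tibble(
      accuracy = runif(70, 0.5, 1),
      knowledge_score = sample(0:20, 70, TRUE),
      age = sample(20:50, 70, TRUE),
      gender = sample(c("female", "male"), 70, TRUE)
    )
  })
  fit <- regression_accuracy(d, n_boot = 400, seed = 2)
  k <- fit$coefficients[fit$coefficients$term == "knowledge_c", ]
  expect_lt(abs(k$estimate), 0.01)
  expect_true(k$ci_lower < 0 && k$ci_upper > 0)
  fit2 <- regression_accuracy(d, n_boot = 400, seed = 2)
  expect_equal(fit$coefficients, fit2$coefficients)
  d_bad <- dplyr::mutate(d, age = knowledge_score * 2)
  expect_error(regression_accuracy(d_bad, n_boot = 10),
               "rank deficient|collinear")
})
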