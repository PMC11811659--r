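#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the battery report
#'
#' Returns the hypothesis-test block (the three Holm-corrected indicator
#' tests plus the knowledge known-groups test) as one tibble.
#'
#' @param x An `mci_battery` report.
#' @param ... Unused.
#' @return A tibble with one row per test.
#' @export
tidy.mci_battery <- function(x, ...) {
  dplyr::bind_rows(
    x$t_tests,
    dplyr::mutate(x$knowledge_test, p_holm = NA_real_)
  )
}

#' One-row summary of the battery report
#'
#' @param x An `mci_battery` report.
#' @param ... Unused.
#' @return A one-row tibble with the headline quantities.
#' @export
glance.mci_battery <- function(x, ...) {
  rho_ka <- x$spearman[x$spearman$x == "knowledge_score" &
                         x$spearman$y == "accuracy", ]
  tibble(
    n = x$knowledge_test$n_mfr + x$knowledge_test$n_nonmfr,
    d_accuracy = x$t_tests$cohen_d[x$t_tests$indicator == "accuracy"],
    d_speed = x$t_tests$cohen_d[x$t_tests$indicator == "std_speed"],
    d_efficiency = x$t_tests$cohen_d[x$t_tests$indicator == "efficiency"],
    d_knowledge = x$knowledge_test$cohen_d,
    rho_knowledge_accuracy = if (nrow(rho_ka)) rho_ka$rho else NA_real_,
    pillai_doaf = if (nrow(x$manova)) x$manova$pillai[x$manova$family == "doaf"][1] else NA_real_,
    pillai_fc = if (nrow(x$manova)) x$manova$pillai[x$manova$family == "fc"][1] else NA_real_
  )
}

#' Tidy the accuracy regression
#'
#' @param x An `mci_regression` object.
#' @param ... Unused.
#' @return Coefficient tibble with bootstrap percentile CIs.
#' @export
tidy.mci_regression <- function(x, ...) x$coefficients

#' @export
glance.mci_regression <- function(x, ...) {
  tibble(
    r_squared = x$r_squared,
    adj_r_squared = x$adj_r_squared,
    f_statistic = x$f_statistic,
    df1 = x$df[1], df2 = x$df[2],
    n = x$n, n_boot = x$n_boot
  )
}

#' @export
print.mci_regression <- function(x, ...) {
  cat("<mci_regression> accuracy ~ knowledge (centered) + age (centered) + gender (-1/1)\n")
  print(as.data.frame(x$coefficients), digits = 3, row.names = FALSE)
  cat(sprintf(
    "R^2 = %.3f (adj %.3f), F(%d, %d) = %.2f, n = %d, bootstrap draws = %d\n",
    x$r_squared, x$adj_r_squared, x$df[1], x$df[2], x$f_statistic, x$n, x$n_boot
  ))
  invisible(x)
}
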