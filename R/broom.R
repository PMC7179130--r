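# broom-style accessors and plots -------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a contribution fit
#'
#' @param x a `cp_fit`.
#' @param ... unused.
#' @return The contribution tibble: `key`, `kind`, `contribution` (J/mol/K),
#'   `occurrences`, `molecules`, `valid`.
#' @export
tidy.cp_fit <- function(x, ...) x$contributions

#' One-row fit summary
#'
#' @param x a `cp_fit`.
#' @param ... unused.
#' @return A one-row tibble with compound/group counts, r2 and q2, average
#'   and standard deviations (training and cross-validated) and MAPD.
#' @export
glance.cp_fit <- function(x, ...) x$stats

#' Correlation plot of a fit
#'
#' Fitted values in black with the pooled cross-validation predictions
#' superimposed in red, against the experimental heat capacities.
#'
#' @param object a `cp_fit`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.cp_fit <- function(object, ...) {
  fit <- object$fitted
  cv <- object$cv[!object$cv$excluded, ]
  ggplot2::ggplot(fit, ggplot2::aes(x = .data$cp_exp, y = .data$cp_fit)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_point(data = cv,
                        ggplot2::aes(y = .data$cp_cv),
                        colour = "red", size = 1, shape = 1) +
    ggplot2::labs(x = "experimental Cp (J/mol/K)",
                  y = "calculated Cp (J/mol/K)",
                  title = "Group-additivity fit",
                  subtitle = "black: training fit; red: cross-validated") +
    ggplot2::theme_minimal()
}

#' Deviation plot for a fixture validation
#'
#' @param data result of [cp_validate_fixtures()].
#' @return A ggplot object showing recomputed against printed predictions.
#' @export
plot_fixture_validation <- function(data) {
  ggplot2::ggplot(data[!data$needs_3d, ],
                  ggplot2::aes(x = .data$cp_ga, y = .data$cp_calc,
                               colour = .data$source_table)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::labs(x = "printed prediction (J/mol/K)",
                  y = "recomputed prediction (J/mol/K)",
                  colour = "table") +
    ggplot2::theme_minimal()
}
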