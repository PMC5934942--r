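#' Plot sister-pair contrasts against population contrasts
#'
#' Scatter of standardized count contrasts `d` against population contrasts
#' `x`, with the least-squares line. When given a `ww_filter` object,
#' removed pairs are shown hollow.
#'
#' @param object A [pair_contrasts()] tibble or a `ww_filter` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ww_filter
#' @export
autoplot.ww_filter <- function(object, ...) {
  dat <- object$retained
  removed_ids <- object$removed$pair
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$d)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::labs(
      x = expression(Delta * ln(N) / sqrt(BL)),
      y = "standardized count contrast d",
      title = sprintf("Retained pairs after Welch-Waxman filter (n = %d, %d removed)",
                      nrow(object$retained), length(removed_ids))
    ) +
    ggplot2::theme_minimal()
}

#' Diagnostic plot of the Welch-Waxman removal path
#'
#' Shows `|d|` against the square root of branch length for retained and
#' removed pairs; the downweighting of shallow pairs is visible as the
#' hollow points at the left.
#'
#' @param x A `ww_filter` object.
#' @return A ggplot object.
#' @export
plot_ww_path <- function(x) {
  stopifnot(inherits(x, "ww_filter"))
  dat <- bind_rows(
    mutate(x$retained, status = "retained"),
    x$removed %>%
      filter(.data$reason == "ww_iteration") %>%
      mutate(status = "removed", sqrt_bl = sqrt(.data$branch_length),
             abs_d = NA_real_)
  )
  ggplot2::ggplot(
    filter(dat, !is.na(.data$abs_d)),
    ggplot2::aes(x = .data$sqrt_bl, y = .data$abs_d)
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::geom_rug(
      data = filter(dat, .data$status == "removed"),
      ggplot2::aes(x = .data$sqrt_bl), inherit.aes = FALSE, colour = "grey50"
    ) +
    ggplot2::labs(
      x = expression(sqrt(branch ~ length)),
      y = "|standardized contrast|",
      title = "Welch-Waxman reliability diagnostic"
    ) +
    ggplot2::theme_minimal()
}

#' Observed versus fitted split of pair totals under the Poisson model
#'
#' For each pair, plots the observed share of events in member 1 against the
#' model's fitted split probability; a well-fitting population effect moves
#' points along the diagonal away from 0.5.
#'
#' @param object A `rate_fit` from [fit_poisson_rates()].
#' @param data The per-pair table the model was fitted to.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rate_fit
#' @export
autoplot.rate_fit <- function(object, data = NULL, ...) {
  if (object$engine == "contrast") {
    m <- object$details$model
    dat <- m$model
    return(
      ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$d)) +
        ggplot2::geom_point() +
        ggplot2::geom_abline(
          intercept = coef(m)[1], slope = coef(m)[2], colour = "steelblue"
        ) +
        ggplot2::labs(
          x = expression(Delta * ln(N) / sqrt(BL)),
          y = "standardized count contrast d",
          title = sprintf("Contrast regression (slope %.3f, p = %.3g)",
                          object$estimate, object$p_value)
        ) +
        ggplot2::theme_minimal()
    )
  }
  if (is.null(data)) {
    abort("autoplot for a Poisson rate_fit needs the per-pair `data`",
      class = "sisterates_validation_error")
  }
  wide <- .pairs_wide(data, object$response)
  wide <- filter(wide, .data$x1 + .data$x2 > 0)
  wide$observed <- wide$x1 / (wide$x1 + wide$x2)
  wide$fitted <- split_probability(wide$N1, wide$N2, object$estimate)
  ggplot2::ggplot(wide, ggplot2::aes(x = .data$fitted, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "fitted split probability",
      y = "observed share of events in member 1",
      title = sprintf("Poisson rate model (beta = %.3f, LRT = %.2f)",
                      object$estimate, object$statistic)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
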