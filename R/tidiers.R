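#' Tidy a rate-model fit
#'
#' @param x A `rate_fit` from [fit_poisson_rates()] or
#'   [fit_contrast_regression()].
#' @param ... Unused.
#' @return A one-row tibble with `engine`, `response`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @method tidy rate_fit
#' @export
tidy.rate_fit <- function(x, ...) {
  tibble(
    engine = x$engine,
    response = x$response,
    estimate = x$estimate,
    std.error = x$se,
    statistic = x$statistic,
    p.value = x$p_value
  )
}

#' Model-level summary of a rate-model fit
#'
#' @inheritParams tidy.rate_fit
#' @return A one-row tibble with `r.squared`, `statistic`, `p.value`,
#'   `n.pairs` and (for the Poisson engine) `logLik`.
#' @method glance rate_fit
#' @export
glance.rate_fit <- function(x, ...) {
  tibble(
    r.squared = x$r2,
    statistic = x$statistic,
    p.value = x$p_value,
    n.pairs = x$n_pairs,
    logLik = x$details$loglik %||% NA_real_
  )
}

#' Tidy a Welch-Waxman filter result
#'
#' @param x A `ww_filter` object.
#' @param ... Unused.
#' @return The removal log: one row per removed pair with `reason` and
#'   `step` (0 for pairs removed as undefined before iteration).
#' @method tidy ww_filter
#' @export
tidy.ww_filter <- function(x, ...) {
  x$removed
}

#' @rdname tidy.ww_filter
#' @method glance ww_filter
#' @export
glance.ww_filter <- function(x, ...) {
  tibble(
    n.retained = nrow(x$retained),
    n.removed = nrow(x$removed),
    n.undefined = sum(x$removed$reason != "ww_iteration"),
    stop_rule = x$stop_rule,
    final_slope = x$path$slope[nrow(x$path)],
    final_p = x$path$p_value[nrow(x$path)]
  )
}
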