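#' Standardized count and population contrasts for sister pairs
#'
#' For every pair, computes the standardized difference in event counts
#' \deqn{d = \frac{c_1 - c_2}{(c_1 + c_2)/2} \cdot \frac{1}{\sqrt{BL}}}
#' (difference divided by the members' average count and by the square root
#' of branch length, which puts pairs of different ages and data quantities
#' on one scale) and the matching population contrast
#' \deqn{x = \frac{\ln N_1 - \ln N_2}{\sqrt{BL}}.}
#' A contrast is undefined when the branch length is zero (no time for
#' change to accumulate) or both counts are zero (no events to compare);
#' such pairs are flagged rather than dropped, so the Welch-Waxman filter
#' can log them.
#'
#' @inheritParams fit_poisson_rates
#' @return A tibble with one row per pair: `pair`, `taxon1`, `taxon2`, `c1`,
#'   `c2`, `N1`, `N2`, `branch_length`, `d`, `x`, `abs_d`, `sqrt_bl`, and
#'   `undefined_reason` (`NA`, `"zero_branch"` or `"zero_counts"`).
#' @export
#' @examples
#' ie <- sister_pair_data("indo_european")
#' pair_contrasts(ie, response = "loss")
pair_contrasts <- function(data, response = c("loss", "gain"),
                           orientation = c("input", "population")) {
  response <- arg_match(response)
  wide <- .pairs_wide(data, response, arg_match(orientation))
  if (anyNA(wide$branch_length)) {
    abort("branch lengths are required for contrasts",
      class = "sisterates_validation_error"
    )
  }
  wide %>%
    mutate(
      undefined_reason = dplyr::case_when(
        .data$branch_length <= 0 ~ "zero_branch",
        .data$x1 + .data$x2 == 0 ~ "zero_counts",
        TRUE ~ NA_character_
      ),
      sqrt_bl = sqrt(pmax(.data$branch_length, 0)),
      d = ifelse(
        is.na(.data$undefined_reason),
        (.data$x1 - .data$x2) / ((.data$x1 + .data$x2) / 2) / .data$sqrt_bl,
        NA_real_
      ),
      x = ifelse(
        is.na(.data$undefined_reason),
        (log(.data$N1) - log(.data$N2)) / .data$sqrt_bl,
        NA_real_
      ),
      abs_d = abs(.data$d)
    ) %>%
    rename(c1 = "x1", c2 = "x2") %>%
    select(
      "pair", "taxon1", "taxon2", "c1", "c2", "N1", "N2",
      "branch_length", "sqrt_bl", "d", "x", "abs_d", "undefined_reason"
    ) %>%
    structure(response = response)
}

#' Welch-Waxman reliability filter for sister-pair contrasts
#'
#' Pairs that diverged only recently yield noisy standardized contrasts: a
#' handful of chance events over a short branch produces a huge `|d|`. The
#' filter first removes pairs with undefined contrasts, then repeatedly
#' regresses `|d|` on the square root of branch length and removes the
#' shallowest remaining pair for as long as that regression slope is
#' negative under the chosen stopping rule, i.e. until shallow pairs no
#' longer look systematically more extreme than deep ones.
#'
#' Stopping rules: `"one_sided"` (default) keeps removing while the slope is
#' negative with one-sided significance at `alpha`; `"two_sided"` uses the
#' two-sided p-value; `"strict"` removes while the slope is negative at all
#' (very aggressive; retained as the literal reading of the procedure).
#'
#' @param contrasts A tibble from [pair_contrasts()].
#' @param stop_rule One of `"one_sided"`, `"two_sided"`, `"strict"`.
#' @param alpha Significance level of the stopping test (default 0.05).
#' @param min_pairs Abort if the iteration would leave fewer pairs than this.
#' @return A `ww_filter` object: list with `retained` and `removed` tibbles
#'   (removal reasons `zero_branch`, `zero_counts`, `ww_iteration` with step
#'   order) and `path`, the per-iteration slope/p trace.
#' @export
#' @examples
#' cst <- pair_contrasts(sister_pair_data("indo_european"), "loss")
#' ww_filter(cst)
ww_filter <- function(contrasts,
                      stop_rule = c("one_sided", "two_sided", "strict"),
                      alpha = 0.05, min_pairs = 3) {
  stop_rule <- arg_match(stop_rule)
  contrasts <- as_tibble(contrasts)
  undef <- filter(contrasts, !is.na(.data$undefined_reason))
  removed <- tibble(
    pair = undef$pair, taxon1 = undef$taxon1, taxon2 = undef$taxon2,
    branch_length = undef$branch_length,
    reason = undef$undefined_reason, step = 0L
  )
  cur <- contrasts %>%
    filter(is.na(.data$undefined_reason)) %>%
    arrange(.data$branch_length, .data$taxon1)

  path <- list()
  step <- 0L
  repeat {
    if (nrow(cur) < min_pairs) {
      abort(paste0(
        "Welch-Waxman filter left fewer than ", min_pairs, " pairs"
      ), class = "sisterates_validation_error")
    }
    # a degenerate (perfect or constant) fit is handled by the guards below
    fit <- suppressWarnings(
      summary(lm(abs_d ~ sqrt_bl, data = cur))$coefficients
    )
    slope <- fit["sqrt_bl", "Estimate"]
    p_two <- fit["sqrt_bl", "Pr(>|t|)"]
    if (!is.finite(p_two)) p_two <- 1
    if (abs(slope) < 1e-12 * max(1, mean(cur$abs_d))) slope <- 0
    path[[length(path) + 1]] <- tibble(
      step = step, n = nrow(cur), slope = slope, p_value = p_two
    )
    keep_removing <- slope < 0 && switch(stop_rule,
      strict = TRUE,
      two_sided = p_two < alpha,
      one_sided = p_two / 2 < alpha
    )
    if (!keep_removing || nrow(cur) <= min_pairs) break
    step <- step + 1L
    victim <- cur[1, ]
    removed <- bind_rows(removed, tibble(
      pair = victim$pair, taxon1 = victim$taxon1, taxon2 = victim$taxon2,
      branch_length = victim$branch_length,
      reason = "ww_iteration", step = step
    ))
    cur <- cur[-1, ]
  }

  structure(
    list(
      retained = cur,
      removed = removed,
      path = bind_rows(path),
      stop_rule = stop_rule,
      alpha = alpha,
      response = attr(contrasts, "response", exact = TRUE)
    ),
    class = "ww_filter"
  )
}

#' @export
print.ww_filter <- function(x, ...) {
  cat(
    "<ww_filter> retained ", nrow(x$retained), " pairs; removed ",
    nrow(x$removed), " (",
    sum(x$removed$reason != "ww_iteration"), " undefined, ",
    sum(x$removed$reason == "ww_iteration"), " by iteration; rule ",
    x$stop_rule, ")\n",
    sep = ""
  )
  invisible(x)
}

#' Least-squares regression of count contrasts on population contrasts
#'
#' Ordinary least squares of the standardized count difference `d` on the
#' standardized log-population difference `x`, with intercept. The reported
#' statistic is the F statistic of the slope (the squared t), the R-squared
#' is adjusted.
#'
#' @param x A `ww_filter` object or a [pair_contrasts()] tibble (undefined
#'   contrasts are dropped).
#' @return A `rate_fit` object with the underlying `lm` in
#'   `details$model`.
#' @export
#' @examples
#' cst <- pair_contrasts(sister_pair_data("indo_european"), "loss")
#' fit_contrast_regression(ww_filter(cst))
fit_contrast_regression <- function(x) {
  response <- if (inherits(x, "ww_filter")) x$response else {
    attr(x, "response", exact = TRUE)
  }
  cst <- if (inherits(x, "ww_filter")) x$retained else {
    filter(as_tibble(x), is.na(.data$undefined_reason))
  }
  if (nrow(cst) < 3) {
    abort("need at least three defined contrasts",
      class = "sisterates_validation_error"
    )
  }
  if (diff(range(cst$x)) < .Machine$double.eps^0.5) {
    abort("population contrasts are constant; slope is not identifiable",
      class = "sisterates_validation_error"
    )
  }
  model <- lm(d ~ x, data = cst)
  sm <- summary(model)
  slope <- sm$coefficients["x", ]
  new_rate_fit(
    engine = "contrast",
    response = response %||% NA_character_,
    estimate = unname(slope["Estimate"]),
    se = unname(slope["Std. Error"]),
    statistic = unname(slope["t value"]^2),
    p_value = unname(slope["Pr(>|t|)"]),
    r2 = sm$adj.r.squared,
    n_pairs = nrow(cst),
    details = list(model = model, r2_plain = sm$r.squared)
  )
}
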