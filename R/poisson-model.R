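#' Conditional split probability of the Poisson rate model
#'
#' Under the rate model, the event count of member \eqn{i} of pair \eqn{j}
#' is Poisson with mean \eqn{\mu_j N_i^\beta}: the per-pair nuisance
#' \eqn{\mu_j} absorbs divergence time and data quantity, and \eqn{\beta} is
#' the exponent of speaker population size on the rate (rates are linear in
#' population size on a log-log scale). Conditioning on the pair total
#' removes \eqn{\mu_j}: member 1's count is binomial with probability
#' \deqn{p = N_1^\beta / (N_1^\beta + N_2^\beta),}
#' computed here in log space for numerical stability. This is how the model
#' controls for phylogeny without divergence dates: each pair contributes
#' only the split of its own total.
#'
#' @param N1,N2 Speaker population sizes (persons, positive).
#' @param beta Population-size exponent.
#' @return The split probability, in (0, 1); `0.5` when `beta = 0` or
#'   `N1 = N2`.
#' @export
#' @examples
#' split_probability(100, 1, 1) # 100/101
#' split_probability(1e6, 10, 0) # 0.5
split_probability <- function(N1, N2, beta) {
  if (any(N1 <= 0) || any(N2 <= 0)) {
    abort("populations must be positive", class = "sisterates_validation_error")
  }
  # p = 1 / (1 + exp(beta * (log N2 - log N1)))
  stats::plogis(beta * (log(N1) - log(N2)))
}

#' Conditional log-likelihood of the Poisson rate model
#'
#' Sum over pairs of the binomial log-probability of member 1's count given
#' the pair total, at split probabilities [split_probability()]. Pairs with
#' a zero total contribute nothing. Depends on populations only through
#' their ratios, so it is invariant to rescaling all populations by a
#' common factor.
#'
#' @param beta Population-size exponent.
#' @param N1,N2 Numeric vectors of member populations, one entry per pair.
#' @param x1,x2 Non-negative integer event counts per member.
#' @return The log-likelihood (a scalar).
#' @export
poisson_loglik <- function(beta, N1, N2, x1, x2) {
  p <- split_probability(N1, N2, beta)
  sum(dbinom(x1, x1 + x2, p, log = TRUE))
}

#' Fit the population-size Poisson rate model to sister-pair counts
#'
#' Maximises the conditional binomial likelihood over the population
#' exponent `beta`, and reports a likelihood-ratio test against the null of
#' no population-size effect (`beta = 0`), a Wald standard error from the
#' observed information, and a pseudo-R-squared.
#'
#' @param data A per-pair table in long form (two rows per pair) with
#'   columns `pair`, `taxon`, `gain`, `loss`, `population` — e.g. from
#'   [count_pairs()] or [sister_pair_data()].
#' @param response Which event counts to model: `"loss"` or `"gain"`.
#' @param orientation Member order; `"input"` keeps the row order of `data`
#'   (the likelihood itself is orientation-symmetric, only the sign
#'   convention of `beta` relative to member labels changes).
#' @param r2 Pseudo-R-squared flavour: `"deviance"` (default) is the share
#'   of null deviance explained, \eqn{(l_1 - l_0) / (l_{sat} - l_0)};
#'   `"mcfadden"` is \eqn{1 - l_1 / l_0} on the conditional likelihood
#'   including binomial coefficients; `"mcfadden_kernel"` drops the
#'   coefficients.
#' @param se Standard-error flavour: `"wald"` (observed information) or
#'   `"dispersion"` (Wald scaled by the square root of the deviance
#'   dispersion, a quasi-likelihood correction for overdispersed counts).
#' @param interval Search interval for `beta`.
#' @return A `rate_fit` object; see [tidy.rate_fit()].
#' @export
#' @examples
#' ie <- sister_pair_data("indo_european")
#' fit_poisson_rates(ie, response = "loss")
fit_poisson_rates <- function(data, response = c("loss", "gain"),
                              orientation = c("input", "population"),
                              r2 = c("deviance", "mcfadden", "mcfadden_kernel"),
                              se = c("wald", "dispersion"),
                              interval = c(-5, 5)) {
  response <- arg_match(response)
  r2 <- arg_match(r2)
  se <- arg_match(se)
  wide <- .pairs_wide(data, response, arg_match(orientation))
  if (anyNA(wide$N1) || anyNA(wide$N2)) {
    abort("population sizes are required for the Poisson rate model",
      class = "sisterates_validation_error"
    )
  }
  keep <- wide$x1 + wide$x2 > 0
  if (sum(keep) < 2) {
    abort("need at least two pairs with non-zero totals",
      class = "sisterates_validation_error"
    )
  }
  N1 <- wide$N1[keep]; N2 <- wide$N2[keep]
  x1 <- wide$x1[keep]; x2 <- wide$x2[keep]
  n <- x1 + x2

  ll <- function(b) poisson_loglik(b, N1, N2, x1, x2)
  opt <- optimize(ll, interval, maximum = TRUE, tol = 1e-8)
  beta_hat <- .newton_polish(ll, opt$maximum, interval)
  l1 <- ll(beta_hat)
  l0 <- ll(0)
  if (abs(beta_hat) > max(abs(interval)) - 1e-3) {
    abort(paste0(
      "optimizer hit the boundary of the search interval at beta = ",
      signif(beta_hat, 4), "; the fit did not converge"
    ), class = "sisterates_convergence_error")
  }

  h <- 1e-4 * max(1, abs(beta_hat))
  info <- -(ll(beta_hat + h) - 2 * l1 + ll(beta_hat - h)) / h^2
  se_hat <- if (info > 0) 1 / sqrt(info) else NA_real_

  lsat <- sum(dbinom(x1, n, x1 / n, log = TRUE))
  if (se == "dispersion" && !is.na(se_hat)) {
    disp <- 2 * (lsat - l1) / max(1, length(x1) - 1)
    se_hat <- se_hat * sqrt(max(disp, 1))
  }
  statistic <- max(0, 2 * (l1 - l0))
  r2_val <- switch(r2,
    deviance = (l1 - l0) / (lsat - l0),
    mcfadden = 1 - l1 / l0,
    mcfadden_kernel = {
      kern <- function(b) {
        p <- split_probability(N1, N2, b)
        sum(x1 * log(p) + x2 * log1p(-p))
      }
      1 - kern(beta_hat) / kern(0)
    }
  )

  new_rate_fit(
    engine = "poisson",
    response = response,
    estimate = beta_hat,
    se = se_hat,
    statistic = statistic,
    p_value = pchisq(statistic, df = 1, lower.tail = FALSE),
    r2 = r2_val,
    n_pairs = length(x1),
    details = list(
      loglik = l1, loglik_null = l0, loglik_saturated = lsat,
      r2_method = r2, se_method = se, n_pairs_input = nrow(wide)
    )
  )
}

# One or two guarded Newton steps to polish the golden-section optimum.
.newton_polish <- function(ll, b, interval, steps = 2) {
  for (i in seq_len(steps)) {
    h <- 1e-5 * max(1, abs(b))
    g <- (ll(b + h) - ll(b - h)) / (2 * h)
    hess <- (ll(b + h) - 2 * ll(b) + ll(b - h)) / h^2
    if (!is.finite(g) || !is.finite(hess) || hess >= 0) break
    b_new <- b - g / hess
    if (b_new < interval[1] || b_new > interval[2]) break
    if (ll(b_new) < ll(b)) break
    b <- b_new
  }
  b
}

new_rate_fit <- function(engine, response, estimate, se, statistic, p_value,
                         r2, n_pairs, details = list()) {
  structure(
    list(
      engine = engine, response = response, estimate = estimate, se = se,
      statistic = statistic, p_value = p_value, r2 = r2, n_pairs = n_pairs,
      details = details
    ),
    class = "rate_fit"
  )
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(
    "<rate_fit> ", x$engine, " regression of ", x$response,
    " counts on population size\n",
    sep = ""
  )
  cat(sprintf(
    "  n_pairs = %d, estimate = %.4f (SE %.4f), statistic = %.3f, p = %.4g, R2 = %.4f\n",
    x$n_pairs, x$estimate, x$se, x$statistic, x$p_value, x$r2
  ))
  invisible(x)
}
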