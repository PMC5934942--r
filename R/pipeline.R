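#' Re-run a published family analysis from the packaged data
#'
#' Runs one of the two statistical engines on the packaged per-pair table of
#' a family and returns the result row in the layout of the published
#' summary tables (N, Mean, SE, Statistic, P-value, R2).
#'
#' @param family `"austronesian"`, `"indo_european"` or `"bantu"`.
#' @param analysis `"poisson"` (conditional-binomial Poisson rate
#'   regression on all pairs) or `"contrast"` (least-squares contrast
#'   regression after the Welch-Waxman filter).
#' @param response `"loss"` or `"gain"`.
#' @param ... Passed on to [fit_poisson_rates()] or [ww_filter()].
#' @return A one-row tibble with columns `family`, `analysis`, `response`,
#'   `n`, `mean`, `se`, `statistic`, `p_value`, `r2`.
#' @export
#' @examples
#' reproduce("indo_european", "poisson", "loss")
reproduce <- function(family = c("austronesian", "indo_european", "bantu"),
                      analysis = c("poisson", "contrast"),
                      response = c("loss", "gain"), ...) {
  family <- arg_match(family)
  analysis <- arg_match(analysis)
  response <- arg_match(response)
  data <- sister_pair_data(family)
  fit <- if (analysis == "poisson") {
    fit_poisson_rates(data, response = response, ...)
  } else {
    fit_contrast_regression(ww_filter(pair_contrasts(data, response), ...))
  }
  tibble(
    family = family, analysis = analysis, response = response,
    n = fit$n_pairs, mean = fit$estimate, se = fit$se,
    statistic = fit$statistic, p_value = fit$p_value, r2 = fit$r2
  )
}

#' Run the whole sister-pair pipeline on raw inputs
#'
#' Orchestrates ingestion, pair extraction, counting and both statistical
#' engines: wordlist (or cognate matrix) -> cherries above the support
#' threshold -> metadata filter -> per-pair gain/loss counts -> Poisson and
#' contrast fits for gains and losses. Deterministic given its inputs.
#'
#' @param wordlist A [cognate_matrix()] or path to a wordlist file.
#' @param tree An [ape::phylo], Newick string or path.
#' @param meta Language metadata (see [filter_pairs()]).
#' @param taxonomy Optional reference pair list (see [filter_pairs()]).
#' @param min_support Posterior-support threshold for cherries (default 0.8).
#' @param ww_args List of arguments for [ww_filter()].
#' @param out_dir If non-`NULL`, counts (CSV) and fits (JSON) are also
#'   written there.
#' @return A list with `counts` (per-pair table), `pairs`, `fits` (tibble of
#'   all four engine/response results) and `dropped` (pair removal log).
#' @export
run_pipeline <- function(wordlist, tree, meta, taxonomy = NULL,
                         min_support = 0.8, ww_args = list(),
                         out_dir = NULL) {
  cm <- if (inherits(wordlist, "cognate_matrix")) wordlist else read_wordlist(wordlist)
  unknown <- setdiff(cm_languages(cm), .as_phylo(tree)$tip.label)
  if (length(unknown)) {
    abort(paste0(
      "pair extraction: wordlist language(s) absent from tree: ",
      paste(unknown, collapse = ", ")
    ), class = "sisterates_validation_error")
  }
  cherries <- extract_cherries(tree, min_support = min_support)
  pairs <- filter_pairs(cherries, meta, taxonomy)
  counts <- count_pairs(cm, pairs)

  fits <- purrr::map(c("gain", "loss"), function(resp) {
    pois <- fit_poisson_rates(counts, response = resp)
    flt <- do.call(ww_filter, c(list(pair_contrasts(counts, resp)), ww_args))
    cst <- fit_contrast_regression(flt)
    bind_rows(
      tibble(analysis = "poisson", response = resp, n = pois$n_pairs,
             mean = pois$estimate, se = pois$se, statistic = pois$statistic,
             p_value = pois$p_value, r2 = pois$r2),
      tibble(analysis = "contrast", response = resp, n = cst$n_pairs,
             mean = cst$estimate, se = cst$se, statistic = cst$statistic,
             p_value = cst$p_value, r2 = cst$r2)
    )
  }) %>% bind_rows()

  out <- list(
    counts = counts, pairs = pairs, fits = fits,
    dropped = dropped_pairs(pairs)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(counts, file.path(out_dir, "counts.csv"))
    jsonlite::write_json(fits, file.path(out_dir, "fits.json"),
      dataframe = "rows", digits = NA
    )
  }
  out
}
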