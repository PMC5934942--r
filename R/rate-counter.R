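#' Classify a cognate-class presence pattern for a sister pair
#'
#' Implements the rates-informative classification. For a cognate class
#' observed across a language family, only two patterns localise a change to
#' one member of a sister pair: presence in one member and at least one
#' non-pair family language (the other member must have *lost* the ancestral
#' class), and presence in one member only, with no cognates anywhere else in
#' the family (a *gain* of a new word since the split). A class present in
#' both members was inherited by both (non-informative); a class absent from
#' both is assumed absent from their common ancestor (excluded), as are all
#' classes of concepts not documented in both members.
#'
#' @param in1,in2 Logical; class present in member 1 / member 2.
#' @param elsewhere Logical; class present in at least one family language
#'   outside the pair.
#' @param concept_attested Logical; the class's concept is documented in both
#'   members (default `TRUE`).
#' @return A character vector over
#'   `c("gain1", "gain2", "loss1", "loss2", "noninformative", "excluded")`.
#' @export
#' @examples
#' classify_pattern(TRUE, FALSE, TRUE)  # lost by member 2
#' classify_pattern(TRUE, FALSE, FALSE) # gained by member 1
#' classify_pattern(TRUE, TRUE, FALSE)  # shared inheritance, non-informative
classify_pattern <- function(in1, in2, elsewhere, concept_attested = TRUE) {
  n <- max(length(in1), length(in2), length(elsewhere), length(concept_attested))
  in1 <- rep_len(as.logical(in1), n)
  in2 <- rep_len(as.logical(in2), n)
  elsewhere <- rep_len(as.logical(elsewhere), n)
  concept_attested <- rep_len(as.logical(concept_attested), n)
  out <- rep("excluded", n)
  ok <- concept_attested
  out[ok & in1 & in2] <- "noninformative"
  out[ok & in1 & !in2 & elsewhere] <- "loss2"
  out[ok & in1 & !in2 & !elsewhere] <- "gain1"
  out[ok & !in1 & in2 & elsewhere] <- "loss1"
  out[ok & !in1 & in2 & !elsewhere] <- "gain2"
  out
}

#' Count word gains and losses for one sister pair
#'
#' Iterates over every cognate class recorded anywhere in the family matrix
#' and tallies the classification of [classify_pattern()] for the given
#' pair. Each class is one potential event regardless of semantic category
#' (languages may hold several words per concept, so a gain does not imply a
#' loss). Classes belonging to concepts not documented in both members are
#' counted as excluded, since their absence cannot be told apart from
#' missing data.
#'
#' @param x A [cognate_matrix()] for the family.
#' @param lang1,lang2 The two member languages (must be in the matrix).
#' @return A one-row tibble with columns `gains1`, `gains2`, `losses1`,
#'   `losses2`, `noninformative`, `excluded`, `total`. The components always
#'   sum to `total`, the number of classes compared.
#' @export
count_pair <- function(x, lang1, lang2) {
  stopifnot(inherits(x, "cognate_matrix"))
  langs <- cm_languages(x)
  missing_langs <- setdiff(c(lang1, lang2), langs)
  if (length(missing_langs)) {
    abort(paste0("language(s) not in matrix: ",
                 paste(missing_langs, collapse = ", ")),
      class = "sisterates_validation_error"
    )
  }
  env <- .counting_env(x)
  as_tibble(as.list(.count_pair_fast(env, lang1, lang2)))
}

# Precompute integer-indexed structures shared across pairs of one matrix.
.counting_env <- function(x) {
  pres <- x$presence
  concept_levels <- sort(unique(c(pres$concept, x$attested$concept)))
  classes <- distinct(pres, .data$concept, .data$class_id)
  ckey <- paste(classes$concept, classes$class_id, sep = "\r")
  pres_key <- match(paste(pres$concept, pres$class_id, sep = "\r"), ckey)
  n_occ <- tabulate(pres_key, nbins = length(ckey))
  att <- x$attested
  list(
    n_classes = length(ckey),
    class_concept = match(classes$concept, concept_levels),
    n_occ = n_occ,
    by_lang = split(pres_key, pres$language),
    att_by_lang = split(match(att$concept, concept_levels), att$language)
  )
}

# Direct tally of the classify_pattern() labels; equivalence with the
# label-by-label classifier is asserted in the test suite.
.count_pair_fast <- function(env, lang1, lang2) {
  k <- env$n_classes
  in1 <- logical(k); in1[env$by_lang[[lang1]]] <- TRUE
  in2 <- logical(k); in2[env$by_lang[[lang2]]] <- TRUE
  elsewhere <- (env$n_occ - in1 - in2) > 0
  att <- env$class_concept %in%
    intersect(env$att_by_lang[[lang1]], env$att_by_lang[[lang2]])
  only1 <- att & in1 & !in2
  only2 <- att & !in1 & in2
  gains1 <- sum(only1 & !elsewhere)
  gains2 <- sum(only2 & !elsewhere)
  losses1 <- sum(only2 & elsewhere)
  losses2 <- sum(only1 & elsewhere)
  noninf <- sum(att & in1 & in2)
  c(
    gains1 = gains1, gains2 = gains2,
    losses1 = losses1, losses2 = losses2,
    noninformative = noninf,
    excluded = k - gains1 - gains2 - losses1 - losses2 - noninf,
    total = k
  )
}

#' Count gains and losses for a table of sister pairs
#'
#' Applies [count_pair()] to every row of a pair table and returns the
#' per-pair analysis table used by the statistical engines (two rows per
#' pair, one per member, mirroring the published per-pair data layout).
#'
#' @param x A [cognate_matrix()].
#' @param pairs A data frame with columns `lang1`, `lang2` and optionally
#'   `N1`, `N2`, `branch_length`, `support` (as from [extract_cherries()] +
#'   [filter_pairs()]).
#' @return A tibble with columns `pair`, `taxon`, `gain`, `loss`, `total`
#'   (gain + loss) plus any of `population`, `branch_length` available, two
#'   rows per pair in member order.
#' @export
count_pairs <- function(x, pairs) {
  stopifnot(inherits(x, "cognate_matrix"))
  pairs <- as_tibble(pairs)
  env <- .counting_env(x)
  np <- nrow(pairs)
  cnt <- matrix(0L, nrow = np, ncol = 7, dimnames = list(NULL, c(
    "gains1", "gains2", "losses1", "losses2", "noninformative",
    "excluded", "total"
  )))
  for (i in seq_len(np)) {
    cnt[i, ] <- .count_pair_fast(env, pairs$lang1[i], pairs$lang2[i])
  }
  out <- tibble(
    pair = rep(seq_len(np), each = 2),
    taxon = as.vector(rbind(pairs$lang1, pairs$lang2)),
    gain = as.vector(rbind(cnt[, "gains1"], cnt[, "gains2"])),
    loss = as.vector(rbind(cnt[, "losses1"], cnt[, "losses2"])),
    noninformative = rep(cnt[, "noninformative"], each = 2),
    excluded = rep(cnt[, "excluded"], each = 2),
    comparisons = rep(cnt[, "total"], each = 2)
  )
  out$total <- out$gain + out$loss
  if (!is.null(pairs$N1)) {
    out$population <- as.vector(rbind(pairs$N1, pairs$N2))
  }
  if (!is.null(pairs$branch_length)) {
    out$branch_length <- rep(pairs$branch_length, each = 2)
  }
  select(out, "pair", "taxon", "gain", "loss", "total", dplyr::everything())
}

#' Standardize gain/loss counts by the number of comparisons
#'
#' Divides the per-member gain and loss tallies by the total number of
#' comparisons made for the pair (gains + losses + non-informative +
#' excluded), so that rates are comparable across pairs with different
#' amounts of data.
#'
#' @param counts A one-row tibble from [count_pair()] (or several rows).
#' @return The input with `gain_rate1`, `gain_rate2`, `loss_rate1`,
#'   `loss_rate2` columns added; all rates lie in `[0, 1]`.
#' @export
standardize_counts <- function(counts) {
  counts <- as_tibble(counts)
  if (any(counts$total <= 0)) {
    abort("cannot standardize: a pair has zero compared classes",
      class = "sisterates_validation_error"
    )
  }
  mutate(counts,
    gain_rate1 = .data$gains1 / .data$total,
    gain_rate2 = .data$gains2 / .data$total,
    loss_rate1 = .data$losses1 / .data$total,
    loss_rate2 = .data$losses2 / .data$total
  )
}
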