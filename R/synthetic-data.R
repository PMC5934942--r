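#' Configuration for the synthetic language-family generator
#'
#' Bundles and validates the generating parameters of [simulate_family()].
#' The defaults emulate the scale of the real per-pair data: basic
#' vocabularies of a couple of hundred concepts with about one inherited
#' cognate class per concept, speaker populations spanning hundreds to tens
#' of millions (log-uniform), dated divergences of a few hundred to a couple
#' of thousand time units, and baseline rates that yield tens of loss and
#' gain events per language over a typical branch.
#'
#' @param n_pairs Number of sister pairs.
#' @param n_outgroups Number of outgroup languages available to attest
#'   ancestral classes.
#' @param n_concepts Number of semantic categories.
#' @param ancestral_classes_per_concept Mean number of cognate classes per
#'   concept in each pair's ancestral language (Poisson-distributed).
#' @param beta_gain,beta_loss True population-size exponents of the gain and
#'   loss rates.
#' @param a_gain Baseline gain rate: expected gains per unit branch length
#'   for a language with \eqn{N^{\beta} = 1}.
#' @param a_loss Baseline per-class loss hazard per unit branch length for a
#'   language with \eqn{N^{\beta} = 1}.
#' @param pop_log_range Range of log10 population size (drawn uniformly).
#' @param bl_range Range of pair branch lengths (drawn uniformly).
#' @param outgroup_retention Probability that an ancestral class is attested
#'   in at least one outgroup; a class attested nowhere outside the pair is
#'   invisible as a loss.
#' @param seed RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_pairs = 80, n_outgroups = 5, n_concepts = 200,
                       ancestral_classes_per_concept = 1,
                       beta_gain = 0, beta_loss = 0,
                       a_gain = 0.075, a_loss = 2e-4,
                       pop_log_range = c(2, 7), bl_range = c(200, 1500),
                       outgroup_retention = 0.9, seed = 1L) {
  cfg <- list(
    n_pairs = as.integer(n_pairs), n_outgroups = as.integer(n_outgroups),
    n_concepts = as.integer(n_concepts),
    ancestral_classes_per_concept = ancestral_classes_per_concept,
    beta_gain = beta_gain, beta_loss = beta_loss,
    a_gain = a_gain, a_loss = a_loss,
    pop_log_range = as.numeric(pop_log_range),
    bl_range = as.numeric(bl_range),
    outgroup_retention = outgroup_retention, seed = as.integer(seed)
  )
  if (cfg$n_pairs < 1 || cfg$n_concepts < 1) {
    abort("need at least one pair and one concept",
      class = "sisterates_validation_error")
  }
  if (cfg$a_gain < 0 || cfg$a_loss < 0 ||
      cfg$ancestral_classes_per_concept < 0) {
    abort("rates must be non-negative", class = "sisterates_validation_error")
  }
  if (cfg$outgroup_retention < 0 || cfg$outgroup_retention > 1) {
    abort("outgroup_retention must lie in [0, 1]",
      class = "sisterates_validation_error")
  }
  if (cfg$outgroup_retention > 0 && cfg$n_outgroups < 1) {
    abort("outgroup_retention > 0 needs at least one outgroup",
      class = "sisterates_validation_error")
  }
  if (diff(cfg$pop_log_range) < 0 || diff(cfg$bl_range) < 0 ||
      cfg$bl_range[1] <= 0) {
    abort("ranges must be ordered and branch lengths positive",
      class = "sisterates_validation_error")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a language family with population-dependent gain/loss rates
#'
#' Each sister pair descends from its own ancestral language carrying a
#' Poisson number of cognate classes per concept. Over its branch of length
#' \eqn{t}, member \eqn{i} (population \eqn{N_i}) loses each ancestral class
#' independently with probability
#' \eqn{1 - \exp(-a_{loss} N_i^{\beta_{loss}} t)} and gains a Poisson
#' \eqn{(a_{gain} N_i^{\beta_{gain}} t)} number of brand-new classes, each a
#' family-unique singleton. Every ancestral class is additionally attested
#' in a random outgroup with probability `outgroup_retention`; a class
#' attested nowhere outside the pair cannot be recognised as a loss by the
#' counting rules (its surviving copy, if any, looks like a gain).
#'
#' The returned truth table reports both the raw event counts and the
#' *observable* counts implied by the presence logic: a class lost by both
#' members is absent from both and therefore intrinsically uncountable, and
#' a loss is only recognisable when the class is attested outside the pair.
#'
#' @param config A [sim_config()].
#' @return A list with components `matrix` ([cognate_matrix()]), `pairs`
#'   (tibble: `lang1`, `lang2`, `N1`, `N2`, `support`, `branch_length`),
#'   `meta` (metadata table for [filter_pairs()]), `tree` ([ape::phylo],
#'   ultrametric, cherries with support 1), and `truth` (per-language tibble
#'   with `gain_events`, `loss_events`, `obs_gains`, `obs_losses`).
#' @export
#' @examples
#' sim <- simulate_family(sim_config(n_pairs = 4, n_concepts = 20, seed = 42))
#' count_pairs(sim$matrix, sim$pairs)
simulate_family <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  P <- config$n_pairs
  concepts <- sprintf("c%04d", seq_len(config$n_concepts))
  pair_ids <- sprintf("P%03d", seq_len(P))
  lang1 <- paste0(pair_ids, "a")
  lang2 <- paste0(pair_ids, "b")
  outgroups <- if (config$n_outgroups > 0) {
    sprintf("OG%02d", seq_len(config$n_outgroups))
  } else {
    character()
  }

  t_j <- runif(P, config$bl_range[1], config$bl_range[2])
  N1 <- 10^runif(P, config$pop_log_range[1], config$pop_log_range[2])
  N2 <- 10^runif(P, config$pop_log_range[1], config$pop_log_range[2])

  # ancestral inventory: one independent stock per pair
  n_anc <- rpois(P * config$n_concepts, config$ancestral_classes_per_concept)
  slot <- rep(seq_along(n_anc), n_anc)
  anc <- tibble(
    pair = (slot - 1L) %/% config$n_concepts + 1L,
    concept = concepts[(slot - 1L) %% config$n_concepts + 1L],
    copy = sequence(n_anc[n_anc > 0])
  )
  anc$class_id <- paste0("anc_", pair_ids[anc$pair], "_", anc$concept, "_",
                         anc$copy)

  loss_p1 <- 1 - exp(-config$a_loss * N1^config$beta_loss * t_j)
  loss_p2 <- 1 - exp(-config$a_loss * N2^config$beta_loss * t_j)
  anc$lost1 <- runif(nrow(anc)) < loss_p1[anc$pair]
  anc$lost2 <- runif(nrow(anc)) < loss_p2[anc$pair]
  anc$elsewhere <- runif(nrow(anc)) < config$outgroup_retention
  anc$og <- if (length(outgroups)) {
    sample(outgroups, nrow(anc), replace = TRUE)
  } else {
    NA_character_
  }

  gain_n1 <- rpois(P, config$a_gain * N1^config$beta_gain * t_j)
  gain_n2 <- rpois(P, config$a_gain * N2^config$beta_gain * t_j)
  mk_gains <- function(langs, counts) {
    idx <- rep(seq_len(P), counts)
    if (!length(idx)) {
      return(tibble(language = character(), concept = character(),
                    class_id = character(), pair = integer()))
    }
    tibble(
      pair = idx,
      language = langs[idx],
      concept = sample(concepts, length(idx), replace = TRUE),
      class_id = paste0("new_", langs[idx], "_", sequence(counts[counts > 0]))
    )
  }
  gains1 <- mk_gains(lang1, gain_n1)
  gains2 <- mk_gains(lang2, gain_n2)

  presence <- bind_rows(
    anc %>% filter(!.data$lost1) %>%
      mutate(language = lang1[.data$pair]) %>%
      select("language", "concept", "class_id"),
    anc %>% filter(!.data$lost2) %>%
      mutate(language = lang2[.data$pair]) %>%
      select("language", "concept", "class_id"),
    anc %>% filter(.data$elsewhere, !is.na(.data$og)) %>%
      select(language = "og", "concept", "class_id"),
    select(gains1, "language", "concept", "class_id"),
    select(gains2, "language", "concept", "class_id")
  )
  all_langs <- c(lang1, lang2, outgroups)
  attested <- tidyr::expand_grid(language = all_langs, concept = concepts)
  cm <- cognate_matrix(presence, attested)

  per_pair <- anc %>%
    group_by(.data$pair) %>%
    summarise(
      loss1 = sum(.data$lost1),
      loss2 = sum(.data$lost2),
      obs_loss1 = sum(.data$lost1 & !.data$lost2 & .data$elsewhere),
      obs_loss2 = sum(.data$lost2 & !.data$lost1 & .data$elsewhere),
      ghost1 = sum(!.data$lost1 & .data$lost2 & !.data$elsewhere),
      ghost2 = sum(!.data$lost2 & .data$lost1 & !.data$elsewhere),
      .groups = "drop"
    ) %>%
    tidyr::complete(pair = seq_len(P),
                    fill = list(loss1 = 0L, loss2 = 0L, obs_loss1 = 0L,
                                obs_loss2 = 0L, ghost1 = 0L, ghost2 = 0L))

  truth <- bind_rows(
    tibble(
      pair = seq_len(P), language = lang1, population = N1,
      branch_length = t_j,
      gain_events = gain_n1, loss_events = per_pair$loss1,
      obs_gains = gain_n1 + per_pair$ghost1, obs_losses = per_pair$obs_loss1
    ),
    tibble(
      pair = seq_len(P), language = lang2, population = N2,
      branch_length = t_j,
      gain_events = gain_n2, loss_events = per_pair$loss2,
      obs_gains = gain_n2 + per_pair$ghost2, obs_losses = per_pair$obs_loss2
    )
  ) %>% arrange(.data$pair, .data$language)

  pairs <- tibble(
    lang1 = lang1, lang2 = lang2, N1 = N1, N2 = N2,
    support = 1, branch_length = t_j
  )
  meta <- tibble(
    language = all_langs,
    population = c(N1, N2, rep(1e4, length(outgroups))),
    creole = FALSE, extinct = FALSE
  )

  height <- max(t_j) * 1.25
  cherry_txt <- sprintf(
    "(%s:%.6f,%s:%.6f)1.0:%.6f", lang1, t_j, lang2, t_j, height - t_j
  )
  og_txt <- if (length(outgroups)) sprintf("%s:%.6f", outgroups, height) else character()
  clades <- c(cherry_txt, og_txt)
  # binary root (first clade vs the rest) so the tree is unambiguously rooted
  newick <- if (length(clades) == 1) {
    paste0("(", clades, ");")
  } else if (length(clades) == 2) {
    paste0("(", clades[1], ",", clades[2], ");")
  } else {
    paste0("(", clades[1], ",(",
           paste(clades[-1], collapse = ","), "):0);")
  }
  tree <- ape::read.tree(text = newick)

  list(matrix = cm, pairs = pairs, meta = meta, tree = tree, truth = truth,
       config = config)
}

#' Parameter-recovery and calibration experiment
#'
#' Repeatedly simulates a family, runs the counting pipeline
#' ([count_pairs()]) on the emitted matrix, fits the chosen estimator to the
#' recovered counts, and summarises bias, RMSE and the rejection rate of the
#' test of no population effect. With the true exponent at zero the
#' rejection rate estimates the type-I error of the test.
#'
#' @param config A [sim_config()]; `config$seed` seeds replicate `i` with
#'   `seed + i`.
#' @param n_replicates Number of simulated families.
#' @param estimator `"poisson"` (conditional-binomial fit) or `"contrast"`
#'   (Welch-Waxman filtered least squares).
#' @param response `"loss"` or `"gain"` (determines which truth exponent is
#'   the target).
#' @param alpha Nominal level used for the rejection-rate summary.
#' @return A list with `replicates` (tibble of per-replicate `estimate`,
#'   `p_value`) and `summary` (one-row tibble: truth, mean and median
#'   estimate, bias, RMSE, rejection rate).
#' @export
recovery_experiment <- function(config = sim_config(), n_replicates = 50,
                                estimator = c("poisson", "contrast"),
                                response = c("loss", "gain"),
                                alpha = 0.05) {
  estimator <- arg_match(estimator)
  response <- arg_match(response)
  truth <- if (response == "loss") config$beta_loss else config$beta_gain
  reps <- purrr::map(seq_len(n_replicates), function(i) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i
    sim <- simulate_family(cfg_i)
    counts <- count_pairs(sim$matrix, sim$pairs)
    fit <- if (estimator == "poisson") {
      fit_poisson_rates(counts, response = response)
    } else {
      fit_contrast_regression(ww_filter(pair_contrasts(counts, response)))
    }
    tibble(replicate = i, estimate = fit$estimate, p_value = fit$p_value)
  }) %>% bind_rows()

  summary <- tibble(
    estimator = estimator, response = response, truth = truth,
    n_replicates = n_replicates,
    mean_estimate = mean(reps$estimate),
    median_estimate = stats::median(reps$estimate),
    bias = mean(reps$estimate) - truth,
    rmse = sqrt(mean((reps$estimate - truth)^2)),
    rejection_rate = mean(reps$p_value < alpha)
  )
  list(replicates = reps, summary = summary)
}
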