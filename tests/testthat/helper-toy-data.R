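# Small in-code fixtures shared across test files.

# Write a wordlist CSV and return its path.
write_toy_wordlist <- function(rows, path = tempfile(fileext = ".csv")) {
  readr::write_csv(rows, path)
  path
}

toy_wordlist_rows <- function() {
  tibble::tribble(
    ~language, ~concept, ~form, ~cognate_class, ~loan, ~status,
    "A", "hand", "mano", "1", "false", "ok",
    "A", "water", "agua", "1", "false", "ok",
    "B", "hand", "main", "1", "false", "ok"
  )
}

# The worked 4-language family: pair (A, B) should tally
# gains1 = 1, losses2 = 1, noninformative = 2, excluded = 3 (total 7).
toy_family_matrix <- function() {
  presence <- tibble::tribble(
    ~language, ~concept, ~class_id,
    "A", "c1", "x",
    "B", "c1", "x",
    "A", "c1", "y",
    "B", "c1", "y",
    "C", "c1", "y",
    "A", "c1", "g",
    "A", "c2", "l",
    "C", "c2", "l",
    "C", "c2", "e1",
    "C", "c3", "e2",
    "D", "c3", "e2",
    "D", "c3", "e3"
  )
  attested <- tidyr::expand_grid(
    language = c("A", "B", "C", "D"),
    concept = c("c1", "c2", "c3")
  )
  cognate_matrix(presence, attested)
}

# Independent oracle: classify every registered class for a pair one at a
# time with classify_pattern() and tally the labels.
oracle_count_pair <- function(cm, lang1, lang2) {
  classes <- dplyr::distinct(cm$presence, concept, class_id)
  att1 <- dplyr::filter(cm$attested, language == lang1)$concept
  att2 <- dplyr::filter(cm$attested, language == lang2)$concept
  labs <- vapply(seq_len(nrow(classes)), function(i) {
    cc <- classes$concept[i]
    cl <- classes$class_id[i]
    holders <- cm$presence$language[
      cm$presence$concept == cc & cm$presence$class_id == cl
    ]
    classify_pattern(
      in1 = lang1 %in% holders,
      in2 = lang2 %in% holders,
      elsewhere = length(setdiff(holders, c(lang1, lang2))) > 0,
      concept_attested = (cc %in% att1) && (cc %in% att2)
    )
  }, character(1))
  tab <- table(factor(labs, levels = c(
    "gain1", "gain2", "loss1", "loss2", "noninformative", "excluded"
  )))
  tibble::tibble(
    gains1 = as.integer(tab[["gain1"]]),
    gains2 = as.integer(tab[["gain2"]]),
    losses1 = as.integer(tab[["loss1"]]),
    losses2 = as.integer(tab[["loss2"]]),
    noninformative = as.integer(tab[["noninformative"]]),
    excluded = as.integer(tab[["excluded"]]),
    total = nrow(classes)
  )
}

# Random small cognate matrix over <= 6 languages for property tests.
random_matrix <- function(n_lang = 4, n_concepts = 4, max_classes = 3) {
  langs <- LETTERS[seq_len(n_lang)]
  concepts <- paste0("k", seq_len(n_concepts))
  rows <- list()
  for (cc in concepts) {
    for (cl in seq_len(sample(max_classes, 1))) {
      holders <- langs[runif(n_lang) < 0.5]
      if (length(holders)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          language = holders, concept = cc, class_id = as.character(cl)
        )
      }
    }
  }
  presence <- dplyr::bind_rows(rows)
  # random attestation, but everything present is attested
  attested <- tidyr::expand_grid(language = langs, concept = concepts) |>
    dplyr::filter(runif(dplyr::n()) < 0.8)
  cognate_matrix(presence, attested)
}

# Contrast table builder for synthetic regression checks.
toy_contrasts <- function(d, x, bl = rep(4, length(d))) {
  tibble::tibble(
    pair = seq_along(d),
    taxon1 = paste0("L", seq_along(d), "a"),
    taxon2 = paste0("L", seq_along(d), "b"),
    c1 = NA_real_, c2 = NA_real_, N1 = NA_real_, N2 = NA_real_,
    branch_length = bl, sqrt_bl = sqrt(bl),
    d = d, x = x, abs_d = abs(d),
    undefined_reason = NA_character_
  )
}
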