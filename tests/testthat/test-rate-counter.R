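test_that("classify_pattern realises the full decision table", {
  grid <- expand.grid(in1 = c(TRUE, FALSE), in2 = c(TRUE, FALSE),
                      elsewhere = c(TRUE, FALSE))
  got <- classify_pattern(grid$in1, grid$in2, grid$elsewhere)
  expected <- with(grid, ifelse(
    in1 & in2, "noninformative",
    ifelse(!in1 & !in2, "excluded",
      ifelse(in1, # present only in member 1
        ifelse(elsewhere, "loss2", "gain1"),
        ifelse(elsewhere, "loss1", "gain2")
      )
    )
  ))
  expect_equal(got, expected)
  # an unattested concept trumps everything
  expect_equal(
    unique(classify_pattern(grid$in1, grid$in2, grid$elsewhere, FALSE)),
    "excluded"
  )
})

test_that("the worked 4-language family tallies exactly as constructed", {
  cm <- toy_family_matrix()
  got <- count_pair(cm, "A", "B")
  expect_equal(got$gains1, 1)
  expect_equal(got$gains2, 0)
  expect_equal(got$losses1, 0)
  expect_equal(got$losses2, 1)
  expect_equal(got$noninformative, 2)
  expect_equal(got$excluded, 3)
  expect_equal(got$total, 7)
  # and the independent per-class oracle agrees
  expect_equal(got, oracle_count_pair(cm, "A", "B"))
})

test_that("identical inventories give only shared (non-informative) classes", {
  presence <- tidyr::expand_grid(
    language = c("A", "B"), concept = c("c1", "c2"), class_id = c("1", "2")
  )
  cm <- cognate_matrix(presence)
  got <- count_pair(cm, "A", "B")
  expect_equal(got$gains1 + got$gains2 + got$losses1 + got$losses2, 0)
  expect_equal(got$noninformative, 4)
})

test_that("swapping the pair members swaps the member-indexed tallies", {
  cm <- toy_family_matrix()
  ab <- count_pair(cm, "A", "B")
  ba <- count_pair(cm, "B", "A")
  expect_equal(ab$gains1, ba$gains2)
  expect_equal(ab$losses1, ba$losses2)
  expect_equal(ab$noninformative, ba$noninformative)
  expect_equal(ab$excluded, ba$excluded)
})

test_that("count_pair matches the brute-force oracle on random matrices", {
  set.seed(20)
  for (i in 1:25) {
    cm <- random_matrix(n_lang = sample(3:6, 1), n_concepts = sample(2:5, 1))
    langs <- cm_languages(cm)
    pair <- sample(langs, 2)
    expect_equal(
      count_pair(cm, pair[1], pair[2]),
      oracle_count_pair(cm, pair[1], pair[2])
    )
  }
})

test_that("only presence outside the pair matters, not which language", {
  set.seed(7)
  for (i in 1:10) {
    cm <- random_matrix(n_lang = 5)
    langs <- cm_languages(cm)
    pair <- langs[1:2]
    base <- count_pair(cm, pair[1], pair[2])
    # permute the names of the non-pair languages
    others <- setdiff(langs, pair)
    relab <- setNames(sample(others), others)
    cm2 <- cm
    idx <- cm2$presence$language %in% others
    cm2$presence$language[idx] <- relab[cm2$presence$language[idx]]
    idx2 <- cm2$attested$language %in% others
    cm2$attested$language[idx2] <- relab[cm2$attested$language[idx2]]
    expect_equal(count_pair(cm2, pair[1], pair[2]), base)
  }
})

test_that("duplicating member 1's inventory turns its gains into sister losses", {
  set.seed(31)
  for (i in 1:10) {
    cm <- random_matrix(n_lang = 4)
    langs <- cm_languages(cm)
    pair <- langs[1:2]
    base <- count_pair(cm, pair[1], pair[2])
    dup <- dplyr::filter(cm$presence, language == pair[1]) |>
      dplyr::mutate(language = "ZDUP")
    att_dup <- tibble::tibble(
      language = "ZDUP",
      concept = unique(cm$attested$concept)
    )
    cm2 <- cognate_matrix(
      dplyr::bind_rows(cm$presence, dup),
      dplyr::bind_rows(cm$attested, att_dup)
    )
    got <- count_pair(cm2, pair[1], pair[2])
    # every gain1 becomes a loss2 (its classes are now attested elsewhere)
    expect_equal(got$gains1, 0)
    expect_equal(got$losses2, base$losses2 + base$gains1)
    expect_equal(got$noninformative, base$noninformative)
    # and the oracle agrees on the modified matrix
    expect_equal(got, oracle_count_pair(cm2, pair[1], pair[2]))
  }
})

test_that("tallies always partition the class universe", {
  set.seed(5)
  for (i in 1:10) {
    cm <- random_matrix()
    langs <- cm_languages(cm)
    pair <- sample(langs, 2)
    got <- count_pair(cm, pair[1], pair[2])
    expect_equal(
      got$gains1 + got$gains2 + got$losses1 + got$losses2 +
        got$noninformative + got$excluded,
      got$total
    )
  }
})

test_that("standardized rates divide by the comparison total", {
  cnt <- tibble::tibble(
    gains1 = 2L, gains2 = 1L, losses1 = 0L, losses2 = 3L,
    noninformative = 2L, excluded = 2L, total = 10L
  )
  std <- standardize_counts(cnt)
  expect_equal(std$gain_rate1, 0.2)
  expect_equal(std$loss_rate2, 0.3)
  expect_true(
    std$gain_rate1 + std$gain_rate2 + std$loss_rate1 + std$loss_rate2 <= 1
  )
  all_shared <- tibble::tibble(
    gains1 = 0L, gains2 = 0L, losses1 = 0L, losses2 = 0L,
    noninformative = 5L, excluded = 0L, total = 5L
  )
  std2 <- standardize_counts(all_shared)
  expect_equal(std2$gain_rate1 + std2$loss_rate1 + std2$loss_rate2, 0)
  expect_error(
    standardize_counts(dplyr::mutate(cnt, total = 0L)),
    class = "sisterates_validation_error"
  )
})

test_that("a pair member missing from the matrix is a named error", {
  cm <- toy_family_matrix()
  expect_error(count_pair(cm, "A", "Q"), regexp = "Q",
               class = "sisterates_validation_error")
})
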