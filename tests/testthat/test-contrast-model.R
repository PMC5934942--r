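test_that("standardized differences follow the closed-form arithmetic", {
  counts <- tibble::tibble(
    pair = rep(1:3, each = 2),
    taxon = paste0("L", 1:6),
    gain = c(1, 1, 30, 10, 5, 5),
    loss = c(4, 4, 30, 10, 2, 8),
    population = c(10, 10, 100, 100, exp(1) * 50, 50),
    branch_length = rep(c(9, 4, 1), each = 2)
  )
  cst <- pair_contrasts(counts, response = "loss")
  expect_equal(cst$d[1], 0) # equal counts
  expect_equal(cst$d[2], (30 - 10) / 20 / 2) # = 0.5
  expect_equal(cst$x[3], 1) # log ratio e over sqrt(1)
})

test_that("the German/Luxembourgish row reproduces its published contrast", {
  ie <- sister_pair_data("indo_european")
  cst <- pair_contrasts(ie, response = "loss")
  glx <- cst[cst$taxon1 == "German_ST", ]
  # (14 - 30) / 22 / sqrt(641.05), frozen from independent arithmetic
  expect_equal(glx$d, -0.0287244254, tolerance = 1e-8)
  # ln(69.8e6 / 266e3) / sqrt(641.05)
  expect_equal(glx$x, 0.2199889660, tolerance = 1e-8)
  # single-pair slope back-calculation lands near the published coefficient
  expect_equal(glx$d / glx$x, -0.13, tolerance = 0.01)
})

test_that("undefined contrasts are flagged, not dropped silently", {
  counts <- tibble::tibble(
    pair = rep(1:3, each = 2),
    taxon = paste0("L", 1:6),
    gain = c(1, 2, 0, 0, 3, 4),
    loss = c(1, 2, 0, 0, 3, 4),
    population = 100,
    branch_length = rep(c(0, 5, 5), each = 2)
  )
  cst <- pair_contrasts(counts, "gain")
  expect_equal(cst$undefined_reason, c("zero_branch", "zero_counts", NA))
  expect_true(is.na(cst$d[1]) && is.na(cst$d[2]))
})

test_that("the Welch-Waxman filter leaves flat data alone and logs removals", {
  set.seed(1)
  bl <- seq(10, 100, length.out = 12)
  flat <- toy_contrasts(d = rep(c(0.2, -0.2), 6), x = rnorm(12), bl = bl)
  res <- ww_filter(flat)
  expect_equal(nrow(res$retained), 12)
  expect_equal(sum(res$removed$reason == "ww_iteration"), 0)

  # a steep reliability artefact at small branch lengths is trimmed
  noisy <- toy_contrasts(
    d = c(8, -6, 5, rep(c(0.1, -0.1), 6)),
    x = rnorm(15),
    bl = c(0.01, 0.02, 0.05, seq(10, 100, length.out = 12))
  )
  res2 <- ww_filter(noisy)
  expect_lt(nrow(res2$retained), 15)
  expect_equal(res2$removed$reason, rep("ww_iteration", nrow(res2$removed)))
  expect_equal(res2$removed$step, seq_len(nrow(res2$removed)))
  # deterministic: same input, same log
  res3 <- ww_filter(noisy)
  expect_identical(res2$removed, res3$removed)
  # retained set shrinks monotonically along the path
  expect_true(all(diff(res2$path$n) <= 0))
})

test_that("the filter removes the shallow Sorbian pair from the IE losses", {
  ie <- sister_pair_data("indo_european")
  res <- ww_filter(pair_contrasts(ie, "loss"))
  expect_equal(nrow(res$retained), 13)
  it <- dplyr::filter(res$removed, reason == "ww_iteration")
  expect_equal(it$taxon1, "Lusatian_L")
  expect_equal(it$taxon2, "Lusatian_U")
})

test_that("an exact linear relation is recovered perfectly", {
  set.seed(3)
  x <- rnorm(10)
  cst <- toy_contrasts(d = 2 * x, x = x)
  fit <- suppressWarnings(fit_contrast_regression(cst)) # perfect fit warns
  expect_equal(fit$estimate, 2, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_error(
    fit_contrast_regression(toy_contrasts(d = rnorm(5), x = rep(1, 5))),
    class = "sisterates_validation_error"
  )
  expect_error(
    fit_contrast_regression(toy_contrasts(d = 1:2, x = 1:2)),
    class = "sisterates_validation_error"
  )
})

test_that("uniformly flipping pair orientation leaves the slope unchanged", {
  ie <- sister_pair_data("indo_european")
  flipped <- ie |>
    dplyr::group_by(pair) |>
    dplyr::slice(c(2, 1)) |>
    dplyr::ungroup()
  f1 <- fit_contrast_regression(pair_contrasts(ie, "loss"))
  f2 <- fit_contrast_regression(pair_contrasts(flipped, "loss"))
  # d and x both change sign pair-wise, so with the intercept refitted the
  # slope is identical
  expect_equal(f2$estimate, f1$estimate, tolerance = 1e-10)
  expect_equal(f2$statistic, f1$statistic, tolerance = 1e-10)

  c1 <- pair_contrasts(ie, "loss")
  c2 <- pair_contrasts(flipped, "loss")
  expect_equal(c2$d, -c1$d)
  expect_equal(c2$x, -c1$x)
})

test_that("population orientation is available and deterministic", {
  ie <- sister_pair_data("indo_european")
  cst <- pair_contrasts(ie, "loss", orientation = "population")
  expect_true(all(cst$N1 >= cst$N2))
  expect_true(all(cst$x >= 0))
})

test_that("simulated independence yields a null slope", {
  set.seed(42)
  x <- rnorm(60)
  cst <- toy_contrasts(d = rnorm(60), x = x)
  fit <- fit_contrast_regression(cst)
  expect_lt(abs(fit$estimate), 3 * fit$se)
})
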