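test_that("a clean wordlist is ingested form for form", {
  cm <- read_wordlist(write_toy_wordlist(toy_wordlist_rows()))
  expect_s3_class(cm, "cognate_matrix")
  expect_equal(nrow(cm$presence), 3)
  expect_setequal(cm_languages(cm), c("A", "B"))
  expect_setequal(cm_concepts(cm), c("hand", "water"))
})

test_that("doubtful, excluded and loan forms never reach the matrix", {
  rows <- tibble::tribble(
    ~language, ~concept, ~cognate_class, ~loan, ~status,
    "A", "hand", "1", "false", "ok",
    "A", "hand", "2", "false", "doubtful",
    "A", "hand", "3", "false", "exclude",
    "A", "water", "1", "true", "ok",
    "B", "hand", "1", "false", "OK" # case-insensitive status
  )
  cm <- read_wordlist(write_toy_wordlist(rows))
  expect_equal(sort(cm$presence$class_id[cm$presence$language == "A"]), "1")
  # the loan was A's only entry for "water": concept not attested for A
  expect_false(any(cm$attested$language == "A" & cm$attested$concept == "water"))
  expect_true(any(cm$presence$language == "B"))
})

test_that("apply_exclusions keeps exactly ok non-loans and is idempotent", {
  empty <- tibble::tibble(status = character(), loan = logical())
  expect_equal(nrow(apply_exclusions(empty)), 0)

  forms <- tibble::tibble(
    status = c("ok", "doubtful", "exclude", "ok"),
    loan = c(FALSE, FALSE, FALSE, TRUE)
  )
  out <- apply_exclusions(forms)
  expect_equal(nrow(out), 1)
  expect_equal(out$status, "ok")
  expect_identical(apply_exclusions(out), out)

  expect_error(
    apply_exclusions(tibble::tibble(status = "dubious", loan = FALSE)),
    class = "sisterates_validation_error"
  )
})

test_that("format and validation errors are loud and name the offender", {
  no_status <- tibble::tibble(language = "A", concept = "hand",
                              cognate_class = "1", loan = "false")
  expect_error(read_wordlist(write_toy_wordlist(no_status)),
    regexp = "status", class = "sisterates_format_error")

  conflict <- tibble::tribble(
    ~language, ~concept, ~cognate_class, ~loan, ~status,
    "A", "hand", "1", "false", "ok",
    "A", "hand", "1", "false", "exclude"
  )
  expect_error(read_wordlist(write_toy_wordlist(conflict)),
    regexp = "A, hand, 1", class = "sisterates_validation_error")
})

test_that("write_wordlist round-trips the surviving forms and attestation", {
  rows <- tibble::tribble(
    ~language, ~concept, ~cognate_class, ~loan, ~status,
    "A", "hand", "1", "false", "ok",
    "A", "hand", "2", "false", "ok",
    "B", "hand", "1", "false", "ok",
    "B", "water", "", "false", "ok" # attested-but-empty marker
  )
  cm <- read_wordlist(write_toy_wordlist(rows))
  out <- tempfile(fileext = ".csv")
  write_wordlist(cm, out)
  cm2 <- read_wordlist(out)
  expect_equal(
    dplyr::arrange(cm$presence, language, concept, class_id),
    dplyr::arrange(cm2$presence, language, concept, class_id)
  )
  expect_equal(
    dplyr::arrange(cm$attested, language, concept),
    dplyr::arrange(cm2$attested, language, concept)
  )
  expect_true(any(cm2$attested$language == "B" & cm2$attested$concept == "water"))
})

nexus_text <- function(matrix_lines, labels) {
  paste0(
    "#NEXUS\nBEGIN DATA;\nDIMENSIONS NTAX=", length(matrix_lines),
    " NCHAR=", nchar(sub(".*\\s", "", matrix_lines[1])), ";\n",
    "FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=?;\n",
    "CHARSTATELABELS\n  ",
    paste(sprintf("%d %s", seq_along(labels), labels), collapse = ", "),
    ";\nMATRIX\n",
    paste(matrix_lines, collapse = "\n"),
    "\n;\nEND;\n"
  )
}

test_that("NEXUS matrices are read with presence, absence and missing data", {
  f <- tempfile(fileext = ".nex")
  writeLines(nexus_text(
    c("A 111", "B 111"),
    c("hand_1", "hand_2", "water_1")
  ), f)
  cm <- read_nexus_matrix(f)
  expect_equal(nrow(cm$presence), 6)

  f2 <- tempfile(fileext = ".nex")
  writeLines(nexus_text(
    c("A 11?", "B 0?1", "L ??1"),
    c("hand_1", "hand_2", "water_1")
  ), f2)
  cm2 <- read_nexus_matrix(f2)
  # L is ? for every "hand" character: concept missing for L
  expect_false(any(cm2$attested$language == "L" & cm2$attested$concept == "hand"))
  expect_true(any(cm2$attested$language == "L" & cm2$attested$concept == "water"))
  # B observed a 0 for hand_1: attested even though nothing is present
  expect_true(any(cm2$attested$language == "B" & cm2$attested$concept == "hand"))

  f3 <- tempfile(fileext = ".nex")
  writeLines(nexus_text(c("A 121", "B 111"), c("hand_1", "hand_2", "water_1")), f3)
  expect_error(read_nexus_matrix(f3), class = "sisterates_format_error")
})

test_that("equivalent wordlist and NEXUS encodings yield the same matrix", {
  f <- tempfile(fileext = ".nex")
  writeLines(nexus_text(
    c("A 101", "B 011"),
    c("hand_1", "hand_2", "water_1")
  ), f)
  from_nexus <- read_nexus_matrix(f)

  rows <- tibble::tribble(
    ~language, ~concept, ~cognate_class, ~loan, ~status,
    "A", "hand", "1", "false", "ok",
    "A", "water", "1", "false", "ok",
    "B", "hand", "2", "false", "ok",
    "B", "water", "1", "false", "ok"
  )
  from_wordlist <- read_wordlist(write_toy_wordlist(rows))

  srt <- function(x) dplyr::arrange(x, language, concept, class_id)
  expect_equal(srt(from_nexus$presence), srt(from_wordlist$presence))
  expect_equal(
    dplyr::arrange(from_nexus$attested, language, concept),
    dplyr::arrange(from_wordlist$attested, language, concept)
  )
  expect_identical(
    count_pair(from_nexus, "A", "B"),
    count_pair(from_wordlist, "A", "B")
  )
})
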