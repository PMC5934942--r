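#' Read a binary cognate matrix in NEXUS format
#'
#' Reads a presence/absence character matrix (symbols `0`/`1`, missing `?`)
#' whose character labels encode `concept_class`, as distributed for
#' single-variant-per-concept lexical datasets, and assembles a
#' [cognate_matrix()]. A `1` records presence of the class, a `0` absence; a
#' language whose characters are all `?` for a concept has that concept
#' marked as missing (not attested) rather than empty.
#'
#' Character labels are taken from a `CHARSTATELABELS` or `CHARLABELS`
#' statement and split at the last underscore into (concept, class).
#'
#' @param path Path to a NEXUS file with a DATA or CHARACTERS block.
#' @return A [cognate_matrix()].
#' @export
read_nexus_matrix <- function(path) {
  mat <- ape::read.nexus.data(path)
  labels <- .nexus_char_labels(path, n_char = length(mat[[1]]))
  concept <- sub("_[^_]*$", "", labels)
  class_id <- sub("^.*_", "", labels)
  if (any(concept == "" | class_id == "" | concept == labels)) {
    abort("character labels must have the form concept_class",
      class = "sisterates_format_error"
    )
  }

  rows <- purrr::imap(mat, function(states, lang) {
    states <- toupper(unlist(states))
    bad <- setdiff(unique(states), c("0", "1", "?", "N", "-"))
    if (length(bad)) {
      abort(paste0(
        "non-binary symbol(s) in matrix for ", lang, ": ",
        paste(bad, collapse = ", ")
      ), class = "sisterates_format_error")
    }
    miss <- states %in% c("?", "N", "-")
    tibble(
      language = lang, concept = concept, class_id = class_id,
      present = states == "1", missing = miss
    )
  }) %>% bind_rows()

  presence <- rows %>%
    filter(.data$present) %>%
    select("language", "concept", "class_id")
  attested <- rows %>%
    group_by(.data$language, .data$concept) %>%
    summarise(any_obs = any(!.data$missing), .groups = "drop") %>%
    filter(.data$any_obs) %>%
    select("language", "concept")
  cognate_matrix(presence, attested)
}

# Pull character labels out of the raw NEXUS text; ape discards them.
.nexus_char_labels <- function(path, n_char) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  m <- regmatches(
    txt,
    regexpr("(?i)CHAR(STATE)?LABELS[^;]*;", txt, perl = TRUE)
  )
  if (!length(m)) {
    abort("NEXUS file has no CHARSTATELABELS/CHARLABELS statement",
      class = "sisterates_format_error"
    )
  }
  body <- sub("(?i)^CHAR(STATE)?LABELS", "", m, perl = TRUE)
  body <- gsub(";", "", body)
  body <- gsub(",", " ", body)
  toks <- strsplit(trimws(body), "\\s+")[[1]]
  # CHARSTATELABELS interleaves indices with names: "1 hand_1 2 hand_2 ..."
  toks <- toks[!grepl("^[0-9]+$", toks)]
  toks <- gsub("^'|'$", "", toks)
  if (length(toks) != n_char) {
    abort(paste0(
      "found ", length(toks), " character labels for ", n_char, " characters"
    ), class = "sisterates_format_error")
  }
  toks
}
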