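#' Cognate presence/absence matrix
#'
#' A `cognate_matrix` holds, for one language family, which cognate classes
#' are present in which language under which semantic category (concept),
#' together with an attestation table that distinguishes a concept that is
#' truly empty for a language from one that is simply undocumented. Class
#' identifiers are scoped per concept: the label `"1"` under `"hand"` and
#' under `"water"` are unrelated classes.
#'
#' @param presence A data frame with columns `language`, `concept`,
#'   `class_id`; one row per cognate class present in a language.
#' @param attested Optional data frame with columns `language`, `concept`
#'   listing attested (documented) language/concept combinations. Defaults to
#'   the combinations occurring in `presence`. Combinations appearing in
#'   `presence` are always treated as attested.
#'
#' @return An object of class `cognate_matrix`: a list with tibbles
#'   `presence` and `attested`.
#' @export
#' @examples
#' cm <- cognate_matrix(
#'   tibble::tibble(
#'     language = c("A", "A", "B"),
#'     concept = c("hand", "water", "hand"),
#'     class_id = c("1", "1", "1")
#'   )
#' )
#' cm
cognate_matrix <- function(presence, attested = NULL) {
  presence <- as_tibble(presence)
  req <- c("language", "concept", "class_id")
  if (!all(req %in% names(presence))) {
    abort(paste0(
      "`presence` must have columns ",
      paste(req, collapse = ", ")
    ), class = "sisterates_format_error")
  }
  presence <- presence %>%
    mutate(across(all_of(req), as.character)) %>%
    distinct(.data$language, .data$concept, .data$class_id)
  if (any(is.na(presence$class_id) | presence$class_id == "")) {
    abort("cognate class identifiers must be non-empty",
      class = "sisterates_validation_error"
    )
  }
  if (is.null(attested)) {
    attested <- distinct(presence, .data$language, .data$concept)
  } else {
    attested <- as_tibble(attested) %>%
      mutate(language = as.character(.data$language),
             concept = as.character(.data$concept)) %>%
      distinct(.data$language, .data$concept) %>%
      bind_rows(distinct(presence, .data$language, .data$concept)) %>%
      distinct()
  }
  structure(
    list(presence = presence, attested = attested),
    class = "cognate_matrix"
  )
}

#' @export
print.cognate_matrix <- function(x, ...) {
  cat(
    "<cognate_matrix> ",
    dplyr::n_distinct(x$attested$language), " languages, ",
    dplyr::n_distinct(x$attested$concept), " concepts, ",
    nrow(distinct(x$presence, .data$concept, .data$class_id)),
    " cognate classes\n",
    sep = ""
  )
  invisible(x)
}

#' Languages and concepts of a cognate matrix
#'
#' @param x A [cognate_matrix()].
#' @return A character vector.
#' @export
cm_languages <- function(x) sort(unique(x$attested$language))

#' @rdname cm_languages
#' @export
cm_concepts <- function(x) sort(unique(x$attested$concept))

# status vocabulary accepted in wordlists, normalised case-insensitively
.status_levels <- c("ok", "doubtful", "exclude")

#' Drop doubtful, excluded and borrowed forms
#'
#' Word forms flagged as doubtful or excluded by the source database, and any
#' identified loan words, carry no reliable signal of vertically inherited
#' change and are removed before counting. Only forms with status `"ok"` and
#' `loan = FALSE` survive. The operation is idempotent.
#'
#' @param forms A data frame with at least columns `status` (one of
#'   `"ok"`, `"doubtful"`, `"exclude"`, matched case-insensitively) and
#'   `loan` (logical).
#' @return The surviving rows, with `status` normalised to lower case.
#' @export
#' @examples
#' forms <- tibble::tibble(
#'   language = "A", concept = "hand", class_id = as.character(1:3),
#'   loan = c(FALSE, FALSE, TRUE), status = c("ok", "doubtful", "ok")
#' )
#' apply_exclusions(forms) # only the first row survives
apply_exclusions <- function(forms) {
  forms <- as_tibble(forms)
  if (!all(c("status", "loan") %in% names(forms))) {
    abort("`forms` must have `status` and `loan` columns",
      class = "sisterates_format_error"
    )
  }
  status <- tolower(trimws(as.character(forms$status)))
  bad <- setdiff(unique(status), .status_levels)
  if (length(bad)) {
    abort(
      paste0(
        "unknown status value(s): ", paste(bad, collapse = ", "),
        " (expected ok/doubtful/exclude)"
      ),
      class = "sisterates_validation_error"
    )
  }
  loan <- .parse_logical(forms$loan, "loan")
  forms$status <- status
  forms$loan <- loan
  filter(forms, .data$status == "ok", !.data$loan)
}

.parse_logical <- function(x, what) {
  if (is.logical(x)) {
    out <- x
  } else {
    lx <- tolower(trimws(as.character(x)))
    out <- rep(NA, length(lx))
    out[lx %in% c("true", "t", "1", "yes")] <- TRUE
    out[lx %in% c("false", "f", "0", "no")] <- FALSE
  }
  if (anyNA(out)) {
    abort(paste0("column `", what, "` contains values not interpretable as TRUE/FALSE"),
      class = "sisterates_validation_error"
    )
  }
  out
}

#' Read a cognate-coded wordlist
#'
#' Reads a long-format (CLDF-style) wordlist with one row per recorded form,
#' validates it, applies [apply_exclusions()], and assembles a
#' [cognate_matrix()]. A row with an empty `cognate_class` and status `"ok"`
#' is an explicit "attested but empty" marker: the concept counts as
#' documented for that language even if no form survives. A language/concept
#' combination with no rows at all is treated as missing data, not as a true
#' absence.
#'
#' @param path Path to a delimited text file with header columns
#'   `language_id` (or `language`), `concept`, `cognate_class`, `loan`,
#'   `status`, and optionally `form`.
#' @param delim Field delimiter (default comma).
#' @return A [cognate_matrix()].
#' @export
read_wordlist <- function(path, delim = ",") {
  raw <- readr::read_delim(path,
    delim = delim, show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  names(raw) <- tolower(names(raw))
  if ("language_id" %in% names(raw) && !"language" %in% names(raw)) {
    raw <- rename(raw, language = "language_id")
  }
  req <- c("language", "concept", "cognate_class", "loan", "status")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols)) {
    abort(
      paste0("wordlist is missing required column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "sisterates_format_error"
    )
  }
  raw$status <- tolower(trimws(raw$status))
  bad <- setdiff(unique(raw$status), .status_levels)
  if (length(bad)) {
    abort(paste0("unknown status value(s): ", paste(bad, collapse = ", ")),
      class = "sisterates_validation_error"
    )
  }
  raw$loan <- .parse_logical(raw$loan, "loan")
  raw$cognate_class <- ifelse(is.na(raw$cognate_class), "", raw$cognate_class)

  markers <- filter(raw, .data$cognate_class == "", .data$status == "ok")
  forms <- filter(raw, .data$cognate_class != "")

  # the same (language, concept, class) triple must not carry conflicting flags
  conflicts <- forms %>%
    distinct(.data$language, .data$concept, .data$cognate_class,
             .data$loan, .data$status) %>%
    count(.data$language, .data$concept, .data$cognate_class) %>%
    filter(.data$n > 1)
  if (nrow(conflicts)) {
    c1 <- conflicts[1, ]
    abort(
      paste0(
        "conflicting loan/status flags for (",
        c1$language, ", ", c1$concept, ", ", c1$cognate_class, ")",
        if (nrow(conflicts) > 1) paste0(" and ", nrow(conflicts) - 1, " more")
      ),
      class = "sisterates_validation_error"
    )
  }

  kept <- apply_exclusions(forms)
  presence <- kept %>%
    select(language = "language", concept = "concept", class_id = "cognate_class")
  attested <- bind_rows(
    distinct(kept, .data$language, .data$concept),
    distinct(markers, .data$language, .data$concept)
  )
  cognate_matrix(presence, attested)
}

#' Write a cognate matrix back to a wordlist file
#'
#' Emits one row per surviving form (all `status = "ok"`, `loan = FALSE`) and
#' an empty-class marker row for every attested language/concept combination
#' without any surviving class, so that [read_wordlist()] round-trips the
#' matrix.
#'
#' @param x A [cognate_matrix()].
#' @param path Output file path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_wordlist <- function(x, path, delim = ",") {
  stopifnot(inherits(x, "cognate_matrix"))
  forms <- x$presence %>%
    mutate(cognate_class = .data$class_id, loan = FALSE, status = "ok") %>%
    select("language", "concept", "cognate_class", "loan", "status")
  empties <- anti_join(x$attested, x$presence, by = c("language", "concept")) %>%
    mutate(cognate_class = "", loan = FALSE, status = "ok")
  out <- bind_rows(forms, empties) %>%
    arrange(.data$language, .data$concept, .data$cognate_class)
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}
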