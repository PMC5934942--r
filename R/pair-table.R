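# Internal: reshape a long per-pair table (two rows per pair, one per member)
# into one row per pair with member-1/member-2 columns for the chosen
# response. Member order follows the input rows ("input"), which for the
# packaged tables is the published row order; "population" reorients each
# pair larger-population-first (ties broken by taxon label).
.pairs_wide <- function(data, response = c("loss", "gain"),
                        orientation = c("input", "population")) {
  response <- arg_match(response)
  orientation <- arg_match(orientation)
  data <- as_tibble(data)
  req <- c("pair", "taxon", "gain", "loss")
  if (!all(req %in% names(data))) {
    abort(paste0("pair table needs columns ", paste(req, collapse = ", ")),
      class = "sisterates_format_error"
    )
  }
  counts2 <- count(data, .data$pair)
  if (any(counts2$n != 2)) {
    abort("every pair must have exactly two rows (one per member)",
      class = "sisterates_format_error"
    )
  }
  data <- group_by(data, .data$pair)
  if (orientation == "population") {
    if (!"population" %in% names(data)) {
      abort("orientation = \"population\" needs a population column",
        class = "sisterates_format_error"
      )
    }
    data <- arrange(data, dplyr::desc(.data$population), .data$taxon,
                    .by_group = TRUE)
  }
  wide <- summarise(data,
    taxon1 = first(.data$taxon),
    taxon2 = dplyr::nth(.data$taxon, 2),
    x1 = first(.data[[response]]),
    x2 = dplyr::nth(.data[[response]], 2),
    N1 = if ("population" %in% names(data)) first(.data$population) else NA_real_,
    N2 = if ("population" %in% names(data)) dplyr::nth(.data$population, 2) else NA_real_,
    branch_length = if ("branch_length" %in% names(data)) {
      first(.data$branch_length)
    } else {
      NA_real_
    },
    .groups = "drop"
  )
  wide
}
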