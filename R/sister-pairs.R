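#' Extract well-supported sister pairs (cherries) from a phylogeny
#'
#' A sister pair is a pair of tips joined directly by their most recent
#' common ancestor ("cherry"). Differences between the two members arose
#' after their split and independently of every other pair, so cherries are
#' phylogenetically independent data points. Pairs whose ancestral node has
#' posterior support below `min_support` are rejected as insufficiently
#' attested.
#'
#' Node support is read from the tree's internal node labels. Unlabelled
#' nodes are treated as fully supported (published summary topologies fix
#' them); values greater than 1 are interpreted as percentages and divided
#' by 100.
#'
#' @param tree An [ape::phylo] object, or a path to / string of Newick with
#'   node-label supports.
#' @param min_support Minimum posterior probability, as a fraction
#'   (default 0.8).
#' @return A tibble with one row per cherry: `lang1`, `lang2`
#'   (alphabetical), `support`, `branch_length` (see [pair_branch_length()]).
#' @export
#' @examples
#' tr <- ape::read.tree(text = "(((A:1,B:1)0.9:1,C:2)1.0:1,(D:1,E:1)0.99:2);")
#' extract_cherries(tr)
extract_cherries <- function(tree, min_support = 0.8) {
  tree <- .as_phylo(tree)
  if (!ape::is.rooted(tree)) {
    abort("tree must be rooted so that every cherry has an unambiguous parent",
      class = "sisterates_format_error"
    )
  }
  ntip <- length(tree$tip.label)
  supports <- .node_supports(tree)
  # internal nodes whose children are exactly two tips
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  cherry_nodes <- names(kids)[vapply(
    kids, function(ch) length(ch) == 2 && all(ch <= ntip), logical(1)
  )]
  if (!length(cherry_nodes)) {
    return(tibble(
      lang1 = character(), lang2 = character(),
      support = double(), branch_length = double()
    ))
  }
  out <- purrr::map(cherry_nodes, function(nd) {
    labs <- sort(tree$tip.label[kids[[nd]]])
    tibble(
      lang1 = labs[1],
      lang2 = labs[2],
      support = supports[as.integer(nd) - ntip]
    )
  }) %>% bind_rows()
  out$branch_length <- if (is.null(tree$edge.length)) NA_real_ else vapply(
    seq_len(nrow(out)),
    function(i) pair_branch_length(tree, c(out$lang1[i], out$lang2[i])),
    double(1)
  )
  out <- filter(out, .data$support >= min_support)
  arrange(out, .data$lang1)
}

.as_phylo <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && length(tree) == 1) {
    if (file.exists(tree)) return(ape::read.tree(tree))
    return(ape::read.tree(text = tree))
  }
  abort("`tree` must be a phylo object, a Newick string or a file path",
    class = "sisterates_format_error"
  )
}

.node_supports <- function(tree) {
  nnode <- tree$Nnode
  lab <- tree$node.label
  if (is.null(lab)) lab <- rep("", nnode)
  sup <- suppressWarnings(as.numeric(lab))
  sup[is.na(sup) | lab == ""] <- NA_real_
  sup[!is.na(sup) & sup > 1] <- sup[!is.na(sup) & sup > 1] / 100
  sup[is.na(sup)] <- 1
  if (any(sup < 0 | sup > 1)) {
    abort("node supports must lie in [0, 1] (or [0, 100] as percentages)",
      class = "sisterates_validation_error"
    )
  }
  sup
}

#' Divergence scale of a sister pair
#'
#' Returns the height of the pair's most recent common ancestor above the
#' tips: for an ultrametric tree the shared node height, otherwise the mean
#' of the two tip-to-ancestor path lengths (with a warning).
#'
#' @param tree An [ape::phylo] object (or Newick string/path) with edge
#'   lengths.
#' @param pair Character vector of the two tip labels.
#' @return A single non-negative number in the units of the tree.
#' @export
pair_branch_length <- function(tree, pair) {
  tree <- .as_phylo(tree)
  if (is.null(tree$edge.length)) {
    abort("tree has no edge lengths", class = "sisterates_format_error")
  }
  if (any(tree$edge.length < 0)) {
    abort("tree has negative edge lengths", class = "sisterates_validation_error")
  }
  idx <- match(pair, tree$tip.label)
  if (anyNA(idx)) {
    abort(paste0("tip(s) not in tree: ", paste(pair[is.na(idx)], collapse = ", ")),
      class = "sisterates_validation_error"
    )
  }
  parents <- tree$edge[match(idx, tree$edge[, 2]), 1]
  if (parents[1] != parents[2]) {
    abort(paste0(pair[1], " and ", pair[2], " are not a cherry"),
      class = "sisterates_validation_error"
    )
  }
  lens <- tree$edge.length[match(idx, tree$edge[, 2])]
  if (abs(lens[1] - lens[2]) > 1e-8 * max(1, abs(lens[1]), abs(lens[2]))) {
    warn(paste0(
      "tip paths for ", pair[1], "/", pair[2],
      " differ; using their mean as the pair branch length"
    ))
  }
  mean(lens)
}

#' Join metadata and drop unusable sister pairs
#'
#' Attaches speaker population sizes and drops pairs that cannot enter the
#' rate analyses: pairs with a creole or extinct member (their lexica and
#' population sizes are unreliable), pairs with missing metadata or
#' population size, and pairs contradicted by a reference taxonomy. Dropped
#' pairs are logged with a reason code, retrievable with [dropped_pairs()].
#'
#' @param pairs A tibble as produced by [extract_cherries()].
#' @param meta A data frame with columns `language`, `population`, `creole`,
#'   `extinct`.
#' @param taxonomy Optional data frame of accepted pairs (columns `lang1`,
#'   `lang2`, unordered); pairs absent from it are dropped as taxonomy
#'   conflicts.
#' @return The retained pairs with `N1`, `N2` columns added; the removal log
#'   is stored in the `"dropped"` attribute.
#' @export
filter_pairs <- function(pairs, meta, taxonomy = NULL) {
  pairs <- as_tibble(pairs)
  meta <- as_tibble(meta) %>%
    mutate(language = as.character(.data$language))
  if (!all(c("language", "population", "creole", "extinct") %in% names(meta))) {
    abort("`meta` needs columns language, population, creole, extinct",
      class = "sisterates_format_error"
    )
  }
  meta$creole <- .parse_logical(meta$creole, "creole")
  meta$extinct <- .parse_logical(meta$extinct, "extinct")

  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  m1 <- meta[match(pairs$lang1, meta$language), ]
  m2 <- meta[match(pairs$lang2, meta$language), ]
  reason <- rep(NA_character_, nrow(pairs))
  miss <- is.na(m1$population) & !is.na(match(pairs$lang1, meta$language)) |
    is.na(m2$population) & !is.na(match(pairs$lang2, meta$language))
  reason[miss] <- "missing_population"
  reason[is.na(match(pairs$lang1, meta$language)) |
    is.na(match(pairs$lang2, meta$language))] <- "missing_metadata"
  reason[is.na(reason) & (m1$extinct | m2$extinct)] <- "extinct"
  reason[is.na(reason) & (m1$creole | m2$creole)] <- "creole"
  if (!is.null(taxonomy)) {
    taxonomy <- as_tibble(taxonomy)
    tkeys <- key(as.character(taxonomy$lang1), as.character(taxonomy$lang2))
    conflict <- !(key(pairs$lang1, pairs$lang2) %in% tkeys)
    reason[is.na(reason) & conflict] <- "taxonomy_conflict"
  }
  if (any(is.na(reason) & (m1$population <= 0 | m2$population <= 0))) {
    abort("populations must be positive", class = "sisterates_validation_error")
  }

  kept <- pairs[is.na(reason), , drop = FALSE]
  kept$N1 <- m1$population[is.na(reason)]
  kept$N2 <- m2$population[is.na(reason)]
  dropped <- pairs[!is.na(reason), c("lang1", "lang2"), drop = FALSE]
  dropped$reason <- reason[!is.na(reason)]
  attr(kept, "dropped") <- as_tibble(dropped)
  kept
}

#' Removal log of [filter_pairs()]
#'
#' @param pairs The result of [filter_pairs()].
#' @return A tibble with columns `lang1`, `lang2`, `reason`.
#' @export
dropped_pairs <- function(pairs) {
  d <- attr(pairs, "dropped")
  if (is.null(d)) tibble(lang1 = character(), lang2 = character(),
                         reason = character()) else d
}
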