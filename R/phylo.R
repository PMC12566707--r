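# Phylogeny I/O, patristic distances, Faith's PD.

#' Read a rooted phylogeny with branch lengths
#'
#' Thin validating wrapper around [ape::read.tree()]: the tree must
#' parse, every tip label must be unique, and every edge must carry a
#' finite non-negative branch length (missing lengths are an error, not
#' silently zero). Polytomies are allowed.
#'
#' @param path Path to a newick file (or a file containing one tree).
#' @return An [ape::phylo] object.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) {
    stop_format(sprintf("tree file '%s' does not exist", path))
  }
  tree <- tryCatch(
    ape::read.tree(path),
    error = function(e) stop_format(sprintf("cannot parse newick in '%s': %s",
                                            path, conditionMessage(e)))
  )
  if (is.null(tree)) {
    stop_format(sprintf("cannot parse newick in '%s'", path))
  }
  validate_tree(tree)
}

#' Validate a phylo object for use in phyloRI
#'
#' @param tree An [ape::phylo] object.
#' @return The tree, invisibly validated.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) {
    stop_validation("`tree` must be an ape 'phylo' object")
  }
  if (anyDuplicated(tree$tip.label)) {
    dup <- tree$tip.label[duplicated(tree$tip.label)][1]
    stop_validation(sprintf("duplicate tip label '%s' in tree", dup))
  }
  if (is.null(tree$edge.length)) {
    stop_validation("tree has no branch lengths")
  }
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0)) {
    stop_validation("every branch length must be finite and >= 0")
  }
  tree
}

check_tips <- function(tree, labels, what = "species") {
  missing <- setdiff(labels, tree$tip.label)
  if (length(missing) > 0) {
    stop_lookup(sprintf(
      "%s not found in tree: %s", what, paste(missing, collapse = ", ")
    ))
  }
  invisible(labels)
}

#' Patristic distance matrix
#'
#' Tip-to-tip distances as sums of branch lengths along the connecting
#' path, in the tree's branch-length units.
#'
#' @param tree A validated [ape::phylo] tree.
#' @param labels Optional subset (and ordering) of tip labels; defaults
#'   to all tips.
#' @return A symmetric numeric matrix with `labels` as dimnames.
#' @export
patristic_distances <- function(tree, labels = NULL) {
  validate_tree(tree)
  labels <- labels %||% tree$tip.label
  check_tips(tree, labels)
  d <- ape::cophenetic.phylo(tree)
  d[labels, labels, drop = FALSE]
}

#' Faith's phylogenetic diversity
#'
#' Total branch length of the minimal subtree spanning a set of tips.
#' By default the subtree is connected to the root
#' (`include_root = TRUE`), so a single-species community has PD equal
#' to its root-to-tip distance rather than zero; with
#' `include_root = FALSE` the subtree is rooted at the community's most
#' recent common ancestor.
#'
#' @param tree A validated [ape::phylo] tree.
#' @param community Character vector of tip labels, non-empty.
#' @param include_root Include the path from the community's MRCA up to
#'   the tree root (default `TRUE`).
#' @return A single non-negative number in branch-length units.
#' @export
faith_pd <- function(tree, community, include_root = TRUE) {
  validate_tree(tree)
  community <- unique(as.character(community))
  if (length(community) == 0) {
    stop_validation("`community` must contain at least one species")
  }
  check_tips(tree, community)

  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  parent_of <- integer(max(tree$edge))
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  edge_index <- integer(max(tree$edge))
  edge_index[tree$edge[, 2]] <- seq_len(nrow(tree$edge))

  used <- logical(nrow(tree$edge))
  for (tip in match(community, tree$tip.label)) {
    node <- tip
    while (node != root) {
      e <- edge_index[node]
      if (used[e]) break   # path above already collected
      used[e] <- TRUE
      node <- parent_of[node]
    }
  }
  pd <- sum(tree$edge.length[used])
  if (!include_root && length(community) >= 1) {
    mrca <- if (length(community) == 1) {
      match(community, tree$tip.label)
    } else {
      ape::getMRCA(tree, community)
    }
    node <- mrca
    while (node != root) {
      pd <- pd - tree$edge.length[edge_index[node]]
      node <- parent_of[node]
    }
  }
  pd
}

#' Per-plot, per-layer Faith's PD
#'
#' @inheritParams importance_values
#' @param tree A phylogeny whose tips cover the surveyed species.
#' @param include_root Passed to [faith_pd()].
#' @param prune_missing Drop species absent from the tree (with a
#'   warning) instead of erroring.
#' @return A tibble with one row per (plot, layer) and a `pd` column.
#' @export
phylo_diversity <- function(survey, tree, layers = survey_layers(),
                            include_root = TRUE, prune_missing = FALSE) {
  survey <- validate_survey(survey)
  validate_tree(tree)
  recs <- survey |> filter(.data$layer %in% layers)
  missing <- setdiff(unique(recs$species), tree$tip.label)
  if (length(missing) > 0) {
    if (!prune_missing) {
      stop_lookup(sprintf("species not found in tree: %s",
                          paste(missing, collapse = ", ")))
    }
    warn(sprintf("pruning %d species absent from tree: %s",
                 length(missing), paste(missing, collapse = ", ")))
    recs <- recs |> filter(!.data$species %in% missing)
  }
  recs |>
    group_by(.data$plot_id, .data$stage, .data$layer) |>
    summarise(pd = faith_pd(tree, .data$species, include_root = include_root),
              richness = dplyr::n(), .groups = "drop")
}
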