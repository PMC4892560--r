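#' Read a rooted phylogeny from Newick text or a file
#'
#' Parses Newick (quoted labels, internal-node labels and bracketed comments
#' are tolerated; polytomies are preserved) into an [ape::phylo] object and
#' validates the invariants the rest of the package relies on: unique tip
#' labels and non-negative branch lengths. Edges whose length is absent in
#' the input are assigned `default_length`.
#'
#' @param source Newick string (must end in `;`) or path to a Newick file.
#' @param default_length Length assigned to edges with no length in the
#'   input. Default 0.
#' @return A rooted `phylo` object.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' @export
read_newick <- function(source, default_length = 0) {
  stopifnot(is.character(source), length(source) == 1L)
  tr <- if (grepl(";", source, fixed = TRUE)) {
    tryCatch(ape::read.tree(text = source),
             error = function(e) stop("Newick parse error: ", conditionMessage(e)))
  } else {
    if (!file.exists(source)) stop("no such file: ", source)
    ape::read.tree(source)
  }
  if (is.null(tr)) stop("Newick parse error: could not parse input")
  if (inherits(tr, "multiPhylo")) tr <- tr[[1L]]
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip label(s): ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (is.null(tr$edge.length)) {
    tr$edge.length <- rep(default_length, nrow(tr$edge))
  } else if (anyNA(tr$edge.length)) {
    tr$edge.length[is.na(tr$edge.length)] <- default_length
  }
  if (any(tr$edge.length < 0)) stop("negative branch length(s) in input")
  tr
}

#' Write a phylogeny to a Newick string or file
#'
#' Round-trips with [read_newick()]: topology and branch lengths are
#' preserved exactly (up to float formatting).
#'
#' @param tree A `phylo` object.
#' @param file Optional path; if `NULL` (default) the Newick string is
#'   returned invisibly visible.
#' @return The Newick string (invisibly when writing to a file).
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree, digits = 12)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Restrict a phylogeny to a set of tips
#'
#' Drops all tips not in `keep` and suppresses the resulting degree-2
#' internal nodes, summing their incident branch lengths, so that the
#' root-to-tip depth of every kept tip is unchanged.
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of tip labels to retain (at least 2).
#' @return The pruned `phylo`.
#' @export
prune_tree <- function(tree, keep) {
  stopifnot(inherits(tree, "phylo"))
  keep <- unique(as.character(keep))
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing) > 0)
    stop("unknown tip label(s): ", paste(missing, collapse = ", "))
  if (length(keep) < 2) stop("need at least 2 tips to keep")
  if (length(keep) == ape::Ntip(tree)) return(tree)
  ape::keep.tip(tree, keep)
}

#' Phylogenetic resolution
#'
#' The ratio of the number of internal nodes to the number in a fully
#' resolved (bifurcating) rooted tree with the same tips, i.e.
#' `Nnode / (Ntip - 1)`. A fully bifurcating tree scores 1; a star tree
#' with n tips scores `1/(n-1)`.
#'
#' @param tree A `phylo` object with at least 3 tips.
#' @return Fraction in (0, 1].
#' @export
tree_resolution <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n <- ape::Ntip(tree)
  if (n < 3) stop("resolution undefined for trees with fewer than 3 tips")
  tree$Nnode / (n - 1)
}

#' Collapse short internal edges into polytomies
#'
#' Removes every internal edge shorter than `threshold`, reattaching the
#' child's children to its parent; surviving edge lengths are unchanged and
#' tips are never deleted. Used to generate trees of decreasing
#' phylogenetic resolution for sensitivity analysis. Idempotent at a fixed
#' threshold, and resolution is non-increasing in the threshold.
#'
#' @param tree A `phylo` object.
#' @param threshold Non-negative length; internal edges with length
#'   strictly below it are collapsed.
#' @return A `phylo` with `tree_resolution()` no larger than the input's.
#' @export
collapse_short_edges <- function(tree, threshold) {
  stopifnot(inherits(tree, "phylo"), is.numeric(threshold), length(threshold) == 1L)
  if (threshold < 0) stop("threshold must be non-negative")
  if (threshold == 0) return(tree)
  ape::di2multi(tree, tol = threshold)
}

#' Graft taxa onto a phylogeny at genus or family crowns
#'
#' Adds taxa missing from a tree as children of the crown node (MRCA of the
#' existing tips) of their genus, with terminal branch length equal to the
#' crown depth (the maximum node-to-descendant-tip distance), so an
#' ultrametric tree stays ultrametric. Taxa whose genus has no tips in the
#' tree fall back to the family crown. A genus represented by a single tip
#' is handled per `singleton`: `"split"` (default) bisects that tip's
#' terminal edge to create a two-tip genus clade; `"family"` uses the
#' family crown instead.
#'
#' @param tree A `phylo` object.
#' @param assignments Data frame with columns `new_taxon`, `genus`,
#'   `family` (family may be `NA` when the genus is present).
#' @param genus_map Named character vector mapping existing tip labels to
#'   genus names.
#' @param family_map Named character vector mapping existing tip labels to
#'   family names.
#' @param singleton `"split"` or `"family"`; see Details.
#' @return The augmented `phylo`; tip count grows by `nrow(assignments)`.
#' @export
graft_taxa <- function(tree, assignments, genus_map, family_map,
                       singleton = c("split", "family")) {
  stopifnot(inherits(tree, "phylo"), is.data.frame(assignments))
  singleton <- match.arg(singleton)
  req <- c("new_taxon", "genus", "family")
  if (!all(req %in% names(assignments)))
    stop("assignments must have columns: ", paste(req, collapse = ", "))
  clash <- intersect(assignments$new_taxon, tree$tip.label)
  if (length(clash) > 0)
    stop("name collision with existing tips: ", paste(clash, collapse = ", "))
  if (anyDuplicated(assignments$new_taxon) > 0)
    stop("duplicate new_taxon labels in assignments")

  genus_map <- as.character(genus_map[tree$tip.label])
  names(genus_map) <- tree$tip.label
  family_map <- as.character(family_map[tree$tip.label])
  names(family_map) <- tree$tip.label

  for (i in seq_len(nrow(assignments))) {
    a <- assignments[i, ]
    gtips <- names(genus_map)[!is.na(genus_map) & genus_map == a$genus]
    gtips <- intersect(gtips, tree$tip.label)
    if (length(gtips) >= 2) {
      tree <- bind_at_crown(tree, a$new_taxon, gtips)
    } else if (length(gtips) == 1 && singleton == "split") {
      tree <- bind_split_singleton(tree, a$new_taxon, gtips)
    } else {
      ftips <- names(family_map)[!is.na(family_map) & family_map == a$family]
      ftips <- intersect(ftips, tree$tip.label)
      if (length(ftips) < 2)
        stop("cannot place '", a$new_taxon, "': genus '", a$genus,
             "' and family '", a$family, "' unresolvable in tree")
      tree <- bind_at_crown(tree, a$new_taxon, ftips)
    }
    # keep maps valid for subsequently grafted congeners
    genus_map[a$new_taxon] <- a$genus
    family_map[a$new_taxon] <- a$family
  }
  tree
}

# Attach `label` as a child of the MRCA of `tips`, pendant length = crown depth.
bind_at_crown <- function(tree, label, tips) {
  node <- ape::getMRCA(tree, tips)
  depth <- crown_depth(tree, node)
  phytools::bind.tip(tree, label, edge.length = depth, where = node, position = 0)
}

# Split a singleton's terminal edge at half its length and attach there.
bind_split_singleton <- function(tree, label, tip) {
  idx <- match(tip, tree$tip.label)
  len <- tree$edge.length[tree$edge[, 2] == idx]
  phytools::bind.tip(tree, label, edge.length = len / 2, where = idx,
                     position = len / 2)
}

# Max distance from an internal node to its descendant tips.
crown_depth <- function(tree, node) {
  depths <- ape::node.depth.edgelength(tree)
  tips <- ape::extract.clade(tree, node)$tip.label
  max(depths[match(tips, tree$tip.label)]) - depths[node]
}
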