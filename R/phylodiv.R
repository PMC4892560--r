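#' Fair-proportion evolutionary distinctiveness
#'
#' Partitions every edge's length equally among the tips descending from
#' it; a tip's ED is the sum of its shares along its root-to-tip path. The
#' ED values therefore sum exactly to the total branch length of the tree
#' (any root edge excluded — it is shared by all tips and carries no
#' information about distinctiveness).
#'
#' @param tree A `phylo` object with branch lengths and at least 2 tips.
#' @return Named numeric vector of ED values, one per tip, in
#'   branch-length units.
#' @examples
#' fair_proportion(read_newick("((A:1,B:1):1,(C:1,D:1):1);"))  # all 1.5
#' @export
fair_proportion <- function(tree) {
  ed_scores(tree, correction = FALSE)
}

#' Evolutionary distinctiveness with optional polytomy correction
#'
#' Uncorrected ED is the fair proportion ([fair_proportion()]). Unresolved
#' nodes inflate ED: a polytomy hands each of its c daughters a full pendant
#' edge where a resolved tree would let them share internal structure. With
#' `correction = TRUE`, every edge whose parent node has c > 2 children has
#' its contribution multiplied by 2/c before partitioning — the identity on
#' fully bifurcating trees, and a strict down-weighting of polytomy
#' daughters. Corrected ED no longer sums to total branch length.
#'
#' @param tree A `phylo` object with branch lengths.
#' @param correction Apply the polytomy down-weighting? Default `FALSE`.
#' @return Named numeric vector of ED values, one per tip.
#' @export
ed_scores <- function(tree, correction = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  n <- ape::Ntip(tree)
  if (n < 2) stop("need at least 2 tips")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  eo <- ape::reorder.phylo(tree, "postorder")
  m <- n + tree$Nnode
  ntips_below <- c(rep(1L, n), integer(tree$Nnode))
  nchildren <- integer(m)
  for (k in seq_len(nrow(eo$edge))) {
    p <- eo$edge[k, 1L]; ch <- eo$edge[k, 2L]
    ntips_below[p] <- ntips_below[p] + ntips_below[ch]
    nchildren[p] <- nchildren[p] + 1L
  }
  len <- eo$edge.length
  if (correction) {
    cpar <- nchildren[eo$edge[, 1L]]
    len <- len * ifelse(cpar > 2L, 2 / cpar, 1)
  }
  share <- len / ntips_below[eo$edge[, 2L]]
  # accumulate per-tip down the tree: preorder pass adding parent's running sum
  acc <- numeric(m)
  for (k in rev(seq_len(nrow(eo$edge)))) {
    p <- eo$edge[k, 1L]; ch <- eo$edge[k, 2L]
    acc[ch] <- acc[p] + share[k]
  }
  out <- acc[seq_len(n)]
  names(out) <- tree$tip.label
  out
}

#' PhyloSor phylogenetic similarity of two tip sets
#'
#' Twice the branch length shared by the two sets divided by the sum of
#' each set's total branch length, where a set's branch length is the total
#' length of edges on the union of root-to-tip paths of its members
#' (root-spanning convention; any root edge excluded). 1 for identical
#' sets; 0 when the sets' spanning paths share no edges.
#'
#' @param tree A `phylo` object with branch lengths.
#' @param set_a,set_b Non-empty character vectors of tip labels.
#' @return Similarity in [0, 1]; symmetric in its set arguments.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' phylosor_similarity(tr, c("A", "B"), c("A", "C"))  # 4/7
#' @export
phylosor_similarity <- function(tree, set_a, set_b) {
  stopifnot(inherits(tree, "phylo"))
  in_a <- spanning_edges(tree, set_a)
  in_b <- spanning_edges(tree, set_b)
  len <- tree$edge.length
  bl_a <- sum(len[in_a]); bl_b <- sum(len[in_b])
  shared <- sum(len[in_a & in_b])
  if (bl_a + bl_b == 0) return(1)
  2 * shared / (bl_a + bl_b)
}

# logical over edge rows: does the edge lie on a root-to-tip path of `tips`?
spanning_edges <- function(tree, tips) {
  tips <- unique(as.character(tips))
  if (length(tips) == 0) stop("tip set must be non-empty")
  bad <- setdiff(tips, tree$tip.label)
  if (length(bad) > 0) stop("unknown tip label(s): ", paste(bad, collapse = ", "))
  n <- ape::Ntip(tree)
  m <- n + tree$Nnode
  inset <- integer(m)
  inset[match(tips, tree$tip.label)] <- 1L
  eo <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(eo$edge))) {
    p <- eo$edge[k, 1L]
    inset[p] <- inset[p] + inset[eo$edge[k, 2L]]
  }
  inset[tree$edge[, 2L]] > 0L
}

#' Jaccard similarity of two label sets
#'
#' Intersection over union; the "binary" taxonomic overlap measure used to
#' compare prioritization solution sets.
#'
#' @param set_a,set_b Non-empty character vectors.
#' @return Similarity in [0, 1].
#' @export
jaccard_similarity <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (length(set_a) == 0 || length(set_b) == 0) stop("sets must be non-empty")
  length(intersect(set_a, set_b)) / length(union(set_a, set_b))
}
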