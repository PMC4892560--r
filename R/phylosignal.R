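#' Sum of sister-clade differences for a binary trait
#'
#' The raw statistic underlying the Fritz-Purvis D measure of phylogenetic
#' signal. Traversing the tree in postorder, each internal node's value is
#' estimated as the plain mean of its children's values (the
#' contrasts-style estimate under unit branch lengths; polytomies are
#' first-class), and the node contributes the sum of absolute deviations of
#' each child's value from that mean. For a bifurcation this is
#' `|left - right|`. Sigma-d is small for phylogenetically clustered traits
#' and large for overdispersed ones.
#'
#' @param tree A `phylo` object.
#' @param trait Named 0/1 vector covering every tip, non-constant.
#' @return Non-negative scalar.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' sum_sister_differences(tr, c(A = 1, B = 1, C = 0, D = 0))  # 1
#' sum_sister_differences(tr, c(A = 1, B = 0, C = 1, D = 0))  # 2
#' @export
sum_sister_differences <- function(tree, trait) {
  x <- check_binary_trait(tree, trait)
  drop(sigma_d_matrix(tree, matrix(x, ncol = 1)))
}

# Vectorised sigma-d over columns of a tips x m 0/1 matrix (rows in
# tree$tip.label order). One postorder pass shared by all columns.
sigma_d_matrix <- function(tree, traits) {
  n <- ape::Ntip(tree)
  m <- n + tree$Nnode
  eo <- ape::reorder.phylo(tree, "postorder")
  vals <- matrix(0, nrow = m, ncol = ncol(traits))
  vals[seq_len(n), ] <- traits
  sumd <- numeric(ncol(traits))
  edges <- eo$edge
  # children are contiguous per parent in postorder edge lists
  parents <- edges[, 1]
  bounds <- c(0L, which(diff(parents) != 0L), nrow(edges))
  for (b in seq_len(length(bounds) - 1L)) {
    rows <- (bounds[b] + 1L):bounds[b + 1L]
    p <- parents[rows[1L]]
    ch <- edges[rows, 2L]
    cv <- vals[ch, , drop = FALSE]
    nodeval <- colMeans(cv)
    vals[p, ] <- nodeval
    sumd <- sumd + colSums(abs(sweep(cv, 2L, nodeval)))
  }
  sumd
}

check_binary_trait <- function(tree, trait) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(names(trait))) stop("trait must be named by tip label")
  missing <- setdiff(tree$tip.label, names(trait))
  if (length(missing) > 0)
    stop("trait missing for tip(s): ", paste(utils::head(missing, 5), collapse = ", "))
  x <- as.numeric(trait[tree$tip.label])
  if (!all(x %in% c(0, 1))) stop("trait values must be 0 or 1")
  if (all(x == 0) || all(x == 1))
    stop("trait is constant; prevalence must be strictly between 0 and 1")
  x
}

#' Randomly permute a binary trait across tips
#'
#' The random (tip-shuffle) null of the D statistic: the multiset of trait
#' values is preserved, their assignment to tips is uniformly random.
#'
#' @param trait Named 0/1 vector.
#' @param seed Integer RNG seed; identical seeds give identical outputs.
#' @return Named 0/1 vector over the same tips.
#' @export
permute_tips <- function(trait, seed) {
  stopifnot(!is.null(names(trait)))
  set.seed(seed)
  out <- sample(as.numeric(trait))
  names(out) <- names(trait)
  out
}

#' Simulate a binary trait under threshold Brownian motion
#'
#' The clustered (Brownian) null of the D statistic. A continuous character
#' evolves from the root with independent Gaussian increments per edge
#' (variance proportional to edge length; unit lengths are substituted when
#' the tree carries no usable lengths), and the `n_ones` tips with the
#' largest values are set to 1, so prevalence matches exactly.
#'
#' @param tree A `phylo` object.
#' @param n_ones Number of tips to set to 1, strictly between 0 and
#'   `Ntip(tree)`.
#' @param seed Integer RNG seed.
#' @return Named 0/1 vector over the tips.
#' @export
simulate_brownian_threshold <- function(tree, n_ones, seed) {
  stopifnot(inherits(tree, "phylo"))
  n <- ape::Ntip(tree)
  if (n_ones <= 0 || n_ones >= n) stop("n_ones must be strictly between 0 and Ntip")
  set.seed(seed)
  x <- brownian_tips(tree, 1L)[, 1L]
  out <- numeric(n)
  out[order(x, decreasing = TRUE)[seq_len(n_ones)]] <- 1
  names(out) <- tree$tip.label
  out
}

# m independent Brownian simulations; returns tips x m matrix of tip values
# (rows in tree$tip.label order). Uses the current RNG stream.
brownian_tips <- function(tree, m) {
  n <- ape::Ntip(tree)
  len <- tree$edge.length
  if (is.null(len) || all(len == 0)) len <- rep(1, nrow(tree$edge))
  eo <- ape::reorder.phylo(tree, "postorder")
  ord <- rev(seq_len(nrow(eo$edge)))  # preorder: root first
  lens <- eo$edge.length
  if (is.null(lens) || all(lens == 0)) lens <- rep(1, nrow(eo$edge))
  vals <- matrix(0, nrow = n + tree$Nnode, ncol = m)
  inc <- matrix(stats::rnorm(length(ord) * m), nrow = length(ord)) *
    sqrt(lens[ord])
  for (j in seq_along(ord)) {
    k <- ord[j]
    vals[eo$edge[k, 2L], ] <- vals[eo$edge[k, 1L], ] + inc[j, ]
  }
  vals[seq_len(n), , drop = FALSE]
}

#' Fritz-Purvis D statistic for a binary trait
#'
#' Standardizes the observed sum of sister-clade differences against two
#' nulls: random tip shuffles (expectation of D is 1) and
#' threshold-Brownian traits at matched prevalence (expectation 0):
#' \deqn{D = \frac{\Sigma d_{obs} - \overline{\Sigma d}_{Brownian}}
#'            {\overline{\Sigma d}_{random} - \overline{\Sigma d}_{Brownian}}}
#' D < 1 indicates phylogenetic clustering relative to chance; D can fall
#' outside [0, 1]. One-sided p-values: `p_random` is the proportion of
#' permutation replicates with sigma-d at or below the observed value
#' (tests D < 1), `p_brownian` the proportion of Brownian replicates at or
#' above it (tests D > 0).
#'
#' @param tree A `phylo` object.
#' @param trait Named 0/1 vector over the tips, non-constant.
#' @param n_perm Replicates per null (default 1000).
#' @param seed Integer RNG seed.
#' @return A list of class `pieces_d` with elements `D`, `sum_d_obs`,
#'   `mean_sum_d_random`, `mean_sum_d_brownian`, `p_random`, `p_brownian`,
#'   `n_perm`.
#' @export
d_statistic <- function(tree, trait, n_perm = 1000, seed) {
  x <- check_binary_trait(tree, trait)
  if (n_perm < 1) stop("n_perm must be >= 1")
  obs <- drop(sigma_d_matrix(tree, matrix(x, ncol = 1)))
  n <- ape::Ntip(tree)
  n1 <- sum(x)
  set.seed(seed)
  perm <- matrix(0, nrow = n, ncol = n_perm)
  for (j in seq_len(n_perm)) perm[sample.int(n, n1), j] <- 1
  sd_perm <- sigma_d_matrix(tree, perm)
  bm <- brownian_tips(tree, n_perm)
  bro <- matrix(0, nrow = n, ncol = n_perm)
  for (j in seq_len(n_perm))
    bro[order(bm[, j], decreasing = TRUE)[seq_len(n1)], j] <- 1
  sd_bro <- sigma_d_matrix(tree, bro)
  mr <- mean(sd_perm)
  mb <- mean(sd_bro)
  structure(list(
    D = (obs - mb) / (mr - mb),
    sum_d_obs = obs,
    mean_sum_d_random = mr,
    mean_sum_d_brownian = mb,
    p_random = mean(sd_perm <= obs),
    p_brownian = mean(sd_bro >= obs),
    n_perm = n_perm
  ), class = "pieces_d")
}

#' @export
print.pieces_d <- function(x, ...) {
  cat(sprintf("Fritz-Purvis D = %.4f  (n_perm = %d)\n", x$D, x$n_perm))
  cat(sprintf("  P(D < 1) [random null]   = %.4g\n", x$p_random))
  cat(sprintf("  P(D > 0) [Brownian null] = %.4g\n", x$p_brownian))
  invisible(x)
}

#' Sensitivity of D to phylogenetic resolution
#'
#' Collapses internal edges below each threshold (see
#' [collapse_short_edges()]) and recomputes the D statistic on each
#' partially collapsed tree, tracing how signal detection degrades as
#' resolution is lost.
#'
#' @param tree A `phylo` object.
#' @param trait Named 0/1 vector over the tips.
#' @param thresholds Ascending numeric vector of collapse thresholds.
#' @param n_perm Replicates per null per threshold.
#' @param seed Integer RNG seed (re-derived per threshold for independence).
#' @return Data frame with columns `threshold`, `resolution`, `D`,
#'   `p_random`, `p_brownian`.
#' @export
resolution_sensitivity <- function(tree, trait, thresholds, n_perm = 1000, seed) {
  stopifnot(is.numeric(thresholds), !is.unsorted(thresholds))
  rows <- lapply(seq_along(thresholds), function(i) {
    tr <- collapse_short_edges(tree, thresholds[i])
    d <- d_statistic(tr, trait, n_perm = n_perm, seed = seed + i - 1L)
    data.frame(threshold = thresholds[i], resolution = tree_resolution(tr),
               D = d$D, p_random = d$p_random, p_brownian = d$p_brownian)
  })
  do.call(rbind, rows)
}
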