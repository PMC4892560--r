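#' Random pure-birth (Yule) tree
#'
#' An ultrametric, fully bifurcating constant-rate birth tree, used as the
#' backbone for synthetic taxon tables and calibration tests.
#'
#' @param n_tips Number of tips (>= 3).
#' @param seed Integer RNG seed.
#' @return A `phylo` with `tree_resolution() == 1` and equal tip depths.
#' @export
yule_tree <- function(n_tips, seed) {
  if (n_tips < 3) stop("n_tips must be >= 3")
  set.seed(seed)
  ape::rphylo(n_tips, birth = 1, death = 0)
}

#' Parameters for the synthetic taxon-table generator
#'
#' Defaults describe a pool resembling a continental vascular-plant flora:
#' threat-rank proportions matching the North American angiosperm rank
#' totals (R1..R5 = 1490, 2025, 3352, 5582, 6317 of 18,766), per-rank
#' probabilities of being absent from seed banks / living collections
#' matching the observed per-rank coverage, geometric positive-part
#' collection counts (mean 3 seed / 6 living collections among collected
#' taxa — long right tail, occasional counts in the hundreds), and mild
#' phylogenetic clustering of threat ranks (`signal_strength = 0.3`).
#'
#' @param n_tips Ignored here (taken from the tree); kept for record.
#' @param signal_strength Ratio of Brownian to independent variance in the
#'   latent vulnerability trait; 0 = no phylogenetic clustering, large
#'   values approach pure Brownian.
#' @param rank_proportions Five fractions (R1..R5) summing to 1.
#' @param seed_zero_inflation,living_zero_inflation Per-rank probability of
#'   a zero count (absence from that collection type).
#' @param seed_count_mean,living_count_mean Mean count among collected taxa.
#' @return List of class `synth_params`.
#' @export
synth_params <- function(n_tips = NULL,
                         signal_strength = 0.3,
                         rank_proportions = c(1490, 2025, 3352, 5582, 6317) / 18766,
                         seed_zero_inflation = 1 - c(470, 454, 668, 1506, 3207) /
                           c(1490, 2025, 3352, 5582, 6317),
                         living_zero_inflation = 1 - c(559, 670, 1146, 2549, 4357) /
                           c(1490, 2025, 3352, 5582, 6317),
                         seed_count_mean = 3,
                         living_count_mean = 6) {
  stopifnot(length(rank_proportions) == 5,
            abs(sum(rank_proportions) - 1) < 1e-9,
            all(rank_proportions >= 0),
            signal_strength >= 0,
            all(seed_zero_inflation >= 0 & seed_zero_inflation <= 1),
            all(living_zero_inflation >= 0 & living_zero_inflation <= 1),
            seed_count_mean >= 1, living_count_mean >= 1)
  structure(list(n_tips = n_tips, signal_strength = signal_strength,
                 rank_proportions = rank_proportions,
                 seed_zero_inflation = seed_zero_inflation,
                 living_zero_inflation = living_zero_inflation,
                 seed_count_mean = seed_count_mean,
                 living_count_mean = living_count_mean),
            class = "synth_params")
}

#' Synthetic taxon table over a phylogeny
#'
#' Generates threat ranks and collection counts with the statistical
#' structure the analyses assume. A latent vulnerability trait is a mixture
#' of a Brownian component on the tree (weight `signal_strength`) and
#' i.i.d. noise (weight 1); ranks are assigned by exact-quota thresholding
#' of the latent trait (most vulnerable tips become R1), so rank counts
#' match `rank_proportions * n_tips` exactly. Collection counts are
#' zero-inflated geometric with per-rank zero probabilities, reproducing
#' the rank-dependent coverage gaps (and hence phylogenetically clustered
#' coverage when ranks are clustered).
#'
#' @param tree A `phylo` object.
#' @param params A [synth_params()] object.
#' @param seed Integer RNG seed.
#' @return Data frame `taxon, rank, n_seed, n_living`.
#' @export
synth_taxon_table <- function(tree, params = synth_params(), seed) {
  stopifnot(inherits(tree, "phylo"), inherits(params, "synth_params"))
  n <- ape::Ntip(tree)
  quota <- round(params$rank_proportions * n)
  # fix rounding drift on the largest class
  quota[which.max(quota)] <- quota[which.max(quota)] + (n - sum(quota))
  if (any(quota < 0)) stop("rank proportions infeasible for n_tips")
  set.seed(seed)
  bm <- brownian_tips(tree, 1L)[, 1L]
  bm <- (bm - mean(bm)) / max(stats::sd(bm), .Machine$double.eps)
  s <- params$signal_strength
  latent <- sqrt(s / (1 + s)) * bm + sqrt(1 / (1 + s)) * stats::rnorm(n)
  rank <- character(n)
  ord <- order(latent, decreasing = TRUE)  # most vulnerable first
  idx <- 0
  for (r in 1:5) {
    if (quota[r] > 0) {
      rank[ord[(idx + 1):(idx + quota[r])]] <- paste0("R", r)
      idx <- idx + quota[r]
    }
  }
  draw_counts <- function(zi, mu) {
    zero <- stats::runif(n) < zi[match(rank, paste0("R", 1:5))]
    pos <- 1L + stats::rgeom(n, prob = 1 / mu)
    ifelse(zero, 0L, pos)
  }
  data.frame(
    taxon = tree$tip.label,
    rank = rank,
    n_seed = draw_counts(params$seed_zero_inflation, params$seed_count_mean),
    n_living = draw_counts(params$living_zero_inflation, params$living_count_mean),
    stringsAsFactors = FALSE
  )
}

#' Small integration fixture echoing the continental-flora structure
#'
#' A 500-tip Yule tree plus a taxon table generated with the default
#' [synth_params()], so the marginal structure matches the North American
#' angiosperm pool at reduced scale: about one-third of taxa in seed banks,
#' about half in living collections, rank proportions matching the R1..R5
#' totals, and mildly clustered vulnerability.
#'
#' @param seed Integer RNG seed.
#' @param n_tips Tree size (default 500).
#' @return List with elements `tree` (`phylo`) and `table` (data frame
#'   `taxon, rank, n_seed, n_living, ed_raw` — raw fair-proportion ED
#'   appended, polytomy correction unnecessary on a bifurcating tree).
#' @export
flora_fixture <- function(seed = 0, n_tips = 500) {
  tree <- yule_tree(n_tips, seed = seed)
  tab <- synth_taxon_table(tree, synth_params(), seed = seed + 1L)
  tab$ed_raw <- unname(fair_proportion(tree)[tab$taxon])
  list(tree = tree, table = tab)
}

#' Coverage summary of a taxon table
#'
#' Per-rank and overall counts and percentages of taxa present in seed
#' banks, in living collections, and in at least one collection type.
#'
#' @param table Taxon table with `rank`, `n_seed`, `n_living`.
#' @return Data frame with one row per rank plus a `Total` row; columns
#'   `rank, n_taxa, n_seed, n_living, n_any, pct_seed, pct_living, pct_any`.
#' @export
coverage_summary <- function(table) {
  check_taxon_table(table, need_ed = FALSE)
  ranks <- paste0("R", 1:5)
  rows <- lapply(c(ranks, "Total"), function(r) {
    sub <- if (r == "Total") table else table[table$rank == r, ]
    data.frame(rank = r, n_taxa = nrow(sub),
               n_seed = sum(sub$n_seed > 0),
               n_living = sum(sub$n_living > 0),
               n_any = sum(sub$n_seed > 0 | sub$n_living > 0))
  })
  out <- do.call(rbind, rows)
  out$pct_seed <- 100 * out$n_seed / out$n_taxa
  out$pct_living <- 100 * out$n_living / out$n_taxa
  out$pct_any <- 100 * out$n_any / out$n_taxa
  out
}

#' Expand a per-rank coverage summary into a presence/absence taxon table
#'
#' Reconstructs a per-taxon table (with 0/1 collection indicators) from
#' marginal per-rank counts: taxa in the tree-of-record are not identified,
#' only the counts per (rank, status) cell matter, so the expansion fills
#' each cell with anonymous taxon ids. The number of taxa in both
#' collection types per rank is recovered as
#' `n_both = n_seed + n_living - n_any`.
#'
#' @param summary Data frame with columns `rank, n_taxa, n_seed, n_living`
#'   and either `n_any` or `pct_any` (percentage of the rank in at least
#'   one collection).
#' @return Data frame `taxon, rank, n_seed, n_living` with 0/1 counts,
#'   suitable for [gap_table()] and [coverage_summary()].
#' @export
expand_summary_table <- function(summary) {
  req <- c("rank", "n_taxa", "n_seed", "n_living")
  if (!all(req %in% names(summary)))
    stop("summary must have columns: ", paste(req, collapse = ", "))
  if (!"n_any" %in% names(summary)) {
    if (!"pct_any" %in% names(summary)) stop("summary needs n_any or pct_any")
    summary$n_any <- round(summary$n_taxa * summary$pct_any / 100)
  }
  rows <- lapply(seq_len(nrow(summary)), function(i) {
    s <- summary[i, ]
    n_both <- s$n_seed + s$n_living - s$n_any
    if (n_both < 0 || n_both > min(s$n_seed, s$n_living))
      stop("inconsistent marginals for rank ", s$rank)
    cells <- c(both = n_both, seed_only = s$n_seed - n_both,
               living_only = s$n_living - n_both, neither = s$n_taxa - s$n_any)
    data.frame(
      rank = s$rank,
      n_seed = rep(c(1L, 1L, 0L, 0L), cells),
      n_living = rep(c(1L, 0L, 1L, 0L), cells),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- cbind(taxon = sprintf("t%05d", seq_len(nrow(out))), out)
  out
}
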