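#' AHP weights from a pairwise-comparison matrix
#'
#' Analytic hierarchy process weight elicitation: the decision maker's
#' reciprocal pairwise-comparison matrix (Saaty 1-9 scale) is reduced to a
#' weight vector by normalizing the principal right eigenvector, computed
#' by power iteration (tolerance 1e-12, max 10,000 iterations; dense
#' eigendecomposition fallback). Consistency is summarized by
#' `CR = ((lambda_max - n)/(n - 1)) / RI(n)` with Saaty's random-index
#' table; a warning is issued above 0.1 but the result is never rejected.
#'
#' @param matrix Square positive matrix with unit diagonal and reciprocal
#'   symmetry (`a_ji = 1/a_ij`, tolerance 1e-9).
#' @param saaty_check Require entries in [1/9, 9]? Default `FALSE`.
#' @return List with `weights` (positive, summing to 1), `lambda_max`,
#'   `consistency_ratio`.
#' @examples
#' ahp_weights(matrix(1, 4, 4))$weights  # 0.25 each
#' @export
ahp_weights <- function(matrix, saaty_check = FALSE) {
  A <- as.matrix(matrix)
  n <- nrow(A)
  if (n < 2 || ncol(A) != n) stop("matrix must be square with n >= 2")
  if (any(A <= 0)) stop("matrix entries must be positive")
  if (max(abs(diag(A) - 1)) > 1e-9) stop("diagonal entries must be 1")
  if (max(abs(A * t(A) - 1)) > 1e-9 * max(A))
    stop("matrix is not reciprocal (a_ji != 1/a_ij)")
  if (saaty_check && (max(A) > 9 + 1e-9 || min(A) < 1 / 9 - 1e-9))
    stop("entries outside the Saaty 1/9..9 scale")

  w <- rep(1 / n, n)
  lambda <- NA_real_
  converged <- FALSE
  for (it in seq_len(10000L)) {
    v <- drop(A %*% w)
    w_new <- v / sum(v)
    if (max(abs(w_new - w)) < 1e-12) {
      w <- w_new
      lambda <- mean(drop(A %*% w) / w)
      converged <- TRUE
      break
    }
    w <- w_new
  }
  if (!converged) {
    e <- eigen(A)
    k <- which.max(Re(e$values))
    w <- Re(e$vectors[, k])
    w <- w / sum(w)
    lambda <- Re(e$values[k])
  }
  # Saaty random-consistency indices, n = 1..10
  ri <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49)
  ci <- (lambda - n) / (n - 1)
  cr <- if (n <= 2 || n > 10) {
    if (n > 10) NA_real_ else 0
  } else ci / ri[n]
  if (!is.na(cr) && cr > 0.1)
    warning(sprintf("consistency ratio %.3f exceeds 0.1", cr))
  list(weights = w, lambda_max = lambda, consistency_ratio = cr)
}

#' Uniform random weight vectors on the simplex
#'
#' Samples `k` vectors uniformly on the (dims-1)-simplex (flat Dirichlet,
#' normalized unit-rate exponentials), so each vector is non-negative and
#' sums to 1. Used for weight-space analysis.
#'
#' @param k Number of vectors.
#' @param dims Dimension (default 4).
#' @param seed Integer RNG seed.
#' @return `k x dims` matrix with unit row sums.
#' @export
sample_weight_vectors <- function(k, dims = 4, seed) {
  stopifnot(k >= 1, dims >= 2)
  set.seed(seed)
  g <- matrix(stats::rexp(k * dims), nrow = k)
  g / rowSums(g)
}

#' Taxon selections under alternative prioritization schemes
#'
#' The five schemes compared in the framework:
#' \describe{
#'   \item{PIECES}{top-n by the multi-criteria score ([pieces_scores()]);
#'     deterministic.}
#'   \item{EDGE}{top-n by [edge_scores()]; deterministic.}
#'   \item{EDSeedBank}{among taxa absent from seed banks (`n_seed == 0`),
#'     top-n by raw ED; deterministic.}
#'   \item{Endangered}{uniformly random n-subsets of the most threatened
#'     stratum (all of R1, filling from R2, R3, ... when a stratum is
#'     exhausted); returns `n_subsamples` replicate selections.}
#'   \item{ExSitu}{uniformly random n-subsets of taxa with no collections
#'     at all (`n_seed == 0 & n_living == 0`); `n_subsamples` replicates.}
#' }
#'
#' @param scheme One of `"PIECES"`, `"EDGE"`, `"EDSeedBank"`,
#'   `"Endangered"`, `"ExSitu"`.
#' @param table Taxon table with `taxon`, `rank`, `n_seed`, `n_living`,
#'   `ed_raw`.
#' @param n Selection size.
#' @param weights PIECES weights; default [published_weights()].
#' @param n_subsamples Replicates for the degenerate schemes (default 100).
#' @param seed Integer RNG seed (random schemes only).
#' @return For deterministic schemes a character vector of `n` taxa; for
#'   `Endangered` and `ExSitu` a list of `n_subsamples` such vectors.
#' @export
scheme_selection <- function(scheme = c("PIECES", "EDGE", "EDSeedBank",
                                        "Endangered", "ExSitu"),
                             table, n, weights = published_weights(),
                             n_subsamples = 100, seed = 0) {
  scheme <- match.arg(scheme)
  check_taxon_table(table)
  if (n > nrow(table)) stop("n exceeds number of candidate taxa")
  switch(scheme,
    PIECES = rank_select(pieces_scores(table, weights), n),
    EDGE = rank_select(edge_scores(table), n),
    EDSeedBank = {
      pool <- table[table$n_seed == 0, c("taxon", "ed_raw")]
      if (nrow(pool) < n) stop("fewer than n taxa absent from seed banks")
      names(pool)[2] <- "score"
      rank_select(pool, n, "score")
    },
    Endangered = {
      strata <- lapply(paste0("R", 1:5), function(r) sort(table$taxon[table$rank == r]))
      fixed <- character(0)
      pool <- NULL
      need <- n
      for (s in strata) {
        if (length(s) >= need) { pool <- s; break }
        fixed <- c(fixed, s)
        need <- need - length(s)
      }
      if (is.null(pool)) stop("fewer than n candidate taxa")
      random_subsets(pool, need, fixed, n_subsamples, seed)
    },
    ExSitu = {
      pool <- sort(table$taxon[table$n_seed == 0 & table$n_living == 0])
      if (length(pool) < n) stop("fewer than n uncollected taxa")
      random_subsets(pool, n, character(0), n_subsamples, seed)
    }
  )
}

random_subsets <- function(pool, need, fixed, n_subsamples, seed) {
  set.seed(seed)
  lapply(seq_len(n_subsamples), function(i)
    c(fixed, sample(pool, need)))
}

#' Conservation return on investment of a taxon selection
#'
#' For a selected taxon set, the four objective values: the number of novel
#' seed-bank additions (selected taxa with `n_seed == 0`), novel
#' living-collection additions (`n_living == 0`), mean threat level on the
#' 0-4 scale (R5 = 0 .. R1 = 4), and mean raw evolutionary distinctiveness.
#' For a scheme family (list of replicate selections) the mean ROI across
#' replicates is returned.
#'
#' @param selection Character vector of taxa, or a list of such vectors.
#' @param table Taxon table containing every selected taxon.
#' @return Data frame with one row: `new_seed, new_living, mean_threat,
#'   mean_ed`.
#' @export
roi <- function(selection, table) {
  check_taxon_table(table)
  if (is.list(selection)) {
    rows <- do.call(rbind, lapply(selection, roi, table = table))
    return(as.data.frame(as.list(colMeans(rows))))
  }
  idx <- match(selection, table$taxon)
  if (anyNA(idx))
    stop("unknown taxon/taxa in selection: ",
         paste(utils::head(selection[is.na(idx)], 5), collapse = ", "))
  data.frame(
    new_seed = sum(table$n_seed[idx] == 0),
    new_living = sum(table$n_living[idx] == 0),
    mean_threat = mean(threat_level(table$rank[idx])),
    mean_ed = mean(table$ed_raw[idx])
  )
}

#' Weight-space analysis of the priority index
#'
#' Samples `k` preference-weight vectors uniformly on the simplex, and for
#' each computes the PIECES top-n selection and its ROI, tracing the cloud
#' of outcomes attainable across all weightings of the four objectives.
#'
#' @param table Taxon table.
#' @param k Number of weight vectors.
#' @param n Selection size per vector.
#' @param seed Integer RNG seed.
#' @return Data frame with columns `w_sb, w_lc, w_ge, w_ed, new_seed,
#'   new_living, mean_threat, mean_ed`, one row per vector.
#' @export
weight_space_analysis <- function(table, k, n, seed) {
  check_taxon_table(table)
  W <- sample_weight_vectors(k, 4, seed)
  # precompute normalized components once; scores are then a matrix product
  comp <- cbind(sb = normalize_collections(table$n_seed),
                lc = normalize_collections(table$n_living),
                ge = ge_score(table$rank),
                ed = scale_ed(table$ed_raw))
  is_seed0 <- table$n_seed == 0
  is_living0 <- table$n_living == 0
  thr <- threat_level(table$rank)
  edr <- table$ed_raw
  lab <- table$taxon
  out <- matrix(NA_real_, nrow = k, ncol = 4)
  for (i in seq_len(k)) {
    sc <- drop(comp %*% W[i, ])
    top <- order(-sc, lab)[seq_len(n)]
    out[i, ] <- c(sum(is_seed0[top]), sum(is_living0[top]),
                  mean(thr[top]), mean(edr[top]))
  }
  res <- data.frame(W, out)
  names(res) <- c("w_sb", "w_lc", "w_ge", "w_ed",
                  "new_seed", "new_living", "mean_threat", "mean_ed")
  res
}

#' Pareto frontier of a 2-D point cloud
#'
#' The non-dominated subset of points under the given per-axis orientation:
#' a point is on the frontier iff no other point is at least as good on
#' both axes and strictly better on one. Duplicate frontier points are
#' retained once.
#'
#' @param points Two-column numeric matrix or data frame.
#' @param orientation Length-2 character vector, each `"max"` or `"min"`.
#' @return The frontier points (same columns), sorted by the first axis.
#' @export
pareto_front <- function(points, orientation = c("max", "max")) {
  pts <- as.matrix(points)
  if (nrow(pts) < 1 || ncol(pts) != 2) stop("points must be a non-empty 2-column set")
  if (length(orientation) != 2 || !all(orientation %in% c("max", "min")))
    stop("orientation must be two of \"max\"/\"min\"")
  s <- pts
  if (orientation[1] == "min") s[, 1] <- -s[, 1]
  if (orientation[2] == "min") s[, 2] <- -s[, 2]
  u <- unique(s)
  ord <- order(-u[, 1], -u[, 2])
  u <- u[ord, , drop = FALSE]
  best_y <- -Inf
  keep <- logical(nrow(u))
  for (i in seq_len(nrow(u))) {
    if (u[i, 2] > best_y) {
      keep[i] <- TRUE
      best_y <- u[i, 2]
    }
  }
  front <- u[keep, , drop = FALSE]
  if (orientation[1] == "min") front[, 1] <- -front[, 1]
  if (orientation[2] == "min") front[, 2] <- -front[, 2]
  front <- front[order(front[, 1]), , drop = FALSE]
  colnames(front) <- colnames(pts)
  front
}

#' Gap table of collection coverage by threat rank
#'
#' Cross-tabulates taxa by ex situ status (in seed banks only, living
#' collections only, both, or neither) against threat rank, and tests
#' independence with a Pearson chi-squared test (no continuity correction).
#'
#' @param table Taxon table with `rank`, `n_seed`, `n_living`.
#' @return List with `counts` (4 x 5 matrix, statuses x ranks),
#'   `statistic` (X-squared), `df`, `p_value`.
#' @export
gap_table <- function(table) {
  check_taxon_table(table, need_ed = FALSE)
  status <- ifelse(table$n_seed > 0 & table$n_living > 0, "both",
            ifelse(table$n_seed > 0, "seed_only",
            ifelse(table$n_living > 0, "living_only", "neither")))
  status <- factor(status, levels = c("seed_only", "living_only", "both", "neither"))
  rank <- factor(table$rank, levels = paste0("R", 1:5))
  counts <- base::table(status, rank)
  use <- counts[rowSums(counts) > 0, colSums(counts) > 0, drop = FALSE]
  ct <- stats::chisq.test(use, correct = FALSE)
  list(counts = unclass(counts), statistic = unname(ct$statistic),
       df = unname(ct$parameter), p_value = ct$p.value)
}

#' Pairwise similarity of scheme solution sets
#'
#' Taxonomic (Jaccard) and phylogenetic (PhyloSor) similarity between the
#' taxon sets selected by different prioritization schemes. An element of
#' `selections` may be a list of replicate selections (a degenerate-scheme
#' family); similarities involving a family are means across up to
#' `n_draws` replicate draws (replicates paired when both schemes are
#' families).
#'
#' @param selections Named list; each element a character vector of taxa or
#'   a list of such vectors.
#' @param tree Phylogeny containing all selected taxa (for PhyloSor).
#' @param n_draws Max replicate draws averaged over (default 100).
#' @return List of two symmetric matrices, `jaccard` and `phylosor`.
#' @export
compare_solutions <- function(selections, tree, n_draws = 100) {
  stopifnot(is.list(selections), length(selections) >= 2)
  if (is.null(names(selections)) || any(names(selections) == ""))
    stop("selections must be named")
  m <- length(selections)
  jac <- phs <- matrix(1, m, m, dimnames = list(names(selections), names(selections)))
  draws <- function(x) if (is.list(x)) x[seq_len(min(n_draws, length(x)))] else list(x)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      a <- draws(selections[[i]])
      b <- draws(selections[[j]])
      r <- max(length(a), length(b))
      jv <- pv <- numeric(r)
      for (k in seq_len(r)) {
        sa <- a[[(k - 1) %% length(a) + 1]]
        sb <- b[[(k - 1) %% length(b) + 1]]
        jv[k] <- jaccard_similarity(sa, sb)
        pv[k] <- phylosor_similarity(tree, sa, sb)
      }
      jac[i, j] <- jac[j, i] <- mean(jv)
      phs[i, j] <- phs[j, i] <- mean(pv)
    }
  }
  list(jaccard = jac, phylosor = phs)
}
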