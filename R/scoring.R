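#' Collection-deficit normalization
#'
#' Converts raw collection counts into deficits in [0, 1]: counts are
#' log-transformed (`ln(x + 1)`, diminishing returns per extra collection)
#' and scaled in reverse so that 0 collections maps to 1 (maximal deficit)
#' and the maximum count across the pool maps to 0:
#' `deficit = 1 - ln(count + 1) / ln(max_count + 1)`.
#' When every count is 0 the deficit is 1 for all taxa by convention.
#'
#' @param counts Non-negative integer vector.
#' @return Numeric vector of deficits in [0, 1], strictly decreasing in
#'   the count.
#' @export
normalize_collections <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  mx <- max(counts)
  if (mx == 0) return(rep(1, length(counts)))
  1 - log(counts + 1) / log(mx + 1)
}

#' Threat-rank score (GE component)
#'
#' Maps NatureServe-style ranks to the globally-endangered score used in
#' the priority index: R1 (critically imperiled) = 1, R2 = 0.75, R3 = 0.5,
#' R4 = 0.25, R5 (secure) = 0.
#'
#' @param rank Character vector of ranks in `R1..R5`.
#' @return Numeric vector in \{0, 0.25, 0.5, 0.75, 1\}.
#' @export
ge_score <- function(rank) {
  map <- c(R1 = 1, R2 = 0.75, R3 = 0.5, R4 = 0.25, R5 = 0)
  bad <- setdiff(unique(rank), names(map))
  if (length(bad) > 0) stop("unknown threat rank(s): ", paste(bad, collapse = ", "))
  unname(map[as.character(rank)])
}

# Threat level on the 0-4 integer scale (R5 = 0 .. R1 = 4) used by the
# EDGE score and ROI mean threat rank.
threat_level <- function(rank) {
  4 * ge_score(rank)
}

#' Min-max scaling of raw evolutionary distinctiveness
#'
#' Scales raw ED to [0, 1] (least to most evolutionarily distinct) over the
#' full candidate pool: `(x - min) / (max - min)`.
#'
#' @param ed_raw Numeric vector, length >= 2, not all equal.
#' @return Numeric vector in [0, 1].
#' @export
scale_ed <- function(ed_raw) {
  if (length(ed_raw) < 2) stop("need at least 2 ED values")
  rng <- range(ed_raw)
  if (rng[1] == rng[2]) stop("degenerate ED input: all values equal")
  (ed_raw - rng[1]) / (rng[2] - rng[1])
}

#' Published preference weights for the priority index
#'
#' The four objective weights (seed-bank deficit, living-collection
#' deficit, threat, evolutionary distinctiveness) elicited through the
#' analytic hierarchy process for the North American angiosperm analysis.
#'
#' @return Named numeric vector `(sb, lc, ge, ed)` summing to 1.
#' @export
published_weights <- function() {
  c(sb = 0.4623, lc = 0.0771, ge = 0.1979, ed = 0.2627)
}

check_weights <- function(weights) {
  w <- as.numeric(weights)
  if (length(w) != 4) stop("weights must have length 4 (sb, lc, ge, ed)")
  if (any(w < 0)) stop("weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-9) stop("weights must sum to 1 (got ", sum(w), ")")
  w
}

check_taxon_table <- function(table, need_ed = TRUE) {
  req <- c("taxon", "rank", "n_seed", "n_living")
  if (need_ed) req <- c(req, "ed_raw")
  miss <- setdiff(req, names(table))
  if (length(miss) > 0)
    stop("taxon table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(table$taxon) > 0) stop("duplicate taxon ids in table")
  if (any(table$n_seed < 0) || any(table$n_living < 0))
    stop("collection counts must be non-negative")
  invisible(table)
}

#' PIECES priority scores
#'
#' The multi-criteria priority index
#' `PIECES = 100 * (w1*SB + w2*LC + w3*GE + w4*ED)`,
#' where SB and LC are the seed-bank and living-collection deficits
#' ([normalize_collections()], denominators taken over the full input
#' table), GE the threat score ([ge_score()]) and ED the min-max scaled
#' evolutionary distinctiveness ([scale_ed()]). Scores range from 0
#' (lowest priority) to 100 (no collections, critically imperiled, most
#' distinct).
#'
#' @param table Data frame with columns `taxon`, `rank`, `n_seed`,
#'   `n_living`, `ed_raw`.
#' @param weights Four non-negative weights `(sb, lc, ge, ed)` summing
#'   to 1; default [published_weights()].
#' @return Data frame `taxon, sb, lc, ge, ed, pieces` in input row order.
#' @export
pieces_scores <- function(table, weights = published_weights()) {
  check_taxon_table(table)
  w <- check_weights(weights)
  sb <- normalize_collections(table$n_seed)
  lc <- normalize_collections(table$n_living)
  ge <- ge_score(table$rank)
  ed <- scale_ed(table$ed_raw)
  data.frame(
    taxon = table$taxon, sb = sb, lc = lc, ge = ge, ed = ed,
    pieces = 100 * (w[1] * sb + w[2] * lc + w[3] * ge + w[4] * ed),
    stringsAsFactors = FALSE
  )
}

#' EDGE priority scores
#'
#' The evolutionarily-distinct / globally-endangered score
#' `EDGE = ln(1 + ED_raw) + GE_level * ln(2)`, with the threat level on the
#' 0-4 integer scale (R1 = 4 .. R5 = 0). Each extra threat level is worth a
#' doubling of (1 + ED).
#'
#' @param table Data frame with columns `taxon`, `rank`, `ed_raw`.
#' @return Data frame `taxon, edge_score` in input row order.
#' @export
edge_scores <- function(table) {
  if (!all(c("taxon", "rank", "ed_raw") %in% names(table)))
    stop("table must have columns taxon, rank, ed_raw")
  data.frame(
    taxon = table$taxon,
    edge_score = log1p(table$ed_raw) + threat_level(table$rank) * log(2),
    stringsAsFactors = FALSE
  )
}

#' Select the top-n taxa by score
#'
#' Deterministic selection of the `n` highest-scoring taxa; ties are broken
#' by ascending taxon label.
#'
#' @param scores Data frame with columns `taxon` and a score column.
#' @param n Number of taxa to select (0 to `nrow(scores)`).
#' @param score_col Name of the score column; default the second column.
#' @return Character vector of `n` taxon labels, highest score first.
#' @export
rank_select <- function(scores, n, score_col = NULL) {
  if (is.null(score_col)) {
    known <- intersect(c("pieces", "edge_score", "score"), names(scores))
    score_col <- if (length(known) > 0) known[1] else utils::tail(setdiff(names(scores), "taxon"), 1)
  }
  if (n > nrow(scores)) stop("n exceeds number of available taxa")
  if (n == 0) return(character(0))
  ord <- order(-scores[[score_col]], scores$taxon)
  scores$taxon[ord[seq_len(n)]]
}
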