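#' Read a taxon table CSV
#'
#' Expects header `taxon,rank,n_seed,n_living` with an optional `ed`
#' (or `ed_raw`) column of precomputed raw evolutionary distinctiveness.
#'
#' @param path CSV path.
#' @return Data frame with validated columns.
#' @export
read_taxon_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("ed" %in% names(tab) && !"ed_raw" %in% names(tab))
    names(tab)[names(tab) == "ed"] <- "ed_raw"
  check_taxon_table(tab, need_ed = FALSE)
  tab
}

#' Run the full prioritization pipeline
#'
#' End-to-end driver: reads (or simulates) a phylogeny and taxon table,
#' computes evolutionary distinctiveness, PIECES and EDGE scores, the five
#' scheme selections and their ROI, a weight-space cloud with pairwise
#' Pareto frontiers, the coverage gap table, and pairwise solution-set
#' similarities; writes everything as CSVs plus a JSON run manifest
#' (input checksums, configuration, package version). Reruns with an
#' identical configuration reproduce identical outputs.
#'
#' @param config Named list: `tree` and `table` paths (or `n_tips` to
#'   simulate), `out_dir`, and optional `weights` (default
#'   [published_weights()]), `n` (selection size, default 100), `k`
#'   (weight-space vectors, default 1000), `n_subsamples` (default 100),
#'   `seed` (default 0), `isaac_correction` (default: on when the tree has
#'   polytomies), `allow_missing_tips` (default FALSE).
#' @return Invisibly, a list of the computed objects and written paths.
#' @export
run_pipeline <- function(config) {
  cfg <- utils::modifyList(list(weights = published_weights(), n = 100,
                                k = 1000, n_subsamples = 100, seed = 0,
                                allow_missing_tips = FALSE), config)
  if (is.null(cfg$out_dir)) stop("config$out_dir is required")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(cfg$tree) && !is.null(cfg$table)) {
    tree <- read_newick(cfg$tree)
    tab <- read_taxon_table(cfg$table)
  } else if (!is.null(cfg$n_tips)) {
    fx <- flora_fixture(seed = cfg$seed, n_tips = cfg$n_tips)
    tree <- fx$tree
    tab <- fx$table
  } else stop("config must provide tree+table paths or n_tips to simulate")

  missing <- setdiff(tab$taxon, tree$tip.label)
  if (length(missing) > 0) {
    if (!isTRUE(cfg$allow_missing_tips))
      stop("taxa absent from tree (", length(missing), "): ",
           paste(utils::head(missing, 5), collapse = ", "),
           if (length(missing) > 5) ", ..." else "")
    message("dropping ", length(missing), " taxa absent from the tree")
    tab <- tab[tab$taxon %in% tree$tip.label, ]
  }
  extra <- setdiff(tree$tip.label, tab$taxon)
  if (length(extra) > 0 && length(tab$taxon) >= 2)
    tree <- prune_tree(tree, tab$taxon)

  if (is.null(cfg$isaac_correction))
    cfg$isaac_correction <- !ape::is.binary(tree)
  if (!"ed_raw" %in% names(tab)) {
    ed <- ed_scores(tree, correction = cfg$isaac_correction)
    tab$ed_raw <- unname(ed[tab$taxon])
  }

  w <- check_weights(cfg$weights)
  scores <- pieces_scores(tab, w)
  scores$edge_score <- edge_scores(tab)$edge_score

  schemes <- c("PIECES", "EDGE", "EDSeedBank", "Endangered", "ExSitu")
  sels <- lapply(schemes, function(s)
    scheme_selection(s, tab, n = cfg$n, weights = w,
                     n_subsamples = cfg$n_subsamples, seed = cfg$seed))
  names(sels) <- schemes
  roi_tab <- do.call(rbind, lapply(sels, roi, table = tab))
  roi_tab <- cbind(scheme = schemes, roi_tab)

  cloud <- weight_space_analysis(tab, k = cfg$k, n = cfg$n, seed = cfg$seed)
  gaps <- gap_table(tab)
  sims <- compare_solutions(sels, tree, n_draws = min(100, cfg$n_subsamples))

  p <- function(f) file.path(cfg$out_dir, f)
  utils::write.csv(scores, p("scores.csv"), row.names = FALSE)
  utils::write.csv(roi_tab, p("roi.csv"), row.names = FALSE)
  utils::write.csv(cloud, p("weight_space.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(gaps$counts), p("gap_table.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(sims$jaccard), p("similarity_jaccard.csv"))
  utils::write.csv(as.data.frame(sims$phylosor), p("similarity_phylosor.csv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("pieces")),
    config = cfg[setdiff(names(cfg), "weights")],
    weights = signif(w, 6),
    normalization = list(max_n_seed = max(tab$n_seed),
                         max_n_living = max(tab$n_living),
                         ed_min = signif(min(tab$ed_raw), 6),
                         ed_max = signif(max(tab$ed_raw), 6)),
    gap_chi_squared = signif(gaps$statistic, 6),
    inputs = if (!is.null(cfg$tree))
      as.list(tools::md5sum(c(cfg$tree, cfg$table))) else NULL
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null")

  invisible(list(tree = tree, table = tab, scores = scores,
                 selections = sels, roi = roi_tab, cloud = cloud,
                 gaps = gaps, similarities = sims,
                 paths = vapply(c("scores.csv", "roi.csv", "weight_space.csv",
                                  "gap_table.csv", "similarity_jaccard.csv",
                                  "similarity_phylosor.csv", "manifest.json"),
                                p, character(1))))
}
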