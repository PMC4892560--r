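test_that("AHP recovers weights from consistent matrices with CR = 0", {
  r <- ahp_weights(matrix(1, 4, 4))
  expect_equal(r$weights, rep(0.25, 4))
  expect_equal(r$lambda_max, 4, tolerance = 1e-9)
  expect_equal(r$consistency_ratio, 0, tolerance = 1e-9)

  v <- c(0.5, 0.25, 0.125, 0.125)
  r2 <- ahp_weights(outer(v, v, "/"))
  expect_equal(r2$weights, v, tolerance = 1e-10)
  expect_equal(r2$consistency_ratio, 0, tolerance = 1e-9)
})

test_that("AHP matches a dense-eigendecomposition oracle on inconsistent matrices", {
  A <- matrix(c(1, 3, 5,
                1 / 3, 1, 2,
                1 / 5, 1 / 2, 1), 3, 3, byrow = TRUE)
  r <- suppressWarnings(ahp_weights(A))
  e <- eigen(A)
  k <- which.max(Re(e$values))
  w_ref <- Re(e$vectors[, k]); w_ref <- w_ref / sum(w_ref)
  expect_equal(r$weights, w_ref, tolerance = 1e-8)
  expect_equal(r$lambda_max, Re(e$values[k]), tolerance = 1e-8)
  expect_gt(r$consistency_ratio, 0)
  expect_true(all(r$weights > 0))
  expect_equal(sum(r$weights), 1)
})

test_that("AHP validates its input matrix", {
  expect_error(ahp_weights(matrix(c(1, 2, 3, 1), 2, 2)), "reciprocal")
  bad <- matrix(1, 3, 3); diag(bad) <- 2
  expect_error(ahp_weights(bad), "diagonal")
  expect_error(ahp_weights(matrix(1, 1, 1)), "square")
  big <- matrix(c(1, 20, 1 / 20, 1), 2, 2, byrow = TRUE)
  expect_error(ahp_weights(big, saaty_check = TRUE), "Saaty")
  expect_warning(ahp_weights(matrix(c(1, 9, 1 / 9,
                                      1 / 9, 1, 9,
                                      9, 1 / 9, 1), 3, 3, byrow = TRUE)),
                 "consistency ratio")
})

test_that("weight vectors sample uniformly on the simplex", {
  W <- sample_weight_vectors(100000, 4, seed = 123)
  expect_true(all(abs(rowSums(W) - 1) < 1e-12))
  expect_true(all(W >= 0))
  expect_true(all(abs(colMeans(W) - 0.25) < 0.005))
  expect_identical(W, sample_weight_vectors(100000, 4, seed = 123))
})

test_that("deterministic schemes select exactly the contract sets", {
  tab <- toy_table()
  # EDSeedBank: the two taxa with n_seed = 0, ED-ordered
  expect_equal(scheme_selection("EDSeedBank", tab, n = 2), c("A", "C"))
  # PIECES/EDGE deterministic and repeatable
  expect_identical(scheme_selection("PIECES", tab, n = 3),
                   scheme_selection("PIECES", tab, n = 3))
  expect_identical(scheme_selection("EDGE", tab, n = 2),
                   scheme_selection("EDGE", tab, n = 2))
  expect_error(scheme_selection("EDSeedBank", tab, n = 3), "fewer than n")
})

test_that("random schemes draw from the correct pools, reproducibly", {
  fx <- flora_fixture(seed = 9, n_tips = 200)
  tab <- fx$table
  r1 <- tab$taxon[tab$rank == "R1"]
  n <- min(10, length(r1) - 1)
  sel <- scheme_selection("Endangered", tab, n = n, n_subsamples = 25, seed = 1)
  expect_length(sel, 25)
  for (s in sel) {
    expect_length(s, n)
    expect_true(all(s %in% r1))
  }
  expect_identical(sel, scheme_selection("Endangered", tab, n = n,
                                         n_subsamples = 25, seed = 1))

  # stratum overflow: n beyond |R1| forces all of R1 plus an R2 remainder
  n2 <- length(r1) + 5
  sel2 <- scheme_selection("Endangered", tab, n = n2, n_subsamples = 5, seed = 2)
  for (s in sel2) {
    expect_true(all(r1 %in% s))
    expect_true(all(s[!s %in% r1] %in% tab$taxon[tab$rank == "R2"]))
  }

  pool <- tab$taxon[tab$n_seed == 0 & tab$n_living == 0]
  sel3 <- scheme_selection("ExSitu", tab, n = 10, n_subsamples = 25, seed = 3)
  for (s in sel3) expect_true(all(s %in% pool))
})

test_that("ROI fields match their definitions on a toy table", {
  tab <- toy_table()
  r <- roi(c("A", "B"), tab)  # A: R1, nothing; B: R2, seed-banked only
  expect_equal(r$new_seed, 1)
  expect_equal(r$new_living, 2)
  expect_equal(r$mean_threat, 3.5)  # (4 + 3) / 2
  expect_equal(r$mean_ed, 4.5)
  # all-uncollected selection
  r2 <- roi("A", tab)
  expect_equal(r2$new_seed, 1)
  expect_equal(r2$new_living, 1)
  expect_equal(r2$mean_threat, 4)  # all-R1
  # family of selections -> mean ROI
  rf <- roi(list(c("A", "B"), c("A", "C")), tab)
  expect_equal(rf$new_seed, mean(c(1, 2)))
  expect_error(roi(c("A", "nope"), tab), "unknown taxon")
})

test_that("weight-space ROI respects bounds and contains extreme optima", {
  fx <- flora_fixture(seed = 15, n_tips = 150)
  n <- 40
  cloud <- weight_space_analysis(fx$table, k = 150, n = n, seed = 16)
  expect_equal(nrow(cloud), 150)
  expect_true(all(cloud$new_seed >= 0 & cloud$new_seed <= n))
  expect_true(all(cloud$new_living >= 0 & cloud$new_living <= n))
  expect_true(all(cloud$mean_threat >= 0 & cloud$mean_threat <= 4))
  expect_true(all(abs(rowSums(cloud[, 1:4]) - 1) < 1e-9))
  # the pure-ED extreme attains the maximum mean ED achievable in the cloud
  ed_opt <- roi(rank_select(pieces_scores(fx$table, c(0, 0, 0, 1)), n), fx$table)
  expect_gte(ed_opt$mean_ed, max(cloud$mean_ed) - 1e-9)
  sb_opt <- roi(rank_select(pieces_scores(fx$table, c(1, 0, 0, 0)), n), fx$table)
  expect_gte(sb_opt$new_seed, max(cloud$new_seed))
})

test_that("pareto_front equals brute-force dominance filtering", {
  pts <- rbind(c(1, 1), c(2, 0), c(0, 2), c(0.5, 0.5))
  expect_equal(pareto_front(pts), pareto_oracle(pts))
  expect_equal(nrow(pareto_front(matrix(c(3, 7), 1))), 1)
  # strictly decreasing curve: every point non-dominated
  curve <- cbind(1:20, 20:1)
  expect_equal(nrow(pareto_front(curve)), 20)
  set.seed(77)
  for (i in 1:25) {
    cloud <- matrix(stats::rnorm(2 * sample(10:400, 1)), ncol = 2)
    expect_equal(pareto_front(cloud), pareto_oracle(cloud))
  }
  # orientation handling: minimizing both flips the frontier
  mn <- pareto_front(pts, orientation = c("min", "min"))
  ref <- -pareto_oracle(-pts)
  expect_equal(mn[order(mn[, 1]), ], ref[order(ref[, 1]), ], ignore_attr = TRUE)
  expect_error(pareto_front(matrix(numeric(0), ncol = 2)), "non-empty")
})

test_that("every weight-space ROI lies weakly inside the cloud's Pareto front", {
  fx <- flora_fixture(seed = 25, n_tips = 120)
  cloud <- weight_space_analysis(fx$table, k = 80, n = 30, seed = 26)
  pairs <- list(c("new_seed", "mean_ed"), c("new_living", "mean_threat"))
  for (pr in pairs) {
    pts <- as.matrix(cloud[, pr])
    front <- pareto_front(pts)
    for (i in seq_len(nrow(pts))) {
      dominated_by_front <- any(front[, 1] >= pts[i, 1] & front[, 2] >= pts[i, 2])
      expect_true(dominated_by_front)
    }
  }
})

test_that("gap table counts partition the pool and chi-squared matches the closed form", {
  tab <- data.frame(
    taxon = paste0("t", 1:40),
    rank = rep(c("R1", "R5"), each = 20),
    n_seed = rep(c(1L, 0L), 20),
    n_living = rep(c(1L, 1L, 0L, 0L), 10),
    stringsAsFactors = FALSE
  )
  g <- gap_table(tab)
  expect_equal(sum(g$counts), 40)
  expect_equal(unname(colSums(g$counts)[c("R1", "R5")]), c(20, 20))
  # perfectly balanced 2x2 design -> independence, X^2 = 0
  expect_equal(g$statistic, 0, tolerance = 1e-12)

  # hand-computed oracle on a known table
  tab2 <- toy_table()[, c("taxon", "rank", "n_seed", "n_living")]
  g2 <- suppressWarnings(gap_table(tab2))  # tiny counts trip the approximation warning
  O <- g2$counts[rowSums(g2$counts) > 0, colSums(g2$counts) > 0, drop = FALSE]
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(g2$statistic, sum((O - E)^2 / E), tolerance = 1e-12)
  expect_gte(g2$statistic, 0)
})

test_that("solution-set comparison is symmetric with unit diagonal", {
  fx <- flora_fixture(seed = 31, n_tips = 100)
  tab <- fx$table
  sels <- list(
    PIECES = scheme_selection("PIECES", tab, n = 25),
    EDGE = scheme_selection("EDGE", tab, n = 25),
    ExSitu = scheme_selection("ExSitu", tab, n = 25, n_subsamples = 10, seed = 5)
  )
  cmp <- compare_solutions(sels, fx$tree, n_draws = 10)
  for (m in cmp) {
    expect_equal(m, t(m))
    expect_equal(unname(diag(m)), rep(1, 3))
    expect_true(all(m >= 0 & m <= 1))
  }
  # identical selections compare at exactly 1
  cmp2 <- compare_solutions(list(a = sels$PIECES, b = sels$PIECES), fx$tree)
  expect_equal(cmp2$jaccard["a", "b"], 1)
  expect_equal(cmp2$phylosor["a", "b"], 1)
})

test_that("clade-restricted selections on a two-clade tree share nothing", {
  tr <- read_newick("((a1:1,a2:1,a3:1):5,(b1:1,b2:1,b3:1):5);")
  cmp <- compare_solutions(list(A = c("a1", "a2"), B = c("b1", "b3")), tr)
  expect_equal(cmp$jaccard["A", "B"], 0)
  expect_equal(cmp$phylosor["A", "B"], 0)
})
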