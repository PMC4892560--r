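# Small fixed trees and tables shared across test files.

balanced4 <- function() read_newick("((A:1,B:1):1,(C:1,D:1):1);")

star3 <- function() read_newick("(A:2,B:2,C:2);")

caterpillar <- function() read_newick("(((A:1,B:1):1,C:2):1,D:3);")

# tiny taxon table with known structure
toy_table <- function() {
  data.frame(
    taxon = c("A", "B", "C", "D", "E"),
    rank = c("R1", "R2", "R3", "R4", "R5"),
    n_seed = c(0L, 3L, 0L, 1L, 10L),
    n_living = c(0L, 0L, 2L, 5L, 20L),
    ed_raw = c(5, 4, 3, 2, 1),
    stringsAsFactors = FALSE
  )
}

# brute-force Pareto oracle: O(k^2) dominance filter, maximizing both axes
pareto_oracle <- function(pts) {
  pts <- unique(as.matrix(pts))
  keep <- vapply(seq_len(nrow(pts)), function(i) {
    dominated <- (pts[, 1] >= pts[i, 1]) & (pts[, 2] >= pts[i, 2]) &
      (pts[, 1] > pts[i, 1] | pts[, 2] > pts[i, 2])
    !any(dominated)
  }, logical(1))
  front <- pts[keep, , drop = FALSE]
  front[order(front[, 1]), , drop = FALSE]
}
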