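# Shared fixture builders for the test suite.

# Island system with all pairwise distances equal (uniform kernel for any
# exponent only when alpha = 0; for alpha > 0 the kernel is uniform because
# the distances are).
uniform_system <- function(n, d = 1) {
  m <- matrix(d, n, n)
  diag(m) <- 0
  labs <- paste0("I", seq_len(n))
  dimnames(m) <- list(labs, labs)
  island_system(m)
}

# Naive patristic oracle: sum edge lengths along the node path between each
# pair of tips (independent of the cophenetic code path).
naive_patristic <- function(tree) {
  n <- length(tree$tip.label)
  elen <- tree$edge.length
  key <- paste(tree$edge[, 1], tree$edge[, 2])
  m <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    np <- ape::nodepath(tree, i, j)
    steps <- cbind(np[-length(np)], np[-1])
    # edges can be traversed in either direction along the path
    idx <- match(paste(steps[, 1], steps[, 2]), key)
    rev_idx <- match(paste(steps[, 2], steps[, 1]), key)
    idx[is.na(idx)] <- rev_idx[is.na(idx)]
    m[i, j] <- m[j, i] <- sum(elen[idx])
  }
  m
}

table3_matrix <- function() {
  trait_difference_matrix(load_fixture("table3_skulls"))
}

table3_pairs <- function() {
  p <- load_fixture("sympatric_pairs")
  sympatry_assignment(p[, c("terminal_a", "terminal_b")])
}
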