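#' Patristic distance matrix from a phylogeny
#'
#' Pairwise patristic distances: the sum of branch lengths along the path
#' connecting each pair of terminals.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @return A symmetric numeric matrix with tip labels as dimnames and zero
#'   diagonal.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' patristic_matrix(tr)
#' @export
patristic_matrix <- function(tree) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a \"phylo\" object")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree is missing branch lengths")
  if (any(tree$edge.length < 0))
    stop("negative branch lengths are not allowed")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels")
  if (length(tree$tip.label) < 2L)
    stop("at least two terminals required")
  m <- stats::cophenetic(tree)
  m[tree$tip.label, tree$tip.label]
}

#' Absolute pairwise trait-difference matrix
#'
#' @param traits a trait table: data frame with columns `terminal` and a
#'   trait mean column (`mean_mm` or `mean`), or a named numeric vector of
#'   per-terminal means.
#' @return Symmetric matrix of absolute differences between terminal means.
#' @examples
#' trait_difference_matrix(c(a = 1, b = 3, c = 6))
#' @export
trait_difference_matrix <- function(traits) {
  x <- trait_means(traits)
  if (length(x) < 2L) stop("at least two terminals required")
  abs(outer(x, x, "-"))
}

# Normalize the accepted trait-table representations to a named vector.
trait_means <- function(traits) {
  if (is.numeric(traits)) {
    if (is.null(names(traits))) stop("trait vector must be named")
    x <- traits
  } else {
    traits <- as.data.frame(traits)
    if (!"terminal" %in% names(traits))
      stop("trait table must have a 'terminal' column")
    mcol <- intersect(c("mean_mm", "mean"), names(traits))[1]
    if (is.na(mcol)) stop("trait table must have a 'mean_mm' or 'mean' column")
    x <- stats::setNames(traits[[mcol]], traits$terminal)
  }
  if (anyDuplicated(names(x))) stop("duplicate terminal names")
  if (anyNA(x) || any(!is.finite(x))) stop("trait means must be finite")
  x
}

#' Declare sympatric terminal pairs
#'
#' A sympatry assignment is a set of disjoint unordered terminal pairs --
#' empirically, the species pairs that co-occur on the same island unit.
#' It is the object randomized by the permutation null.
#'
#' @param pairs a two-column matrix/data frame of terminal names, or a list
#'   of length-2 character vectors.
#' @param labels optional character vector of valid terminal names; if
#'   given, every pair member must belong to it.
#' @return A two-column character matrix of class `"sympatry_assignment"`.
#' @export
sympatry_assignment <- function(pairs, labels = NULL) {
  if (is.list(pairs) && !is.data.frame(pairs))
    pairs <- do.call(rbind, pairs)
  pairs <- as.matrix(pairs)
  if (ncol(pairs) < 2L) stop("pairs must have two columns")
  pairs <- matrix(as.character(pairs[, 1:2]), ncol = 2)
  if (nrow(pairs) < 1L) stop("at least one pair required")
  members <- as.vector(pairs)
  if (anyDuplicated(members))
    stop("pairs must be disjoint: a terminal appears more than once")
  if (!is.null(labels)) {
    unknown <- setdiff(members, labels)
    if (length(unknown))
      stop("pair member(s) not among terminals: ",
           paste(unknown, collapse = ", "))
  }
  structure(pairs, class = c("sympatry_assignment", "matrix"))
}

#' Dispersion statistic: sympatric minus allopatric aggregate
#'
#' The community-dispersion statistic: an aggregator (mean or median) of the
#' pairwise distances between sympatric pairs minus the same aggregator over
#' all remaining (allopatric) unordered pairs. Applied to a patristic matrix
#' it measures phylogenetic dispersion; applied to a trait-difference matrix,
#' trait (e.g. body-size) dispersion. Positive values indicate
#' overdispersion: co-occurring terminals are more distant or more different
#' than the average non-co-occurring pair.
#'
#' @param matrix a symmetric pair-distance matrix with terminal dimnames
#'   (from [patristic_matrix()] or [trait_difference_matrix()]).
#' @param sympatry a [sympatry_assignment()] (or coercible pairs).
#' @param aggregator `"mean"` or `"median"`.
#' @return The scalar statistic.
#' @export
delta_stat <- function(matrix, sympatry, aggregator = c("mean", "median")) {
  aggregator <- match.arg(aggregator)
  agg <- if (aggregator == "mean") mean else stats::median
  labs <- rownames(matrix)
  if (is.null(labs)) stop("'matrix' must have terminal dimnames")
  if (!inherits(sympatry, "sympatry_assignment"))
    sympatry <- sympatry_assignment(sympatry, labs)
  ia <- match(sympatry[, 1], labs)
  ib <- match(sympatry[, 2], labs)
  if (anyNA(ia) || anyNA(ib))
    stop("sympatric pair member(s) not among matrix terminals")
  ut <- upper.tri(matrix)
  all_vals <- matrix[ut]
  # locate each sympatric pair within the upper triangle
  ridx <- pmin(ia, ib); cidx <- pmax(ia, ib)
  ut_rows <- row(matrix)[ut]; ut_cols <- col(matrix)[ut]
  sym_idx <- match(paste(ridx, cidx), paste(ut_rows, ut_cols))
  sym_vals <- all_vals[sym_idx]
  allo_vals <- all_vals[-sym_idx]
  if (length(allo_vals) == 0L)
    stop("sympatry covers all pairs: no allopatric set to compare against")
  agg(sym_vals) - agg(allo_vals)
}

#' Draw a uniform random sympatry assignment
#'
#' Draws `k` disjoint unordered pairs uniformly at random from the set of
#' all such configurations (a uniform random permutation of the labels,
#' paired off consecutively, gives every configuration equal probability).
#' Uses the current RNG state.
#'
#' @param labels character vector of terminal names.
#' @param k number of pairs, `2 * k <= length(labels)`.
#' @return A [sympatry_assignment()].
#' @export
sample_sympatry <- function(labels, k) {
  k <- as.integer(k)
  if (k < 1L) stop("'k' must be >= 1")
  if (2L * k > length(labels))
    stop("2 * k exceeds the number of terminals")
  perm <- sample(labels)
  sympatry_assignment(matrix(perm[seq_len(2L * k)], ncol = 2, byrow = TRUE))
}

#' Permutation test for overdispersion of sympatric pairs
#'
#' Builds a null distribution of the dispersion statistic by redrawing the
#' sympatry assignment uniformly at random (same number of disjoint pairs)
#' and recomputing [delta_stat()] each time, then reports the one-tailed
#' P-value: the proportion of null values greater than or equal to the
#' observed statistic. The observed assignment is not included in the null;
#' the `(r + 1) / (n + 1)`-corrected P-value is also reported for
#' conservatism.
#'
#' @inheritParams delta_stat
#' @param replicates number of random assignments (conventional: 2000).
#' @param seed optional integer seed.
#' @return An object of class `"dispersion_test"` with elements `observed`,
#'   `null_values`, `p` (plain upper-tail proportion), `p_corrected`,
#'   `aggregator`, `replicates`, `seed`.
#' @examples
#' skulls <- load_fixture("table3_skulls")
#' pairs <- load_fixture("sympatric_pairs")
#' m <- trait_difference_matrix(skulls)
#' permutation_test(m, pairs[, 1:2], replicates = 200, seed = 1)
#' @export
permutation_test <- function(matrix, sympatry,
                             replicates = 2000,
                             aggregator = c("mean", "median"),
                             seed = NULL) {
  aggregator <- match.arg(aggregator)
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L) stop("'replicates' must be >= 1")
  labs <- rownames(matrix)
  if (!inherits(sympatry, "sympatry_assignment"))
    sympatry <- sympatry_assignment(sympatry, labs)
  observed <- delta_stat(matrix, sympatry, aggregator)
  k <- nrow(sympatry)
  if (!is.null(seed)) set.seed(seed)
  null_values <- vapply(seq_len(replicates), function(i) {
    delta_stat(matrix, sample_sympatry(labs, k), aggregator)
  }, numeric(1))
  r <- sum(null_values >= observed)
  structure(list(observed = observed, null_values = null_values,
                 p = r / replicates,
                 p_corrected = (r + 1) / (replicates + 1),
                 aggregator = aggregator, replicates = replicates,
                 seed = seed, k = k),
            class = "dispersion_test")
}

#' @export
print.dispersion_test <- function(x, ...) {
  cat(sprintf(
    "Dispersion permutation test (%s aggregator, %d sympatric pairs)\n",
    x$aggregator, x$k))
  cat(sprintf("  observed = %.4f; one-tailed P = %.4g (corrected %.4g) from %d randomizations\n",
              x$observed, x$p, x$p_corrected, x$replicates))
  invisible(x)
}

# Number of ways to choose k disjoint unordered pairs from n labels.
n_pair_configurations <- function(n, k) {
  choose(n, 2 * k) * factorial(2 * k) / (2^k * factorial(k))
}

#' Exact enumeration test for the dispersion statistic
#'
#' Enumerates every configuration of `k` disjoint unordered pairs over the
#' matrix terminals, computes the dispersion statistic for each, and returns
#' the exact proportion at least as large as `observed`. The oracle against
#' which the Monte-Carlo permutation test converges.
#'
#' @inheritParams delta_stat
#' @param k number of sympatric pairs in each configuration.
#' @param observed the observed statistic to place in the exact null.
#' @param cap refuse to enumerate more than this many configurations
#'   (default `1e6`).
#' @return List with `p` (exact upper-tail proportion), `n_configurations`,
#'   and `values` (the full exact null distribution).
#' @export
exact_test <- function(matrix, k, observed,
                       aggregator = c("mean", "median"), cap = 1e6) {
  aggregator <- match.arg(aggregator)
  labs <- rownames(matrix)
  if (is.null(labs)) stop("'matrix' must have terminal dimnames")
  n <- length(labs)
  k <- as.integer(k)
  if (2L * k > n) stop("2 * k exceeds the number of terminals")
  total <- n_pair_configurations(n, k)
  if (total > cap)
    stop(sprintf(
      "enumeration of %.3g configurations exceeds cap %.3g; use the Monte-Carlo permutation_test instead",
      total, cap))
  vals <- numeric(total)
  cnt <- 0L
  recurse <- function(avail, pairs) {
    if (nrow(pairs) == k) {
      cnt <<- cnt + 1L
      vals[cnt] <<- delta_stat(matrix,
                               sympatry_assignment(pairs), aggregator)
      return(invisible())
    }
    # configurations containing avail[1] paired with each later label ...
    a <- avail[1]
    for (b in avail[-1])
      recurse(setdiff(avail, c(a, b)), rbind(pairs, c(a, b)))
    # ... and, if enough labels remain, configurations omitting avail[1]
    if (length(avail) - 1L >= 2L * (k - nrow(pairs)))
      recurse(avail[-1], pairs)
    invisible()
  }
  recurse(labs, base::matrix(character(), 0, 2))
  stopifnot(cnt == total)
  list(p = mean(vals >= observed), n_configurations = as.integer(total),
       values = vals)
}
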