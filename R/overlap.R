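#' Construct a suitability grid
#'
#' A rectangular raster of nonnegative suitability values with a validity
#' mask delimiting the analysis region. Grid coordinates are row-major from
#' the top-left corner; occurrence coordinates `(x, y)` are 0-based cell
#' units, so the value at a point is `values[y + 1, x + 1]`.
#'
#' @param values numeric matrix of suitabilities (rows top to bottom).
#' @param mask logical matrix of the same shape: `TRUE` marks cells inside
#'   the analysis region. Defaults to all non-`NA` cells of `values`.
#' @param xllcorner,yllcorner,cellsize,nodata_value georeferencing metadata
#'   carried through I/O (not used by the metrics).
#' @param normalized set to `TRUE` only if `values` already sum to one over
#'   the valid cells.
#' @return An object of class `"suitability_grid"`.
#' @export
suitability_grid <- function(values, mask = NULL, xllcorner = 0,
                             yllcorner = 0, cellsize = 1,
                             nodata_value = -9999, normalized = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(mask)) mask <- !is.na(values)
  if (!is.logical(mask) || !identical(dim(mask), dim(values)))
    stop("'mask' must be a logical matrix matching 'values'")
  v <- values[mask]
  if (anyNA(v)) stop("valid cells must not be NA")
  if (any(v < 0)) stop("suitability values must be nonnegative")
  if (normalized && abs(sum(v) - 1) > 1e-9)
    stop("'normalized' is TRUE but valid cells do not sum to 1")
  structure(list(values = values, mask = mask, xllcorner = xllcorner,
                 yllcorner = yllcorner, cellsize = cellsize,
                 nodata_value = nodata_value, normalized = normalized),
            class = "suitability_grid")
}

#' @export
print.suitability_grid <- function(x, ...) {
  cat(sprintf("Suitability grid: %d x %d cells, %d valid%s\n",
              nrow(x$values), ncol(x$values), sum(x$mask),
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

.check_same_mask <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)) ||
      !identical(a$mask, b$mask))
    stop("grids must share identical dimensions and masks")
}

#' Normalize a suitability grid to a probability distribution
#'
#' Divides the values by their sum over valid cells, the prerequisite for
#' the overlap metrics, which are defined on probability distributions over
#' the shared analysis region. Idempotent.
#'
#' @param grid a [suitability_grid()].
#' @return The normalized grid (`normalized = TRUE`).
#' @export
normalize_grid <- function(grid) {
  stopifnot(inherits(grid, "suitability_grid"))
  s <- sum(grid$values[grid$mask])
  if (s <= 0) stop("cannot normalize: all valid cells are zero")
  grid$values[grid$mask] <- grid$values[grid$mask] / s
  grid$values[!grid$mask] <- NA_real_
  grid$normalized <- TRUE
  grid
}

# Suitability values at occurrence points (0-based cell coordinates).
.values_at <- function(grid, points) {
  points <- as.data.frame(points)
  if (!all(c("x", "y") %in% names(points)))
    stop("occurrence points must have columns 'x' and 'y'")
  row <- as.integer(points$y) + 1L
  col <- as.integer(points$x) + 1L
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  if (any(row < 1L | row > nr | col < 1L | col > nc))
    stop("occurrence point outside the grid")
  idx <- cbind(row, col)
  if (any(!grid$mask[idx]))
    stop("occurrence point on an invalid (masked) cell")
  grid$values[idx]
}

#' Minimum-training-presence threshold
#'
#' Converts a continuous suitability map to presence/absence using the
#' lowest suitability observed at any training occurrence as the cutoff:
#' cells at or above that value become 1, all other valid cells 0.
#'
#' @param grid a [suitability_grid()].
#' @param training occurrence points (data frame with 0-based cell
#'   coordinates `x`, `y`) falling on valid cells.
#' @return A binary [suitability_grid()] (not normalized), with the cutoff
#'   attached as attribute `"threshold"`.
#' @export
min_presence_threshold <- function(grid, training) {
  stopifnot(inherits(grid, "suitability_grid"))
  training <- as.data.frame(training)
  if (nrow(training) == 0L) stop("training occurrence set is empty")
  thr <- min(.values_at(grid, training))
  out <- grid
  out$values[grid$mask] <- as.numeric(grid$values[grid$mask] >= thr)
  out$values[!grid$mask] <- NA_real_
  out$normalized <- FALSE
  attr(out, "threshold") <- thr
  out
}

#' Schoener's D niche-overlap metric
#'
#' `D = 1 - 0.5 * sum(|a_i - b_i|)` over the shared valid cells of two
#' normalized suitability grids; 1 for identical distributions, 0 for
#' disjoint supports.
#'
#' @param a,b normalized [suitability_grid()]s with identical masks.
#' @return Overlap in `[0, 1]`.
#' @export
schoener_d <- function(a, b) {
  stopifnot(inherits(a, "suitability_grid"), inherits(b, "suitability_grid"))
  if (!a$normalized || !b$normalized)
    stop("both grids must be normalized (see normalize_grid)")
  .check_same_mask(a, b)
  1 - 0.5 * sum(abs(a$values[a$mask] - b$values[b$mask]))
}

#' Hellinger-based I niche-overlap metric
#'
#' `I = 1 - 0.5 * sum((sqrt(a_i) - sqrt(b_i))^2)`, i.e. one minus half the
#' squared Hellinger distance between the two normalized distributions.
#' Always at least as large as Schoener's D on the same pair of grids.
#'
#' @inheritParams schoener_d
#' @return Overlap in `[0, 1]`.
#' @export
hellinger_i <- function(a, b) {
  stopifnot(inherits(a, "suitability_grid"), inherits(b, "suitability_grid"))
  if (!a$normalized || !b$normalized)
    stop("both grids must be normalized (see normalize_grid)")
  .check_same_mask(a, b)
  1 - 0.5 * sum((sqrt(a$values[a$mask]) - sqrt(b$values[b$mask]))^2)
}

#' Climate-envelope niche-model fitter
#'
#' The default model-fitting contract for [background_similarity()]: for
#' each covariate, suitability follows a triangular kernel spanning the
#' min-max range of the covariate values at the training occurrences:
#' 1 at the range midpoint, declining linearly to 0.5 at the range limits,
#' and 0 outside the range. The floor of 0.5 at the limits keeps every
#' training point strictly inside its own envelope, so the
#' minimum-training-presence threshold is informative rather than zero.
#' Per-covariate kernels are multiplied. Deliberately simple -- it
#' exercises the full randomization machinery at desk scale, while real
#' analyses plug in their own fitter.
#'
#' @return A fitter: `function(points, covariates)` taking training
#'   occurrences and a list of covariate [suitability_grid()]s (identical
#'   masks) and returning a suitability grid over the full analysis region.
#' @export
envelope_fitter <- function() {
  function(points, covariates) {
    stopifnot(length(covariates) >= 1L)
    base <- covariates[[1]]
    out <- rep(1, sum(base$mask))
    for (cov in covariates) {
      .check_same_mask(base, cov)
      tv <- .values_at(cov, points)
      lo <- min(tv); hi <- max(tv)
      v <- cov$values[cov$mask]
      if (hi > lo) {
        mid <- (lo + hi) / 2
        half <- (hi - lo) / 2
        k <- ifelse(v >= lo & v <= hi, 1 - 0.5 * abs(v - mid) / half, 0)
      } else {
        k <- as.numeric(v == lo)
      }
      out <- out * k
    }
    g <- base
    g$values[base$mask] <- out
    g$values[!base$mask] <- NA_real_
    g$normalized <- FALSE
    g
  }
}

#' Background-similarity randomization test for niche overlap
#'
#' Tests whether the observed niche overlap between two species differs
#' from the overlap expected when one species' occurrences are replaced by
#' random points drawn from the region accessible to it (its "M"). Each
#' replicate draws `n_points` cells uniformly from the valid cells of
#' `m_mask`, fits the pluggable niche model to those points, projects it
#' over the full analysis region, applies the minimum-training-presence
#' threshold of the random points, normalizes, and computes Schoener's D
#' and Hellinger's I against the fixed empirical grid of the *other*
#' species. The observed values are then placed in the two null
#' distributions.
#'
#' Replicates on which the fitter fails (or yields an all-zero map) are
#' excluded from the P-value denominators and counted in `failed`.
#'
#' @param empirical_other normalized [suitability_grid()] of the species
#'   that is *not* randomized (typically thresholded then normalized).
#' @param observed_d,observed_i the observed overlap values to test.
#' @param n_points number of random occurrence points per replicate (the
#'   empirical sample size of the randomized species).
#' @param m_mask a [suitability_grid()] or logical matrix whose valid cells
#'   define the accessible region M of the randomized species.
#' @param covariates list of covariate grids passed to the fitter; masks
#'   must match `empirical_other`.
#' @param fitter a `function(points, covariates)` returning a suitability
#'   grid over the full region (default [envelope_fitter()]).
#' @param replicates number of randomizations (conventional: 999).
#' @param seed optional integer seed.
#' @return An object of class `"overlap_test"`: observed values, null
#'   distributions `null_d` / `null_i`, upper-tail fractions `p_upper_d` /
#'   `p_upper_i` (proportion of null at or above the observed; small when
#'   the species are more similar than random), lower-tail fractions
#'   `p_lower_d` / `p_lower_i`, `replicates`, `failed`, `seed`.
#' @export
background_similarity <- function(empirical_other, observed_d, observed_i,
                                  n_points, m_mask, covariates,
                                  fitter = envelope_fitter(),
                                  replicates = 999, seed = NULL) {
  stopifnot(inherits(empirical_other, "suitability_grid"))
  if (!empirical_other$normalized)
    stop("'empirical_other' must be normalized")
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L) stop("'replicates' must be >= 1")
  mmat <- if (inherits(m_mask, "suitability_grid")) m_mask$mask else m_mask
  if (!is.logical(mmat)) stop("'m_mask' must be logical or a suitability_grid")
  cells <- which(mmat, arr.ind = TRUE)
  if (nrow(cells) == 0L) stop("'m_mask' has no valid cells")
  if (!is.null(seed)) set.seed(seed)
  null_d <- null_i <- rep(NA_real_, replicates)
  failed <- 0L
  for (r in seq_len(replicates)) {
    idx <- if (n_points <= nrow(cells)) {
      sample.int(nrow(cells), n_points)
    } else {
      sample.int(nrow(cells), n_points, replace = TRUE)
    }
    pts <- data.frame(x = cells[idx, "col"] - 1L, y = cells[idx, "row"] - 1L)
    fit <- tryCatch({
      g <- fitter(pts, covariates)
      g <- min_presence_threshold(g, pts)
      normalize_grid(g)
    }, error = function(e) NULL)
    if (is.null(fit)) { failed <- failed + 1L; next }
    null_d[r] <- schoener_d(fit, empirical_other)
    null_i[r] <- hellinger_i(fit, empirical_other)
  }
  ok_d <- null_d[!is.na(null_d)]
  ok_i <- null_i[!is.na(null_i)]
  if (length(ok_d) == 0L) stop("all replicates failed in the fitter")
  structure(list(observed_d = observed_d, observed_i = observed_i,
                 null_d = ok_d, null_i = ok_i,
                 p_upper_d = mean(ok_d >= observed_d),
                 p_upper_i = mean(ok_i >= observed_i),
                 p_lower_d = mean(ok_d <= observed_d),
                 p_lower_i = mean(ok_i <= observed_i),
                 replicates = replicates, failed = failed, seed = seed),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf("Background similarity test (%d randomizations, %d failed)\n",
              x$replicates, x$failed))
  cat(sprintf("  D: observed %.4f, null >= observed in %.3f, <= in %.3f\n",
              x$observed_d, x$p_upper_d, x$p_lower_d))
  cat(sprintf("  I: observed %.4f, null >= observed in %.3f, <= in %.3f\n",
              x$observed_i, x$p_upper_i, x$p_lower_i))
  invisible(x)
}
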