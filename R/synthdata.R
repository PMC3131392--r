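#' Simulate a Yule (pure-birth) tree
#'
#' Generates an ultrametric tree under a constant-rate pure-birth process
#' conditioned on the number of tips. By default the tree is rescaled to
#' unit root-to-tip depth (divergence-time analyses of the kind these tools
#' accompany typically work on an arbitrary time scale).
#'
#' @param n number of tips (`>= 2`).
#' @param birth_rate speciation rate per lineage per unit time.
#' @param seed optional integer seed.
#' @param scale_depth if `TRUE` (default) rescale branch lengths so the
#'   root-to-tip depth is exactly 1.
#' @return An ultrametric [ape::phylo] tree with tip labels `t1..tn`.
#' @export
yule_tree <- function(n, birth_rate = 1, seed = NULL, scale_depth = TRUE) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("'n' must be an integer >= 2")
  if (birth_rate <= 0) stop("'birth_rate' must be positive")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n, birth = birth_rate, death = 0)
  if (scale_depth) {
    depth <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length / depth
  }
  tree
}

#' Simulate Brownian-motion traits with tunable phylogenetic signal
#'
#' Draws tip trait values from the multivariate normal implied by Brownian
#' motion on the tree with a lambda-transformed covariance: off-diagonal
#' entries (shared path lengths) are multiplied by `lambda`, diagonal
#' entries (tip depths) are left untouched. `lambda = 1` is plain Brownian
#' motion; `lambda = 0` gives independent tips with variance
#' `sigma2 * depth`.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param sigma2 Brownian rate (trait variance per unit branch length).
#' @param lambda signal parameter in `[0, 1]`.
#' @param root trait value at the root (the mean of every tip).
#' @param seed optional integer seed.
#' @return A named numeric vector of tip trait values.
#' @export
bm_traits <- function(tree, sigma2 = 1, lambda = 1, root = 0, seed = NULL) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a \"phylo\" object")
  if (is.null(tree$edge.length)) stop("tree is missing branch lengths")
  if (sigma2 <= 0) stop("'sigma2' must be positive")
  if (lambda < 0 || lambda > 1) stop("'lambda' must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  C <- ape::vcv(tree)
  V <- lambda * C
  diag(V) <- diag(C)
  L <- chol(sigma2 * V)
  z <- stats::rnorm(nrow(V))
  stats::setNames(root + as.vector(t(L) %*% z), rownames(V))
}

#' Generate a synthetic island system
#'
#' Places islands by a simple geometry and derives the inter-island
#' distance matrix from pairwise Euclidean separations.
#'
#' @param count number of islands (`>= 2`).
#' @param geometry `"line"` (evenly spaced on a line), `"ring"` (regular
#'   polygon; the distance matrix is circulant), or `"random-planar"`
#'   (uniform points in a square).
#' @param scale spacing in km: inter-neighbour spacing for `"line"`, circle
#'   radius for `"ring"`, side length for `"random-planar"`.
#' @param seed optional integer seed (used by `"random-planar"`).
#' @param spacings optional numeric vector of `count - 1` successive gaps
#'   overriding the even spacing of `"line"` (for heterogeneous-distance
#'   fixtures).
#' @return An [island_system()] with islands named `I1..In`.
#' @export
random_island_system <- function(count, geometry = c("line", "ring",
                                                     "random-planar"),
                                 scale = 1, seed = NULL, spacings = NULL) {
  geometry <- match.arg(geometry)
  count <- as.integer(count)
  if (is.na(count) || count < 2L) stop("'count' must be an integer >= 2")
  if (!is.null(seed)) set.seed(seed)
  xy <- switch(geometry,
    "line" = {
      gaps <- if (is.null(spacings)) rep(scale, count - 1L) else spacings
      if (length(gaps) != count - 1L)
        stop("'spacings' must have length count - 1")
      cbind(c(0, cumsum(gaps)), 0)
    },
    "ring" = {
      th <- 2 * pi * (seq_len(count) - 1L) / count
      scale * cbind(cos(th), sin(th))
    },
    "random-planar" = {
      for (try in 1:100) {
        p <- matrix(stats::runif(2L * count, 0, scale), ncol = 2)
        if (min(stats::dist(p)) > scale * 1e-6) break
        p <- NULL
      }
      if (is.null(p)) stop("failed to place distinct islands in 100 tries")
      p
    })
  d <- as.matrix(stats::dist(xy))
  dimnames(d) <- list(paste0("I", seq_len(count)),
                      paste0("I", seq_len(count)))
  island_system(d)
}

#' Generate a smooth synthetic landscape with species responses
#'
#' Builds smooth covariate surfaces (a random-direction linear gradient
#' plus a random-phase sinusoid, rescaled to `[0, 1]`) standing in for
#' climate layers, and defines each species' true suitability as the
#' product of Gaussian responses to the covariates.
#'
#' @param ncols,nrows grid dimensions.
#' @param n_covariates number of covariate surfaces.
#' @param optima numeric matrix (`n_species` x `n_covariates`) of response
#'   optima in `[0, 1]`; defaults to uniform random draws for 2 species.
#' @param width Gaussian response width (sd) on the covariate scale.
#' @param n_species number of species (used only when `optima` is NULL).
#' @param seed optional integer seed.
#' @return A list with `covariates` (list of [suitability_grid()]s),
#'   `suitability` (list of per-species true-suitability grids), and
#'   `optima` (the response matrix used).
#' @export
synthetic_landscape <- function(ncols, nrows, n_covariates = 2,
                                optima = NULL, width = 0.15,
                                n_species = 2, seed = NULL) {
  if (ncols < 1 || nrows < 1) stop("grid dimensions must be positive")
  if (!is.null(seed)) set.seed(seed)
  xs <- (seq_len(ncols) - 0.5) / ncols
  ys <- (seq_len(nrows) - 0.5) / nrows
  X <- base::matrix(rep(xs, each = nrows), nrows, ncols)
  Y <- base::matrix(rep(ys, times = ncols), nrows, ncols)
  covariates <- vector("list", n_covariates)
  for (j in seq_len(n_covariates)) {
    th <- stats::runif(1, 0, 2 * pi)
    ph <- stats::runif(1, 0, 2 * pi)
    freq <- stats::runif(1, 1, 3)
    v <- cos(th) * X + sin(th) * Y +
      0.35 * sin(2 * pi * freq * (sin(th) * X - cos(th) * Y) + ph)
    v <- (v - min(v)) / (max(v) - min(v))
    covariates[[j]] <- suitability_grid(v)
  }
  if (is.null(optima))
    optima <- base::matrix(stats::runif(n_species * n_covariates),
                           n_species, n_covariates)
  optima <- as.matrix(optima)
  if (ncol(optima) != n_covariates)
    stop("'optima' must have one column per covariate")
  suitability <- vector("list", nrow(optima))
  for (s in seq_len(nrow(optima))) {
    g <- base::matrix(1, nrows, ncols)
    for (j in seq_len(n_covariates))
      g <- g * exp(-((covariates[[j]]$values - optima[s, j])^2) /
                     (2 * width^2))
    suitability[[s]] <- suitability_grid(g)
  }
  list(covariates = covariates, suitability = suitability, optima = optima)
}

#' Sample occurrence points proportional to suitability
#'
#' Draws `n` cells (with replacement) with probability proportional to the
#' suitability value of each valid cell and returns points at cell centers
#' in 0-based cell coordinates (`x` = column, `y` = row from the top).
#'
#' @param grid a [suitability_grid()], nonnegative and not all zero.
#' @param n number of points.
#' @param seed optional integer seed.
#' @return A data frame with columns `x`, `y`.
#' @export
sample_occurrences <- function(grid, n, seed = NULL) {
  stopifnot(inherits(grid, "suitability_grid"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be >= 1")
  v <- grid$values[grid$mask]
  if (sum(v) <= 0) stop("all valid cells are zero: cannot sample occurrences")
  cells <- which(grid$mask, arr.ind = TRUE)
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(nrow(cells), n, replace = TRUE, prob = v)
  data.frame(x = cells[idx, "col"] - 1L, y = cells[idx, "row"] - 1L)
}

#' Load a packaged data fixture
#'
#' The package ships, as plain CSV, the occupancy and skull-length tables
#' of the Philippine *Crocidura* radiation that the analyses were designed
#' around, plus its three sympatric species pairs and a clearly synthetic
#' example distance matrix (the real inter-shore distances were never
#' published).
#'
#' @param name one of `"table1_occupancy"` (species x island occupancy with
#'   areas and Pleistocene island-complex membership), `"table3_skulls"`
#'   (12 per-population mean condylo-incisive lengths in mm, with SE and
#'   N), `"sympatric_pairs"` (the three sympatric species pairs), or
#'   `"synthetic_paic_distances"` (an invented 6-unit distance matrix for
#'   examples only).
#' @return A data frame (`"synthetic_paic_distances"`: a numeric matrix).
#' @examples
#' load_fixture("table3_skulls")
#' @export
load_fixture <- function(name) {
  files <- c(table1_occupancy = "table1_occupancy.csv",
             table3_skulls = "table3_skulls.csv",
             sympatric_pairs = "sympatric_pairs.csv",
             synthetic_paic_distances = "synthetic_paic_distances_km.csv")
  if (!name %in% names(files))
    stop("unknown fixture '", name, "'; available: ",
         paste(names(files), collapse = ", "))
  path <- system.file("extdata", files[[name]], package = "islandassembly",
                      mustWork = TRUE)
  if (name == "synthetic_paic_distances") {
    d <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
    storage.mode(d) <- "double"
    return(d)
  }
  utils::read.csv(path, check.names = FALSE)
}

#' Occupancy records of the packaged shrew fixture at a chosen scope
#'
#' Derives the (species, island-unit) population records used by
#' [min_colonization_events()] from the packaged occupancy table, treating
#' island groups that were united during Pleistocene sea-level low-stands
#' (PAICs) as single units.
#'
#' At both scopes the two species confined to *separate* modern islands of
#' the Negros-Panay complex are counted as a single population: one
#' colonization of the complex followed by within-complex divergence during
#' high sea-level isolation explains both without a second over-water
#' event. The three genuinely sympatric pairs (Palawan, Mindanao, Mindoro)
#' each count as two populations.
#'
#' @param scope `"archipelago"`: every PAIC and oceanic island with a
#'   record, giving 11 populations over 8 units (minimum 10 colonization
#'   events). `"paic"`: PAIC units only, giving 8 populations (minimum 7).
#' @return Data frame with columns `species` and `island` (the unit label).
#' @export
fixture_occupancy <- function(scope = c("archipelago", "paic")) {
  scope <- match.arg(scope)
  occ <- load_fixture("table1_occupancy")
  unit <- ifelse(is.na(occ$paic) | occ$paic == "", occ$island, occ$paic)
  rec <- unique(data.frame(species = occ$species, island = unit,
                           stringsAsFactors = FALSE))
  if (scope == "paic") {
    paics <- stats::na.omit(unique(occ$paic[occ$paic != ""]))
    rec <- rec[rec$island %in% paics, ]
  }
  # single colonization explains both Negros-Panay endemics (see docs)
  np <- rec$island == "Negros-Panay"
  if (sum(np) > 1L) {
    rec$species[np] <- paste(sort(rec$species[np]), collapse = "+")
    rec <- unique(rec)
  }
  rownames(rec) <- NULL
  rec
}
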