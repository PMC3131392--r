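#' Construct an island system
#'
#' An island system is the geographic substrate of the colonization analyses:
#' a set of named island units (modern oceanic islands and/or Pleistocene
#' aggregate island complexes treated as single units), a symmetric matrix of
#' minimum inter-shore distances, optional island areas, and optional species
#' occupancy records.
#'
#' @param distance square numeric matrix of minimum inter-shore distances in
#'   km, with island names as row and column names. Must be symmetric (within
#'   `tol`; it is then exactly symmetrized), have a zero diagonal and strictly
#'   positive off-diagonal entries.
#' @param area optional named numeric vector of island areas in km^2.
#' @param occupancy optional data frame with columns `species` and `island`
#'   recording which species occur on which island unit. Every island named
#'   here must be a row of `distance`; duplicate (species, island) records
#'   are an error.
#' @param tol numeric tolerance for the symmetry check (default `1e-9`).
#'
#' @return An object of class `"island_system"`: a list with elements
#'   `islands` (character), `distance` (symmetrized matrix), `area`
#'   (named numeric or `NULL`) and `occupancy` (data frame or `NULL`).
#'
#' @examples
#' d <- matrix(c(0, 10, 20, 10, 0, 15, 20, 15, 0), 3, 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' sys <- island_system(d, occupancy = data.frame(
#'   species = c("sp1", "sp1"), island = c("A", "B")))
#' sys$islands
#' @export
island_system <- function(distance, area = NULL, occupancy = NULL, tol = 1e-9) {
  if (!is.matrix(distance) || !is.numeric(distance))
    stop("'distance' must be a numeric matrix")
  if (nrow(distance) != ncol(distance))
    stop("'distance' must be square")
  labs <- rownames(distance)
  if (is.null(labs) || is.null(colnames(distance)))
    stop("'distance' must have island names as dimnames")
  if (!identical(labs, colnames(distance)))
    stop("row and column names of 'distance' disagree")
  if (anyDuplicated(labs))
    stop("duplicate island names in 'distance'")
  if (anyNA(distance))
    stop("'distance' contains missing values")
  if (any(distance < 0)) {
    bad <- which(distance < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative distance at (%s, %s)",
                 labs[bad[1]], labs[bad[2]]))
  }
  asym <- abs(distance - t(distance))
  if (any(asym > tol)) {
    bad <- which(asym > tol, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "distance matrix asymmetric beyond tolerance at (%s, %s): %g vs %g",
      labs[bad[1]], labs[bad[2]],
      distance[bad[1], bad[2]], distance[bad[2], bad[1]]))
  }
  distance <- (distance + t(distance)) / 2
  if (any(diag(distance) != 0))
    stop("diagonal of 'distance' must be exactly zero")
  off <- distance[row(distance) != col(distance)]
  if (length(off) && any(off <= 0))
    stop("off-diagonal distances must be strictly positive")

  if (!is.null(area)) {
    area <- area[labs]
    storage.mode(area) <- "double"
    if (anyNA(area))
      stop("'area' must provide a value for every island")
  }
  if (!is.null(occupancy)) {
    occupancy <- validate_occupancy(occupancy, labs)
  }
  structure(list(islands = labs, distance = distance,
                 area = area, occupancy = occupancy),
            class = "island_system")
}

validate_occupancy <- function(occupancy, islands = NULL) {
  occupancy <- as.data.frame(occupancy)
  if (!all(c("species", "island") %in% names(occupancy)))
    stop("occupancy must have columns 'species' and 'island'")
  occupancy$species <- as.character(occupancy$species)
  occupancy$island <- as.character(occupancy$island)
  if (!is.null(islands)) {
    unknown <- setdiff(occupancy$island, islands)
    if (length(unknown))
      stop("unknown island label(s) in occupancy: ",
           paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(occupancy[c("species", "island")]))
    stop("duplicate (species, island) records in occupancy")
  occupancy
}

#' @export
print.island_system <- function(x, ...) {
  cat("Island system with", length(x$islands), "island units:",
      paste(x$islands, collapse = ", "), "\n")
  rng <- range(x$distance[upper.tri(x$distance)])
  cat(sprintf("Inter-shore distances: %.3g-%.3g km\n", rng[1], rng[2]))
  if (!is.null(x$occupancy))
    cat("Occupancy:", nrow(x$occupancy), "(species, island) records for",
        length(unique(x$occupancy$species)), "species\n")
  invisible(x)
}

#' Read an island system from CSV tables
#'
#' @param distance_file CSV distance matrix: first column and header row are
#'   island labels, entries minimum inter-shore distances in km.
#' @param occupancy_file optional CSV with columns `species,island`.
#' @param area_file optional CSV with columns `island,area_km2`.
#' @param tol symmetry tolerance passed to [island_system()].
#' @return An [island_system()] object.
#' @export
load_island_system <- function(distance_file, occupancy_file = NULL,
                               area_file = NULL, tol = 1e-9) {
  if (!file.exists(distance_file)) stop("no such file: ", distance_file)
  d <- utils::read.csv(distance_file, row.names = 1, check.names = FALSE)
  d <- as.matrix(d)
  storage.mode(d) <- "double"
  occ <- if (!is.null(occupancy_file)) utils::read.csv(occupancy_file)
  area <- NULL
  if (!is.null(area_file)) {
    a <- utils::read.csv(area_file)
    if (!all(c("island", "area_km2") %in% names(a)))
      stop("area table must have columns 'island' and 'area_km2'")
    area <- stats::setNames(a$area_km2, a$island)
  }
  island_system(d, area = area, occupancy = occ, tol = tol)
}

#' Write an island system back to CSV tables
#'
#' Inverse of [load_island_system()]; `load -> write -> load` round-trips
#' exactly for well-formed inputs.
#'
#' @param system an [island_system()] object.
#' @param distance_file,occupancy_file,area_file output paths; the latter two
#'   are only written when the system carries the corresponding component.
#' @return Invisibly, the paths written.
#' @export
write_island_system <- function(system, distance_file,
                                occupancy_file = NULL, area_file = NULL) {
  stopifnot(inherits(system, "island_system"))
  d <- as.data.frame(system$distance)
  utils::write.csv(cbind(island = rownames(d), d), distance_file,
                   row.names = FALSE, quote = FALSE)
  written <- distance_file
  if (!is.null(occupancy_file) && !is.null(system$occupancy)) {
    utils::write.csv(system$occupancy[c("species", "island")],
                     occupancy_file, row.names = FALSE, quote = FALSE)
    written <- c(written, occupancy_file)
  }
  if (!is.null(area_file) && !is.null(system$area)) {
    utils::write.csv(data.frame(island = names(system$area),
                                area_km2 = unname(system$area)),
                     area_file, row.names = FALSE, quote = FALSE)
    written <- c(written, area_file)
  }
  invisible(written)
}

#' Minimum number of colonization events implied by an occupancy pattern
#'
#' Under a model in which every isolated island population descends from a
#' single over-water colonization (the seeding of the very first population
#' not counted), the minimum number of inter-island colonization events
#' consistent with an occupancy pattern is simply the number of distinct
#' (species, island-unit) populations minus one.
#'
#' @param occupancy a data frame with columns `species` and `island`, or an
#'   [island_system()] carrying one.
#' @return A non-negative integer count of colonization events.
#' @examples
#' occ <- data.frame(species = c("a", "a", "b"), island = c("X", "Y", "Y"))
#' min_colonization_events(occ)  # 3 populations -> 2 events
#' @export
min_colonization_events <- function(occupancy) {
  if (inherits(occupancy, "island_system")) occupancy <- occupancy$occupancy
  if (is.null(occupancy) || nrow(as.data.frame(occupancy)) == 0L)
    stop("occupancy is empty: at least one (species, island) record required")
  occupancy <- as.data.frame(occupancy)
  if (!all(c("species", "island") %in% names(occupancy)))
    stop("occupancy must have columns 'species' and 'island'")
  n <- nrow(unique(occupancy[c("species", "island")]))
  as.integer(n - 1L)
}
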