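#' Read and write Newick trees
#'
#' Thin, validating wrappers around the standard Newick parser: trees must
#' carry branch lengths on every edge, and `read -> write -> read`
#' round-trips topology and branch lengths to better than 1e-12.
#'
#' @param path file path.
#' @return `read_newick`: an [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("Newick parse error in '", path,
                                            "': ", conditionMessage(e),
                                            call. = FALSE))
  if (is.null(tree))
    stop("Newick parse error: no tree could be read from '", path, "'")
  if (inherits(tree, "multiPhylo")) tree <- tree[[1]]
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree in '", path, "' is missing branch lengths")
  tree
}

#' @param tree an [ape::phylo] tree with branch lengths.
#' @rdname read_newick
#' @return `write_newick`: the path, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a \"phylo\" object")
  if (is.null(tree$edge.length)) stop("tree is missing branch lengths")
  ape::write.tree(tree, file = path, digits = 15)
  invisible(path)
}

#' Read and write ESRI ASCII grid rasters
#'
#' Plain-text raster format with a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by
#' row-major values from the top-left. `NODATA` cells become invalid mask
#' entries of the [suitability_grid()]. Round-trips are bit-stable at the
#' written decimal precision.
#'
#' @param path file path.
#' @return `read_ascii_grid`: a [suitability_grid()].
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^[A-Za-z]", trimws(lines[i]))) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2L)
      stop("malformed header line ", i, ": '", lines[i], "'")
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  req <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  missing_keys <- setdiff(req, names(hdr))
  if (length(missing_keys))
    stop("header missing: ", paste(missing_keys, collapse = ", "))
  nodata <- if ("nodata_value" %in% names(hdr)) hdr$nodata_value else -9999
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  body <- lines[seq(i, length.out = length(lines) - i + 1L)]
  if (length(body) != nr)
    stop("expected ", nr, " data rows, found ", length(body))
  vals <- base::matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    row <- as.numeric(strsplit(trimws(body[r]), "\\s+")[[1]])
    if (length(row) != nc)
      stop("row ", r, " has ", length(row), " values, expected ncols = ", nc)
    vals[r, ] <- row
  }
  mask <- vals != nodata & !is.na(vals)
  vals[!mask] <- NA_real_
  suitability_grid(vals, mask, xllcorner = hdr$xllcorner,
                   yllcorner = hdr$yllcorner, cellsize = hdr$cellsize,
                   nodata_value = nodata)
}

#' @param grid a [suitability_grid()].
#' @param digits significant digits written per cell.
#' @rdname read_ascii_grid
#' @return `write_ascii_grid`: the path, invisibly.
#' @export
write_ascii_grid <- function(grid, path, digits = 10) {
  stopifnot(inherits(grid, "suitability_grid"))
  v <- grid$values
  v[!grid$mask] <- grid$nodata_value
  hdr <- c(paste("ncols", ncol(v)),
           paste("nrows", nrow(v)),
           paste("xllcorner", format(grid$xllcorner, digits = 15)),
           paste("yllcorner", format(grid$yllcorner, digits = 15)),
           paste("cellsize", format(grid$cellsize, digits = 15)),
           paste("NODATA_value", format(grid$nodata_value, digits = 15)))
  rows <- apply(v, 1, function(r)
    paste(formatC(r, digits = digits, format = "g"), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Run an analysis stage and write its artifacts
#'
#' A small stage dispatcher tying the pipeline together for scripted use:
#' runs one named analysis stage from a configuration list, writes its
#' numeric outputs under `out_dir`, and records a machine-readable
#' `manifest.json` (stage, parameters, seed, package version, input files,
#' artifact paths) sufficient to regenerate every output exactly.
#'
#' Stages and their parameters:
#' \describe{
#'   \item{`"dispersion"`}{`traits_file` (CSV `terminal,mean[,se,n]`; default
#'     the packaged skull table) or `tree_file` (Newick), `pairs_file` (CSV
#'     of sympatric pairs; default the packaged pairs), `aggregator`,
#'     `replicates`. Writes the observed statistic, P-values and null
#'     distribution.}
#'   \item{`"simulate"`}{`distance_file` (CSV matrix), `target_islands`,
#'     `exponent`, `replicates`, `start_rule`, `observed_min` (optional).
#'     Writes per-replicate event counts and a summary with tail P-value.}
#' }
#'
#' @param config list with elements `stage`, `seed`, and stage parameters.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with `results` (stage-specific) and
#'   `artifacts` (paths written).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.null(config$stage)) stop("config$stage is required")
  if (is.null(config$seed)) stop("config$seed is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- config$stage
  artifacts <- character()
  inputs <- character()

  if (stage == "dispersion") {
    pairs_file <- config$pairs_file %||%
      system.file("extdata", "sympatric_pairs.csv",
                  package = "islandassembly", mustWork = TRUE)
    pairs <- utils::read.csv(pairs_file)[, 1:2]
    if (!is.null(config$tree_file)) {
      m <- patristic_matrix(read_newick(config$tree_file))
      inputs <- c(inputs, config$tree_file, pairs_file)
    } else {
      traits_file <- config$traits_file %||%
        system.file("extdata", "table3_skulls.csv",
                    package = "islandassembly", mustWork = TRUE)
      m <- trait_difference_matrix(utils::read.csv(traits_file))
      inputs <- c(inputs, traits_file, pairs_file)
    }
    res <- permutation_test(m, pairs,
                            replicates = config$replicates %||% 2000,
                            aggregator = config$aggregator %||% "mean",
                            seed = config$seed)
    rfile <- file.path(out_dir, "dispersion_test.json")
    jsonlite::write_json(list(observed = res$observed, p = res$p,
                              p_corrected = res$p_corrected,
                              aggregator = res$aggregator,
                              replicates = res$replicates,
                              seed = config$seed),
                         rfile, auto_unbox = TRUE, digits = NA)
    nfile <- file.path(out_dir, "dispersion_null.csv")
    utils::write.csv(data.frame(delta = res$null_values), nfile,
                     row.names = FALSE)
    artifacts <- c(rfile, nfile)
    message(sprintf("dispersion: observed = %.4f, P = %.4g (%d replicates)",
                    res$observed, res$p, res$replicates))
  } else if (stage == "simulate") {
    if (is.null(config$distance_file))
      stop("simulate stage requires 'distance_file'")
    sys <- load_island_system(config$distance_file)
    inputs <- c(inputs, config$distance_file)
    cfg <- colonization_config(
      target_islands = config$target_islands,
      exponent = config$exponent %||% 1,
      replicates = config$replicates %||% 10000,
      start_rule = config$start_rule %||% "random",
      seed = config$seed)
    res <- simulate_colonization(sys, cfg)
    cfile <- file.path(out_dir, "event_counts.csv")
    utils::write.csv(data.frame(start = res$start_islands,
                                events = res$event_counts),
                     cfile, row.names = FALSE)
    summ <- list(mean = mean(res$event_counts),
                 quantiles = as.list(stats::quantile(
                   res$event_counts, c(0.025, 0.25, 0.5, 0.75, 0.975))),
                 replicates = cfg$replicates, seed = config$seed,
                 exponent = cfg$exponent, target_islands = cfg$target_islands)
    if (!is.null(config$observed_min))
      summ$p_value <- colonization_pvalue(res, config$observed_min)
    sfile <- file.path(out_dir, "simulation_summary.json")
    jsonlite::write_json(summ, sfile, auto_unbox = TRUE, digits = NA)
    artifacts <- c(cfile, sfile)
    message(sprintf("simulate: %d replicates, mean events = %.2f%s",
                    cfg$replicates, mean(res$event_counts),
                    if (!is.null(summ$p_value))
                      sprintf(", P = %.4g", summ$p_value) else ""))
  } else {
    stop("unknown stage '", stage, "'; available: dispersion, simulate")
  }

  manifest <- list(
    stage = stage, seed = config$seed,
    parameters = config[setdiff(names(config), c("stage", "seed"))],
    inputs = inputs, artifacts = artifacts,
    package_version = as.character(utils::packageVersion("islandassembly")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  mfile <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mfile, auto_unbox = TRUE, digits = NA)
  invisible(list(results = res, artifacts = c(artifacts, mfile)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
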