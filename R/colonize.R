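#' Configuration for the colonization simulator
#'
#' @param target_islands integer K: the simulation terminates once K distinct
#'   islands are occupied.
#' @param exponent nonnegative dispersal-kernel power alpha. Colonization
#'   probability decays as distance^(-alpha); `1` gives inverse-distance
#'   weighting, `2` inverse-squared (long-distance colonization much rarer),
#'   and `0` a uniform kernel (every recipient equally likely), which admits
#'   a closed-form expectation ([expected_events_uniform()]).
#' @param replicates number of independent simulation replicates.
#' @param start_rule either `"random"` (the seeded island is drawn uniformly
#'   at random each replicate) or the name of a fixed starting island.
#' @param seed integer seed fixing the whole simulation (a single RNG stream
#'   is used across replicates; see Details).
#'
#' @details Reproducibility contract: [simulate_colonization()] calls
#' `set.seed(seed)` once and then consumes R's default Mersenne-Twister
#' stream sequentially across replicates. Identical seed, system and
#' configuration give bit-identical event counts; replicates do not get
#' independent substreams.
#'
#' @return An object of class `"colonization_config"`.
#' @export
colonization_config <- function(target_islands, exponent = 1,
                                replicates = 10000, start_rule = "random",
                                seed = NULL) {
  if (!is.numeric(exponent) || length(exponent) != 1L || exponent < 0)
    stop("'exponent' must be a single nonnegative number")
  target_islands <- as.integer(target_islands)
  if (is.na(target_islands) || target_islands < 1L)
    stop("'target_islands' must be a positive integer")
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L)
    stop("'replicates' must be >= 1")
  if (!is.character(start_rule) || length(start_rule) != 1L)
    stop("'start_rule' must be \"random\" or an island name")
  structure(list(exponent = exponent, target_islands = target_islands,
                 replicates = replicates, start_rule = start_rule,
                 seed = seed),
            class = "colonization_config")
}

#' Dispersal-kernel transition probabilities from a source island
#'
#' Probability that a propagule leaving `source` arrives on each other
#' island: `d(source, j)^(-exponent)` normalized to sum to one over all
#' islands other than the source. The source itself has probability exactly
#' zero. Already-occupied islands are *not* excluded: arrivals there are
#' "failed" colonizations that still consume an event.
#'
#' @param system an [island_system()].
#' @param source island name (or index).
#' @param exponent nonnegative kernel power.
#' @return Named probability vector over all islands, summing to 1.
#' @examples
#' d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3,
#'             dimnames = list(LETTERS[1:3], LETTERS[1:3]))
#' transition_probabilities(island_system(d), "A", exponent = 1)
#' @export
transition_probabilities <- function(system, source, exponent = 1) {
  stopifnot(inherits(system, "island_system"))
  if (is.character(source)) {
    source <- match(source, system$islands)
    if (is.na(source)) stop("unknown source island")
  }
  d <- system$distance[source, ]
  if (any(d[-source] == 0))
    stop("zero distance between distinct islands: kernel undefined")
  w <- d^(-exponent)
  w[source] <- 0
  w / sum(w)
}

# Cumulative-probability rows for all sources, for fast inverse-cdf draws.
.transition_cum <- function(system, exponent) {
  n <- length(system$islands)
  P <- matrix(0, n, n)
  for (i in seq_len(n))
    P[i, ] <- transition_probabilities(system, i, exponent)
  t(apply(P, 1, cumsum))
}

# One replicate on precomputed cumulative rows; consumes the current RNG
# stream. Returns the event count (and the trajectory if asked).
.colonize_once <- function(cumP, n, K, start, keep_trajectory = FALSE) {
  occupied <- integer(n)
  occupied[1L] <- start
  n_occ <- 1L
  is_occ <- logical(n)
  is_occ[start] <- TRUE
  events <- 0L
  traj <- if (keep_trajectory) list() else NULL
  while (n_occ < K) {
    src <- occupied[sample.int(n_occ, 1L)]
    rec <- findInterval(stats::runif(1L), cumP[src, ]) + 1L
    events <- events + 1L
    if (keep_trajectory) traj[[events]] <- c(src, rec)
    if (!is_occ[rec]) {
      is_occ[rec] <- TRUE
      n_occ <- n_occ + 1L
      occupied[n_occ] <- rec
    }
  }
  list(events = events, trajectory = traj)
}

#' Run a single colonization replicate
#'
#' One realisation of the stochastic colonization process: an island is
#' seeded (uncounted), then colonization events occur one at a time -- the
#' source drawn uniformly from currently occupied islands, the recipient
#' from [transition_probabilities()] -- until `target_islands` distinct
#' islands are occupied. Events landing on already-occupied islands count
#' toward the total but leave the occupied set unchanged.
#'
#' Uses the current RNG state; call `set.seed()` beforehand for
#' reproducibility, or use [simulate_colonization()].
#'
#' @param system an [island_system()].
#' @param config a [colonization_config()] (its `seed` is ignored here).
#' @param keep_trajectory if `TRUE`, also return the ordered list of
#'   (source, recipient) events.
#' @return A list with `events` (integer count), `start` (seeded island
#'   name) and optionally `trajectory` (two-column matrix of island names).
#' @export
run_replicate <- function(system, config, keep_trajectory = FALSE) {
  stopifnot(inherits(system, "island_system"),
            inherits(config, "colonization_config"))
  n <- length(system$islands)
  K <- config$target_islands
  if (K > n)
    stop("target_islands exceeds the number of islands")
  start <- if (identical(config$start_rule, "random")) {
    sample.int(n, 1L)
  } else {
    s <- match(config$start_rule, system$islands)
    if (is.na(s)) stop("unknown start island: ", config$start_rule)
    s
  }
  cumP <- .transition_cum(system, config$exponent)
  res <- .colonize_once(cumP, n, K, start, keep_trajectory)
  out <- list(events = res$events, start = system$islands[start])
  if (keep_trajectory) {
    tr <- do.call(rbind, res$trajectory)
    out$trajectory <- if (is.null(tr)) {
      matrix(character(), 0, 2, dimnames = list(NULL, c("source", "recipient")))
    } else {
      matrix(system$islands[tr], ncol = 2,
             dimnames = list(NULL, c("source", "recipient")))
    }
  }
  out
}

#' Simulate the inter-island colonization process
#'
#' Repeats the colonization replicate many times and records the number of
#' colonization events each replicate needed before `target_islands`
#' distinct islands were occupied. Comparing the resulting null distribution
#' with the *minimum* number of events implied by the observed occupancy
#' ([min_colonization_events()]) asks whether a purely stochastic dispersal
#' process, with no ecological interactions, plausibly produced the
#' observed distribution with so few events.
#'
#' @param system an [island_system()].
#' @param config a [colonization_config()].
#' @return An object of class `"colonization_summary"`: list with
#'   `event_counts` (integer vector, one per replicate), `start_islands`
#'   (character vector of seeded islands), `islands`, and `config`.
#' @examples
#' d <- matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
#' diag(d) <- 0
#' sys <- island_system(d)
#' cfg <- colonization_config(target_islands = 4, replicates = 200, seed = 1)
#' sim <- simulate_colonization(sys, cfg)
#' mean(sim$event_counts)
#' expected_events_uniform(4, 4)
#' @export
simulate_colonization <- function(system, config) {
  stopifnot(inherits(system, "island_system"),
            inherits(config, "colonization_config"))
  n <- length(system$islands)
  K <- config$target_islands
  if (K > n) stop("target_islands exceeds the number of islands")
  if (!is.null(config$seed)) set.seed(config$seed)
  fixed_start <- NA_integer_
  if (!identical(config$start_rule, "random")) {
    fixed_start <- match(config$start_rule, system$islands)
    if (is.na(fixed_start)) stop("unknown start island: ", config$start_rule)
  }
  cumP <- .transition_cum(system, config$exponent)
  R <- config$replicates
  counts <- integer(R)
  starts <- integer(R)
  for (r in seq_len(R)) {
    starts[r] <- if (is.na(fixed_start)) sample.int(n, 1L) else fixed_start
    counts[r] <- .colonize_once(cumP, n, K, starts[r])$events
  }
  structure(list(event_counts = counts,
                 start_islands = system$islands[starts],
                 islands = system$islands, config = config),
            class = "colonization_summary")
}

#' @export
print.colonization_summary <- function(x, ...) {
  cat(sprintf(
    "Colonization simulation: %d replicates, K = %d of %d islands, alpha = %g\n",
    length(x$event_counts), x$config$target_islands, length(x$islands),
    x$config$exponent))
  cat(sprintf("Events per replicate: mean %.2f, median %g, range [%d, %d]\n",
              mean(x$event_counts), stats::median(x$event_counts),
              min(x$event_counts), max(x$event_counts)))
  invisible(x)
}

#' Lower-tail P-value of an observed minimum event count
#'
#' The proportion of simulation replicates whose event count was less than
#' or equal to the observed minimum number of colonization events. A small
#' value means the stochastic process rarely spreads across the archipelago
#' with so few events, suggesting that something (e.g. competitive
#' exclusion of arriving propagules) suppressed successful colonization.
#'
#' @param summary a [simulate_colonization()] result.
#' @param observed_min nonnegative integer, typically
#'   [min_colonization_events()].
#' @return Proportion in `[0, 1]`, nondecreasing in `observed_min`.
#' @export
colonization_pvalue <- function(summary, observed_min) {
  stopifnot(inherits(summary, "colonization_summary"))
  if (length(summary$event_counts) == 0L)
    stop("summary contains no replicates")
  observed_min <- as.integer(observed_min)
  if (is.na(observed_min) || observed_min < 0L)
    stop("'observed_min' must be a nonnegative integer")
  mean(summary$event_counts <= observed_min)
}

#' Restrict a simulation summary to replicates seeded from one island
#'
#' Used to condition the null distribution on biologically plausible
#' colonization routes (e.g. seeding from the islands nearest a continental
#' source): retains only replicates whose randomly seeded island matches,
#' after which [colonization_pvalue()] applies to the subset.
#'
#' @param summary a [simulate_colonization()] result.
#' @param island island name to condition on.
#' @return A `"colonization_summary"` for the subset.
#' @export
filter_by_start <- function(summary, island) {
  stopifnot(inherits(summary, "colonization_summary"))
  if (!island %in% summary$islands)
    stop("unknown island: ", island)
  keep <- summary$start_islands == island
  if (!any(keep))
    stop("no replicates were seeded from island '", island,
         "' (empty subset)")
  out <- summary
  out$event_counts <- summary$event_counts[keep]
  out$start_islands <- summary$start_islands[keep]
  out
}

#' Expected event count under a uniform kernel (closed form)
#'
#' With all inter-island distances equal (or `exponent = 0`) the recipient
#' is uniform over the `n - 1` non-source islands, so reaching a new island
#' from `m` occupied ones is a Bernoulli trial with success probability
#' `(n - m) / (n - 1)` and geometric waiting time. The expected total number
#' of events to occupy `K` islands is the coupon-collector-style sum
#' `sum_{m=1}^{K-1} (n - 1) / (n - m)`. Serves as the analytic oracle for
#' the simulator.
#'
#' @param n number of islands.
#' @param K target number of occupied islands, `1 <= K <= n`.
#' @return Expected number of colonization events (seeding uncounted).
#' @examples
#' expected_events_uniform(6, 5)  # 77/12
#' @export
expected_events_uniform <- function(n, K) {
  n <- as.integer(n); K <- as.integer(K)
  if (is.na(n) || is.na(K) || K < 1L || n < 1L)
    stop("'n' and 'K' must be positive integers")
  if (K > n) stop("K exceeds n")
  if (K == 1L) return(0)
  m <- seq_len(K - 1L)
  sum((n - 1) / (n - m))
}
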