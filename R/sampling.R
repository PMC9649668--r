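#' Sampling completeness and sampling-effort checks
#'
#' Completeness treats each unique plant-bird link as a "species" and its
#' interaction frequency as its "abundance", and applies the abundance-based
#' sample-coverage estimator built from singleton and doubleton links. The
#' sampling-effort check rarefies event logs to a common number of
#' camera-days and rebuilds the networks from the subsampled data.
#'
#' @name sampling
NULL

#' Abundance-based sample coverage of an interaction matrix
#'
#' With n the total number of independent events, f1 the number of links
#' seen exactly once and f2 the number seen exactly twice:
#' \deqn{\hat C = 1 - (f_1/n) \cdot (n-1) f_1 / ((n-1) f_1 + 2 f_2)}
#'
#' @param M plants x birds frequency matrix (integer counts).
#' @return list with `n`, `f1`, `f2`, `c_hat` in \[0, 1\].
#' @export
sample_coverage <- function(M) {
  check_matrix(M)
  f <- M[M > 0]
  n <- sum(f)
  if (n == 0) stop("matrix has no events", call. = FALSE)
  f1 <- sum(f == 1)
  f2 <- sum(f == 2)
  c_hat <- if (f1 == 0) {
    1
  } else if ((n - 1) * f1 + 2 * f2 == 0) {
    0  # n = 1: the single singleton covers nothing beyond itself
  } else {
    1 - (f1 / n) * ((n - 1) * f1 / ((n - 1) * f1 + 2 * f2))
  }
  list(n = n, f1 = f1, f2 = f2, c_hat = c_hat)
}

camera_day_of <- function(events) {
  paste(events$camera_id, as.Date(events$timestamp, tz = "UTC"), sep = "@")
}

#' Rarefy an event log to a fixed number of camera-days
#'
#' Subsamples whole camera-day blocks (camera x calendar day) without
#' replacement, applies the independence filter, rebuilds the network and
#' records richness; repeated `reps` times. Used to check that unequal
#' sampling effort does not drive diversity patterns (the study rarefied
#' every island to its minimum effort of 414 camera-days).
#'
#' @param events raw event records of a single site.
#' @param site_id the site.
#' @param target_days camera-days to retain; must not exceed the number of
#'   distinct camera-day blocks with events... see Details.
#' @param reps number of subsamples.
#' @param seed optional seed.
#' @param total_days optional total effort (camera-days) of the site; blocks
#'   without events are then part of the sampling frame. Defaults to the
#'   number of blocks that recorded at least one event.
#' @return data frame with one row per metric (`n_birds`, `n_plants`,
#'   `n_species`, `n_links`): `mean`, `sd`, `reps`, `target_days`.
#' @export
rarefy_camera_days <- function(events, site_id, target_days = 414L,
                               reps = 1000L, seed = NULL, total_days = NULL) {
  check_events(events)
  if (!is.null(seed)) set.seed(seed)
  block <- camera_day_of(events)
  blocks <- unique(block)
  n_avail <- if (is.null(total_days)) length(blocks) else total_days
  if (n_avail < length(blocks))
    stop("total_days smaller than the number of blocks with events",
         call. = FALSE)
  if (target_days > n_avail)
    stop("target_days (", target_days, ") exceeds available camera-days (",
         n_avail, ")", call. = FALSE)
  vals <- matrix(NA_real_, reps, 4,
                 dimnames = list(NULL,
                                 c("n_birds", "n_plants", "n_species",
                                   "n_links")))
  for (r in seq_len(reps)) {
    # sample block indices from the full frame; indices beyond the observed
    # blocks are empty camera-days
    take <- sample.int(n_avail, target_days)
    keep <- events[block %in% blocks[take[take <= length(blocks)]], ,
                   drop = FALSE]
    if (nrow(keep) == 0L) {
      vals[r, ] <- 0
      next
    }
    M <- build_network(filter_independent_events(keep), site_id)
    vals[r, ] <- c(ncol(M), nrow(M), ncol(M) + nrow(M), sum(M > 0))
  }
  data.frame(site_id = site_id, metric = colnames(vals),
             mean = colMeans(vals), sd = apply(vals, 2, stats::sd),
             reps = reps, target_days = target_days,
             row.names = NULL, stringsAsFactors = FALSE)
}
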