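#' Camera-trap event logs and interaction matrices
#'
#' An event record is one camera-trap detection of a frugivorous bird at a
#' fruiting plant: `camera_id`, `island_id`, `plant_species`,
#' `plant_individual`, `bird_species`, `timestamp` (POSIXct), `n_birds`.
#' Interaction frequency is the number of *independent* events: consecutive
#' records of the same plant-frugivore interaction are merged unless they
#' are separated by more than five minutes.
#'
#' @name event_processing
NULL

event_columns <- c("camera_id", "island_id", "plant_species",
                   "plant_individual", "bird_species", "timestamp", "n_birds")

check_events <- function(events) {
  missing <- setdiff(event_columns, names(events))
  if (length(missing))
    stop("event table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  invisible(events)
}

#' Read an events CSV
#'
#' Timestamps are ISO-8601, parsed in UTC; an unparseable timestamp is a
#' record-level error reporting the offending line number.
#'
#' @param path path to a CSV with the event-record columns.
#' @return a data frame of event records with POSIXct timestamps.
#' @export
read_events <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  check_events(ev)
  ts <- as.POSIXct(strptime(ev$timestamp, "%Y-%m-%dT%H:%M:%OS", tz = "UTC"))
  alt <- is.na(ts)
  ts[alt] <- as.POSIXct(strptime(ev$timestamp[alt], "%Y-%m-%d %H:%M:%OS",
                                 tz = "UTC"))
  bad <- which(is.na(ts))
  if (length(bad))
    stop("unparseable timestamp at line(s) ",
         paste(utils::head(bad + 1L, 5L), collapse = ", "),
         " of ", path, call. = FALSE)
  ev$timestamp <- ts
  ev$n_birds <- as.integer(ev$n_birds)
  ev
}

#' Enforce the five-minute independence rule
#'
#' Within each (camera, plant individual, bird species) group, records are
#' chained: a record extends the current event when its gap to the previous
#' record is at most `window_minutes` (a gap of exactly the window still
#' merges; the rule is "more than" the window); a larger gap starts a new
#' independent event. Each independent event keeps the fields and the
#' timestamp of its first record. Filtering is idempotent.
#'
#' @param events event-record data frame.
#' @param window_minutes independence window, minutes; default 5.
#' @return the independent events, ordered by group and time, with a column
#'   `n_merged` (records absorbed into each event, >= 1) and an attribute
#'   `"n_raw"` with the input record count, so raw records = sum(n_merged).
#' @export
filter_independent_events <- function(events, window_minutes = 5) {
  check_events(events)
  if (!inherits(events$timestamp, "POSIXct"))
    stop("timestamps must be POSIXct; use read_events()", call. = FALSE)
  n_raw <- nrow(events)
  if (n_raw == 0L) {
    events$n_merged <- integer(0)
    attr(events, "n_raw") <- 0L
    return(events)
  }
  key <- paste(events$camera_id, events$plant_individual,
               events$bird_species, sep = "\r")
  ord <- order(key, events$timestamp)
  events <- events[ord, , drop = FALSE]
  key <- key[ord]
  gap <- c(Inf, diff(as.numeric(events$timestamp)) / 60)
  new_group <- c(TRUE, key[-1L] != key[-length(key)])
  starts <- new_group | gap > window_minutes
  run <- cumsum(starts)
  # records already carrying a merge count keep contributing it, so raw
  # record counts are conserved under repeated filtering
  w <- if (is.null(events$n_merged)) rep(1L, nrow(events)) else events$n_merged
  keep <- events[starts, , drop = FALSE]
  keep$n_merged <- as.integer(rowsum(w, run))
  rownames(keep) <- NULL
  attr(keep, "n_raw") <- sum(w)
  keep
}

#' Build a weighted interaction matrix for one site
#'
#' Cell (plant, bird) counts the independent events of that pair at the
#' site. Species without events are absent, so every row and column of the
#' result has at least one nonzero cell.
#'
#' @param events independence-filtered events of a single site.
#' @param site_id the site; events from any other site are rejected.
#' @return an integer plants x birds matrix with dimnames and attribute
#'   `"site_id"`.
#' @export
build_network <- function(events, site_id) {
  check_events(events)
  if (nrow(events) == 0L)
    stop("no events for site '", site_id, "': empty network", call. = FALSE)
  other <- setdiff(unique(events$island_id), site_id)
  if (length(other))
    stop("events from other site(s) present: ",
         paste(other, collapse = ", "), call. = FALSE)
  M <- table(factor(events$plant_species), factor(events$bird_species))
  M <- matrix(as.integer(M), nrow = nrow(M), dimnames = dimnames(M))
  M <- M[rowSums(M) > 0, colSums(M) > 0, drop = FALSE]
  attr(M, "site_id") <- site_id
  M
}

#' Aggregate interaction matrices over sites
#'
#' Takes the species union over the inputs and sums frequencies cellwise;
#' associative and commutative up to label order.
#'
#' @param matrices list of plants x birds matrices with dimnames.
#' @param tag site tag for the aggregate.
#' @return an aggregated matrix with attribute `"site_id" = tag`.
#' @export
aggregate_networks <- function(matrices, tag = "aggregate") {
  stopifnot(length(matrices) >= 1L)
  plants <- sort(unique(unlist(lapply(matrices, rownames))))
  birds <- sort(unique(unlist(lapply(matrices, colnames))))
  A <- matrix(0L, length(plants), length(birds),
              dimnames = list(plants, birds))
  for (M in matrices) A[rownames(M), colnames(M)] <-
    A[rownames(M), colnames(M)] + M
  attr(A, "site_id") <- tag
  A
}
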