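#' Synthetic archipelago generator
#'
#' Emulates a reservoir-island frugivory study: islands spanning orders of
#' magnitude in area, species occupancy thinning with decreasing area,
#' log-series-like plant abundances, lognormal bird body masses, an
#' interaction propensity matrix blending a nested and a modular kernel
#' with tunable weights, and per-camera event streams whose burst structure
#' exercises the five-minute independence filter. Every stage is
#' deterministic under the configuration seed.
#'
#' @name synthetic_data
NULL

#' Configuration of a synthetic archipelago
#'
#' @param n_islands,n_plants,n_birds counts (>= 1).
#' @param area_range_ha island area range, hectares; areas are drawn
#'   log-uniformly so small islands dominate, as in reservoir systems.
#'   Default matches a span of 0.59 to about 1290 ha.
#' @param isolation_range_m island-to-mainland distance range, metres.
#' @param sar_exponent strength of the occupancy-area scaling (0 = area
#'   plays no role).
#' @param nestedness_knob,modularity_knob weights in \[0,1\] of the nested
#'   and the block-diagonal interaction kernels.
#' @param n_modules number of modules of the block kernel.
#' @param camera_days_per_island camera-days of effort per transect; the
#'   per-island total scales with the transect count, which follows the
#'   proportional sampling rule (1 transect below 10 ha, 2 to 100 ha, 4 to
#'   1000 ha, 8 above).
#' @param detection_rate_per_day expected raw detections per camera-day.
#' @param burst_prob probability that a detection spawns a follow-up record
#'   of the same pair within 5 minutes.
#' @param seed integer seed (mandatory).
#' @return a validated list of class `"archipelago_config"`.
#' @export
archipelago_config <- function(n_islands = 22L,
                               area_range_ha = c(0.59, 1289.23),
                               isolation_range_m = c(640, 3262),
                               n_plants = 34L, n_birds = 44L,
                               sar_exponent = 1,
                               nestedness_knob = 0.5,
                               modularity_knob = 0.5,
                               n_modules = 4L,
                               camera_days_per_island = 414L,
                               detection_rate_per_day = 0.5,
                               burst_prob = 0.3,
                               seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  cfg <- list(n_islands = as.integer(n_islands),
              area_range_ha = as.numeric(area_range_ha),
              isolation_range_m = as.numeric(isolation_range_m),
              n_plants = as.integer(n_plants), n_birds = as.integer(n_birds),
              sar_exponent = sar_exponent,
              nestedness_knob = nestedness_knob,
              modularity_knob = modularity_knob,
              n_modules = as.integer(n_modules),
              camera_days_per_island = as.integer(camera_days_per_island),
              detection_rate_per_day = detection_rate_per_day,
              burst_prob = burst_prob,
              seed = as.integer(seed))
  with(cfg, {
    if (n_islands < 1L || n_plants < 1L || n_birds < 1L || n_modules < 1L ||
        camera_days_per_island < 1L)
      stop("counts must be >= 1", call. = FALSE)
    if (length(area_range_ha) != 2L || any(area_range_ha <= 0) ||
        area_range_ha[1L] > area_range_ha[2L])
      stop("invalid area range", call. = FALSE)
    if (length(isolation_range_m) != 2L || any(isolation_range_m < 0) ||
        isolation_range_m[1L] > isolation_range_m[2L])
      stop("invalid isolation range", call. = FALSE)
    for (k in c(nestedness_knob, modularity_knob, burst_prob))
      if (k < 0 || k > 1) stop("knobs must lie in [0, 1]", call. = FALSE)
    if (detection_rate_per_day < 0)
      stop("detection rate must be nonnegative", call. = FALSE)
  })
  structure(cfg, class = "archipelago_config")
}

#' Read an archipelago configuration from YAML or JSON
#'
#' @param path configuration file with the [archipelago_config()] fields;
#'   `seed` is mandatory.
#' @export
read_archipelago_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(archipelago_config, raw)
}

# transects per island under the proportional sampling rule
transects_for_area <- function(area_ha) {
  2L^pmax(0L, as.integer(ceiling(log10(pmax(area_ha, 1e-9)))) - 1L)
}

#' Generate the island table
#'
#' Areas log-uniform within the configured range, isolation uniform, 2-D
#' centroids uniform on a 12 x 12 km square (so pairwise distances are
#' computable), and camera-days assigned proportionally to the transect
#' count implied by island area.
#'
#' @param config an [archipelago_config()].
#' @return data frame: `island_id`, `area_ha`, `isolation_m`, `x`, `y`
#'   (metres), `transects`, `camera_days`, `is_mainland` (all `FALSE`).
#' @export
generate_archipelago <- function(config) {
  stopifnot(inherits(config, "archipelago_config"))
  set.seed(config$seed)
  n <- config$n_islands
  lr <- log(config$area_range_ha)
  area <- exp(stats::runif(n, lr[1L], lr[2L]))
  iso <- stats::runif(n, config$isolation_range_m[1L],
                      config$isolation_range_m[2L])
  tr <- transects_for_area(area)
  out <- data.frame(
    island_id = sprintf("I%02d", order(order(-area))),
    area_ha = area,
    isolation_m = iso,
    x = stats::runif(n, 0, 12000),
    y = stats::runif(n, 0, 12000),
    transects = tr,
    camera_days = tr * config$camera_days_per_island,
    is_mainland = FALSE,
    stringsAsFactors = FALSE)
  out[order(out$island_id), , drop = FALSE]
}

# Fisher log-series abundance sampler via inverse CDF, P(n) ~ theta^n / n
rlogseries <- function(n, theta = 0.95, n_max = 5000L) {
  k <- seq_len(n_max)
  p <- theta^k / k
  sample.int(n_max, n, replace = TRUE, prob = p)
}

# Nested kernel: supports form chains (row p interacts with the first
# birds only, fewer as p grows), values decline smoothly inside the
# support. Block kernel: equal round-robin modules.
nested_kernel <- function(P, B) {
  K <- outer(seq_len(P), seq_len(B), function(p, b)
    pmax(0, 1 - (p - 1) / P - (b - 1) / B))
  K / sum(K)
}

block_kernel <- function(P, B, k) {
  pm <- ((seq_len(P) - 1L) %% k) + 1L
  bm <- ((seq_len(B) - 1L) %% k) + 1L
  K <- outer(pm, bm, `==`) * 1
  K / sum(K)
}

#' Generate species traits, occupancy and interaction propensities
#'
#' Bird body masses are lognormal (median 30 g, so a >100 g tail exists);
#' diet guilds are drawn with omnivores dominant. Plant abundances on each
#' occupied island follow a log-series. Occupancy is Bernoulli with
#' probability increasing in log area (slope `sar_exponent`) plus a
#' species-specific commonness intercept. The propensity matrix is the
#' convex blend `nestedness_knob * nested + modularity_knob * block`,
#' renormalised (uniform when both knobs are zero).
#'
#' @param config an [archipelago_config()].
#' @param islands table from [generate_archipelago()].
#' @return list with `traits` (list: `birds` data frame of
#'   `bird_species`, `body_mass_g`, `guild`; `plant_abundance` data frame of
#'   `island_id`, `plant_species`, `abundance`) and `truth` (list:
#'   occupancy incidence matrices `plant_occ`, `bird_occ` (islands x
#'   species), `propensity`, the knob values, `expected_events` per island,
#'   and the block-module assignments `plant_modules`, `bird_modules`).
#' @export
generate_species_system <- function(config, islands) {
  stopifnot(inherits(config, "archipelago_config"))
  set.seed(config$seed + 1L)
  P <- config$n_plants
  B <- config$n_birds
  plant_ids <- sprintf("P%02d", seq_len(P))
  bird_ids <- sprintf("B%02d", seq_len(B))

  birds <- data.frame(
    bird_species = bird_ids,
    body_mass_g = stats::rlnorm(B, log(30), 0.9),
    guild = sample(c("omnivore", "insectivore", "granivore"), B,
                   replace = TRUE, prob = c(0.72, 0.25, 0.03)),
    stringsAsFactors = FALSE)

  la <- log10(islands$area_ha)
  la_c <- la - mean(la)
  occ_prob <- function(n_sp) {
    # commonness intercept set so mean occupancy is ~0.3, matching the
    # per-network richness of subtropical reservoir-island frugivory
    # surveys (roughly a quarter of the plant pool and a third of the
    # bird pool per island)
    common <- stats::rnorm(n_sp, -0.9, 1.2)
    p <- stats::plogis(outer(config$sar_exponent * la_c, common, `+`))
    (stats::runif(length(p)) < p) * 1L
  }
  plant_occ <- occ_prob(P)
  bird_occ <- occ_prob(B)
  # every island hosts at least one plant and one bird (a camera needs a
  # target plant); force the most common species on empty islands
  plant_occ[rowSums(plant_occ) == 0L, 1L] <- 1L
  bird_occ[rowSums(bird_occ) == 0L, 1L] <- 1L
  dimnames(plant_occ) <- list(islands$island_id, plant_ids)
  dimnames(bird_occ) <- list(islands$island_id, bird_ids)

  occ_long <- which(plant_occ == 1L, arr.ind = TRUE)
  plant_abundance <- data.frame(
    island_id = rownames(plant_occ)[occ_long[, 1L]],
    plant_species = colnames(plant_occ)[occ_long[, 2L]],
    abundance = rlogseries(nrow(occ_long)),
    stringsAsFactors = FALSE)
  plant_abundance <-
    plant_abundance[order(plant_abundance$island_id,
                          plant_abundance$plant_species), , drop = FALSE]
  rownames(plant_abundance) <- NULL

  wn <- config$nestedness_knob
  wm <- config$modularity_knob
  K <- if (wn == 0 && wm == 0) {
    matrix(1 / (P * B), P, B)
  } else {
    wn * nested_kernel(P, B) + wm * block_kernel(P, B, config$n_modules)
  }
  K <- K / sum(K)
  dimnames(K) <- list(plant_ids, bird_ids)

  truth <- list(plant_occ = plant_occ, bird_occ = bird_occ, propensity = K,
                nestedness_knob = wn, modularity_knob = wm,
                plant_modules = ((seq_len(P) - 1L) %% config$n_modules) + 1L,
                bird_modules = ((seq_len(B) - 1L) %% config$n_modules) + 1L,
                expected_events = stats::setNames(
                  islands$camera_days * config$detection_rate_per_day,
                  islands$island_id))
  list(traits = list(birds = birds, plant_abundance = plant_abundance),
       truth = truth)
}

#' Generate a camera-trap event stream
#'
#' Per island the raw detection count is Poisson(camera-days x detection
#' rate); pair identities are drawn proportionally to propensity masked by
#' the island's occupancy. Each occupied plant species hosts two monitored
#' individuals, each with its own camera; timestamps are uniform over the
#' sampling season and strictly increasing per camera. With probability
#' `burst_prob` a detection spawns one follow-up record of the same pair at
#' the same camera within 5 minutes, so the raw stream overstates
#' independent events unless filtered.
#'
#' @param truth,islands,config outputs of the upstream generators.
#' @return event-record data frame (see [event_processing]) ordered by
#'   camera and time, with attribute `"n_burst"` = number of burst
#'   follow-up records inserted.
#' @export
generate_event_log <- function(truth, islands, config) {
  stopifnot(inherits(config, "archipelago_config"))
  set.seed(config$seed + 2L)
  season_start <- as.POSIXct("2019-07-01 00:00:00", tz = "UTC")
  out <- vector("list", nrow(islands))
  n_burst_total <- 0L
  for (i in seq_len(nrow(islands))) {
    isl <- islands$island_id[i]
    n_raw <- stats::rpois(1L, islands$camera_days[i] *
                            config$detection_rate_per_day)
    plants <- colnames(truth$plant_occ)[truth$plant_occ[isl, ] == 1L]
    birds <- colnames(truth$bird_occ)[truth$bird_occ[isl, ] == 1L]
    if (n_raw == 0L || !length(plants) || !length(birds)) next
    W <- truth$propensity[plants, birds, drop = FALSE]
    if (sum(W) == 0) next
    pair <- sample.int(length(W), n_raw, replace = TRUE, prob = as.vector(W))
    pr <- ((pair - 1L) %% nrow(W)) + 1L
    bc <- ((pair - 1L) %/% nrow(W)) + 1L
    ind <- sample.int(2L, n_raw, replace = TRUE)  # two individuals/species
    span_days <- islands$camera_days[i] / max(1L, 2L * length(plants))
    t0 <- season_start +
      stats::runif(n_raw, 0, max(1, span_days) * 86400)
    ev <- data.frame(
      camera_id = sprintf("%s-%s-%d", isl, plants[pr], ind),
      island_id = isl,
      plant_species = plants[pr],
      plant_individual = sprintf("%s-%s-%d", isl, plants[pr], ind),
      bird_species = birds[bc],
      timestamp = t0,
      n_birds = 1L + stats::rpois(n_raw, 0.3),
      stringsAsFactors = FALSE)
    burst <- stats::runif(n_raw) < config$burst_prob
    if (any(burst)) {
      fu <- ev[burst, , drop = FALSE]
      fu$timestamp <- fu$timestamp + stats::runif(sum(burst), 1, 299)
      ev <- rbind(ev, fu)
      n_burst_total <- n_burst_total + sum(burst)
    }
    out[[i]] <- ev
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(camera_id = character(0), island_id = character(0),
                      plant_species = character(0),
                      plant_individual = character(0),
                      bird_species = character(0),
                      timestamp = as.POSIXct(character(0), tz = "UTC"),
                      n_birds = integer(0), stringsAsFactors = FALSE)
  } else {
    out <- out[order(out$camera_id, out$timestamp), , drop = FALSE]
    # strictly increasing timestamps per camera
    same <- c(FALSE, out$camera_id[-1L] == out$camera_id[-nrow(out)] &
                diff(as.numeric(out$timestamp)) <= 0)
    while (any(same)) {
      out$timestamp[same] <- out$timestamp[same] + 0.5
      out <- out[order(out$camera_id, out$timestamp), , drop = FALSE]
      same <- c(FALSE, out$camera_id[-1L] == out$camera_id[-nrow(out)] &
                  diff(as.numeric(out$timestamp)) <= 0)
    }
    rownames(out) <- NULL
  }
  attr(out, "n_burst") <- n_burst_total
  out
}
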