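# Independent oracles and fixture builders. These stay deliberately naive:
# enumeration and direct arithmetic, no shared code with the implementation.

# all set partitions of 1..n as integer label vectors
set_partitions <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (s in set_partitions(n - 1L)) {
    for (j in seq_len(max(s) + 1L)) out[[length(out) + 1L]] <- c(s, j)
  }
  out
}

# exhaustive maximum Barber Q over every joint partition of rows and columns
exhaustive_barber_q <- function(M) {
  n <- nrow(M) + ncol(M)
  best <- -Inf
  for (p in set_partitions(n)) {
    q <- frugnet::barber_modularity(M, p[seq_len(nrow(M))],
                                    p[nrow(M) + seq_len(ncol(M))])
    if (q > best) best <- q
  }
  best
}

# robustness of one plant removal order, traced by hand logic
cascade_R <- function(M, order) {
  n <- length(order)
  y <- 1
  for (k in seq_len(n)) {
    left <- setdiff(order, order[seq_len(k)])
    surv <- if (k == n) 0 else {
      sum(colSums(M[left, , drop = FALSE] > 0) > 0) / ncol(M)
    }
    y <- c(y, surv)
  }
  x <- seq(0, n) / n
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# mean robustness over every plant permutation
enumerate_random_R <- function(M) {
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  mean(vapply(perms(rownames(M)), function(o) cascade_R(M, o), numeric(1)))
}

# small labelled matrix builder
mat <- function(values, nr, plants = NULL, birds = NULL, byrow = TRUE) {
  m <- matrix(values, nrow = nr, byrow = byrow)
  rownames(m) <- if (is.null(plants)) paste0("P", seq_len(nrow(m))) else plants
  colnames(m) <- if (is.null(birds)) paste0("B", seq_len(ncol(m))) else birds
  m
}

# event-record builder; times in minutes from a fixed origin
make_events <- function(camera, plant_sp, plant_ind, bird, t_min,
                        island = "I01", n_birds = 1L) {
  data.frame(
    camera_id = camera, island_id = island, plant_species = plant_sp,
    plant_individual = plant_ind, bird_species = bird,
    timestamp = as.POSIXct("2019-07-01 06:00:00", tz = "UTC") + t_min * 60,
    n_birds = n_birds, stringsAsFactors = FALSE)
}

default_test_config <- function(seed, ...) {
  frugnet::archipelago_config(
    n_islands = 8L, n_plants = 12L, n_birds = 16L,
    camera_days_per_island = 80L, detection_rate_per_day = 2,
    seed = seed, ...)
}

# generative model shaped like the fragmentation path hypothesis
sem_generative <- function(n, resid_sd = 0.6) {
  d <- data.frame(log_area = rnorm(n), log_isolation = rnorm(n))
  e <- function() rnorm(n, 0, resid_sd)
  d$connectance_z <- -0.75 * d$log_area + 0.1 * d$log_isolation + e()
  d$modularity_z <- 0.4 * d$log_area - 0.1 * d$log_isolation +
    0.3 * d$connectance_z + e()
  d$wnodf_z <- -0.1 * d$log_area + 0.57 * d$connectance_z + e()
  d$robustness_z <- 0.35 * d$connectance_z + 0.3 * d$modularity_z +
    0.05 * d$wnodf_z + 0.1 * d$log_area + e()
  d
}

sem_generative_raw <- c(
  log_area.connectance_z = -0.75, log_isolation.connectance_z = 0.1,
  log_area.modularity_z = 0.4, log_isolation.modularity_z = -0.1,
  connectance_z.modularity_z = 0.3,
  log_area.wnodf_z = -0.1, log_isolation.wnodf_z = 0,
  connectance_z.wnodf_z = 0.57,
  log_area.robustness_z = 0.1, log_isolation.robustness_z = 0,
  connectance_z.robustness_z = 0.35,
  modularity_z.robustness_z = 0.3, wnodf_z.robustness_z = 0.05)

# standardised truth for one fitted path, via the sample sds
sem_std_truth <- function(from, to, d) {
  unname(sem_generative_raw[paste(from, to, sep = ".")] *
           sd(d[[from]]) / sd(d[[to]]))
}
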