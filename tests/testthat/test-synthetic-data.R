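test_that("configuration validates ranges, knobs and the mandatory seed", {
  expect_error(archipelago_config(), "seed")
  expect_error(archipelago_config(area_range_ha = c(10, 1), seed = 1),
               "area range")
  expect_error(archipelago_config(nestedness_knob = 1.2, seed = 1), "knobs")
  expect_error(archipelago_config(n_islands = 0, seed = 1), "counts")
  cfg <- archipelago_config(seed = 1)
  expect_s3_class(cfg, "archipelago_config")
})

test_that("island tables respect bounds, sizes and the seed", {
  cfg1 <- archipelago_config(n_islands = 1, seed = 4)
  expect_equal(nrow(generate_archipelago(cfg1)), 1L)
  cfg <- default_test_config(seed = 10)
  a <- generate_archipelago(cfg)
  b <- generate_archipelago(cfg)
  expect_identical(a, b)  # same seed, byte-identical
  big <- generate_archipelago(archipelago_config(
    n_islands = 10000, area_range_ha = c(0.59, 1289.23), seed = 3))
  expect_gte(min(big$area_ha), 0.59)
  expect_lte(max(big$area_ha), 1289.23)
  expect_gte(min(big$isolation_m), archipelago_config(seed = 1)$isolation_range_m[1])
  # proportional sampling: transect count scales by area decade
  expect_equal(unique(big$transects[big$area_ha < 10]), 1L)
  expect_equal(unique(big$transects[big$area_ha > 10 & big$area_ha < 100]), 2L)
  expect_equal(unique(big$transects[big$area_ha > 100 & big$area_ha < 1000]), 4L)
  expect_equal(big$camera_days, big$transects * 414L)
})

test_that("pure kernels give strict nestedness or the analytic block Q", {
  cfg <- archipelago_config(n_plants = 12, n_birds = 16,
                            nestedness_knob = 1, modularity_knob = 0,
                            seed = 5)
  isl <- generate_archipelago(cfg)
  sys <- generate_species_system(cfg, isl)
  K <- sys$truth$propensity
  # row supports form chains: each later row's support is a subset
  for (p in 2:nrow(K)) {
    sup_prev <- which(K[p - 1, ] > 0)
    sup <- which(K[p, ] > 0)
    expect_true(all(sup %in% sup_prev))
  }
  for (b in 2:ncol(K)) {
    expect_true(all(which(K[, b] > 0) %in% which(K[, b - 1] > 0)))
  }
  cfgm <- archipelago_config(n_plants = 12, n_birds = 16,
                             nestedness_knob = 0, modularity_knob = 1,
                             n_modules = 4, seed = 5)
  sysm <- generate_species_system(cfgm, generate_archipelago(cfgm))
  Q <- barber_modularity(sysm$truth$propensity,
                         sysm$truth$plant_modules, sysm$truth$bird_modules)
  expect_equal(Q, 0.75)  # 1 - 1/k for k equal blocks
})

test_that("richness rises with log area when the SAR exponent is positive", {
  rhos <- vapply(1:20, function(s) {
    cfg <- archipelago_config(n_islands = 15, n_plants = 20, n_birds = 20,
                              sar_exponent = 2, seed = 100 + s)
    isl <- generate_archipelago(cfg)
    sys <- generate_species_system(cfg, isl)
    rich <- rowSums(sys$truth$plant_occ) + rowSums(sys$truth$bird_occ)
    cor(rich, log(isl$area_ha), method = "spearman")
  }, numeric(1))
  expect_gt(mean(rhos), 0)
  expect_gt(mean(rhos > 0), 0.8)
})

test_that("event streams follow the Poisson budget and burst contract", {
  cfg <- archipelago_config(n_islands = 2, n_plants = 6, n_birds = 6,
                            detection_rate_per_day = 0, seed = 6)
  isl <- generate_archipelago(cfg)
  sys <- generate_species_system(cfg, isl)
  expect_equal(nrow(generate_event_log(sys$truth, isl, cfg)), 0L)
  # burst_prob = 0: the independence filter leaves the count unchanged
  # (detections are sparse enough that chance sub-5-min pairs are absent)
  cfg0 <- archipelago_config(n_islands = 2, n_plants = 6, n_birds = 6,
                             burst_prob = 0, camera_days_per_island = 40,
                             detection_rate_per_day = 0.5, seed = 7)
  isl0 <- generate_archipelago(cfg0)
  sys0 <- generate_species_system(cfg0, isl0)
  ev0 <- generate_event_log(sys0$truth, isl0, cfg0)
  expect_equal(attr(ev0, "n_burst"), 0L)
  expect_equal(nrow(filter_independent_events(ev0)), nrow(ev0))
  # timestamps strictly increasing per camera
  with_burst <- archipelago_config(n_islands = 2, n_plants = 6, n_birds = 6,
                                   burst_prob = 0.5, seed = 8,
                                   camera_days_per_island = 50,
                                   detection_rate_per_day = 2)
  islb <- generate_archipelago(with_burst)
  sysb <- generate_species_system(with_burst, islb)
  evb <- generate_event_log(sysb$truth, islb, with_burst)
  for (cam in unique(evb$camera_id)) {
    tt <- evb$timestamp[evb$camera_id == cam]
    if (length(tt) > 1) expect_true(all(diff(as.numeric(tt)) > 0))
  }
  # event conservation: raw records = independent events + merged records
  ind <- filter_independent_events(evb)
  expect_equal(sum(ind$n_merged), nrow(evb))
  expect_equal(attr(ind, "n_raw"), nrow(evb))
  # Poisson expectation: mean raw count within 3 SE of camera_days x rate
  # (uniform propensity kernel, so every occupied pair can interact and the
  # only randomness in the count is the Poisson draw)
  cfgp <- archipelago_config(n_islands = 1, n_plants = 4, n_birds = 4,
                             area_range_ha = c(1, 9),  # 1 transect
                             camera_days_per_island = 100,
                             detection_rate_per_day = 2, burst_prob = 0,
                             nestedness_knob = 0, modularity_knob = 0,
                             seed = 1)
  counts <- vapply(1:300, function(s) {
    cfgs <- cfgp
    cfgs$seed <- 1000L + s
    isl <- generate_archipelago(cfgs)
    sys <- generate_species_system(cfgs, isl)
    nrow(generate_event_log(sys$truth, isl, cfgs))
  }, numeric(1))
  expect_lt(abs(mean(counts) - 200), 3 * sqrt(200 / 300))
})

test_that("generator knobs steer the propensity kernel monotonically", {
  # kernel-level check (deterministic): more nestedness weight raises the
  # weighted nestedness of the propensity matrix, more modularity weight
  # raises the Barber Q of the true block partition; the downstream
  # z-score response over replicate archipelagos is covered by the
  # end-to-end recovery test
  truth_of <- function(nest, mod) {
    cfg <- archipelago_config(n_plants = 10, n_birds = 12,
                              nestedness_knob = nest, modularity_knob = mod,
                              n_modules = 3, seed = 1)
    generate_species_system(cfg, generate_archipelago(cfg))$truth
  }
  knobs <- c(0.1, 0.5, 0.9)
  wn <- vapply(knobs, function(k)
    wnodf(truth_of(k, 0.5)$propensity * 1000), numeric(1))
  expect_true(all(diff(wn) > 0))
  qq <- vapply(knobs, function(k) {
    tr <- truth_of(0.5, k)
    barber_modularity(tr$propensity, tr$plant_modules, tr$bird_modules)
  }, numeric(1))
  expect_true(all(diff(qq) > 0))
})
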