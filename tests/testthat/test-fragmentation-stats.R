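test_that("metric regressions recover exact and simulated slopes", {
  tab <- data.frame(island_id = sprintf("I%02d", 1:12),
                    area_ha = 10^seq(0, 3, length.out = 12),
                    isolation_m = c(800, 2100, 1500, 3000, 950, 1200,
                                    2500, 700, 1800, 2900, 1100, 1600))
  tab$n_species <- 10^(2 * log10(tab$area_ha))  # exact y = 2 log10(area)
  f <- fit_metric_model(tab, "n_species")
  expect_equal(unname(f$coefficients["log10_area_ha"]), 2)
  expect_lt(max(abs(residuals(f$fit))), 1e-10)
  tab$connectance_z <- 3.7  # constant response: all slopes 0
  fc <- fit_metric_model(tab, "connectance_z")
  expect_equal(unname(fc$coefficients[-1]), c(0, 0))
  # coverage: 95% CIs catch the true slopes in >= 90% of replicates
  set.seed(1)
  covered <- replicate(100, {
    n <- 200
    d <- data.frame(island_id = seq_len(n),
                    area_ha = 10^runif(n, 0, 3),
                    isolation_m = 10^runif(n, 2.8, 3.5))
    d$n_links <- 10^(0.3 + 0.5 * log10(d$area_ha) -
                       0.2 * log10(d$isolation_m) + rnorm(n, 0, 0.2))
    ci <- confint(fit_metric_model(d, "n_links")$fit)
    all(ci[2:3, 1] <= c(0.5, -0.2) & c(0.5, -0.2) <= ci[2:3, 2])
  })
  expect_gte(mean(covered), 0.9)
})

test_that("SAR and IAR slopes separate when built differently", {
  tab <- data.frame(area_ha = 10^seq(0, 3, length.out = 10))
  tab$n_species <- round(10^(0.5 + 0.25 * log10(tab$area_ha)))
  tab$n_links <- tab$n_species  # identical columns: zero difference
  s0 <- sar_iar_slopes(tab)
  expect_equal(s0$difference, 0)
  set.seed(2)
  n <- 100
  tab2 <- data.frame(area_ha = 10^runif(n, 0, 3))
  tab2$n_species <- 10^(0.6 + 0.25 * log10(tab2$area_ha) + rnorm(n, 0, 0.08))
  tab2$n_links <- 10^(0.4 + 0.50 * log10(tab2$area_ha) + rnorm(n, 0, 0.08))
  s <- sar_iar_slopes(tab2)
  expect_equal(s$sar_slope, 0.25, tolerance = 0.15)
  expect_equal(s$iar_slope, 0.50, tolerance = 0.15)
  expect_gt(s$difference, 0)
  expect_lt(s$p_difference, 0.05)
  expect_error(sar_iar_slopes(tab2[1, ]), "two islands")
  tab2$n_links[1] <- 0
  expect_warning(sar_iar_slopes(tab2), "dropped")
})

test_that("pearson matches the covariance formula and flags degenerate input", {
  x <- 1:8
  expect_equal(pearson(x, x * 2)$r, 1)
  expect_equal(pearson(x, -x)$r, -1)
  set.seed(4)
  a <- rnorm(10)
  b <- 0.3 * a + rnorm(10)
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson(a, b)$r, r_hand)
  expect_error(pearson(a, rep(1, 10)), "variance")
  expect_error(pearson(1:2, 1:2), "n >= 3")
})

test_that("connectivity indices follow the incidence-function closed forms", {
  one <- data.frame(island_id = "I01", x = 0, y = 0, area_ha = 5)
  c1 <- connectivity_indices(one)
  expect_equal(unlist(c1[-1]), setNames(rep(0, 6), names(unlist(c1[-1]))))
  # two islands, distance d, equal areas: S = exp(-alpha d) * A^b
  two <- data.frame(island_id = c("A", "B"), x = c(0, 3000), y = 0,
                    area_ha = c(7, 7))
  alpha <- 1 / 1000
  c2 <- connectivity_indices(two, alpha = alpha)
  expect_equal(c2$conn_a1, rep(exp(-3) * 7, 2))
  expect_equal(c2$conn_a0, rep(exp(-3), 2))
  # three islands: hand-summed values
  tri <- data.frame(island_id = c("A", "B", "C"), x = c(0, 1000, 0),
                    y = c(0, 0, 2000), area_ha = c(4, 9, 25))
  c3 <- connectivity_indices(tri, alpha = alpha)
  dAB <- 1000; dAC <- 2000; dBC <- sqrt(1000^2 + 2000^2)
  expect_equal(c3$conn_a1[1], exp(-dAB / 1000) * 9 + exp(-dAC / 1000) * 25)
  expect_equal(c3$conn_a0.5[2], exp(-dAB / 1000) * 2 + exp(-dBC / 1000) * 5)
  # similarity-weighted variant bounded by the unweighted one
  comp <- data.frame(island_id = rep(c("A", "B", "C"), each = 2),
                     plant_species = c("P1", "P2", "P1", "P3", "P2", "P3"),
                     abundance = c(5, 2, 4, 1, 3, 3))
  c3s <- connectivity_indices(tri, comp, alpha = alpha)
  expect_true(all(c3s$conn_sim_a1 <= c3s$conn_a1 + 1e-12))
  # non-increasing in alpha
  c3b <- connectivity_indices(tri, alpha = alpha * 2)
  expect_true(all(c3b$conn_a1 <= c3$conn_a1))
})

test_that("indirect effects multiply path coefficients", {
  expect_equal(round(indirect_effect(c(-0.75, 0.57)), 2), -0.43)
  expect_equal(indirect_effect(c(0.3, 0, -2)), 0)
  expect_equal(indirect_effect(c(1, 1, 1)), 1)
  expect_error(indirect_effect(numeric(0)), "empty")
})

test_that("piecewise SEM handles saturated DAGs and known basis-set arithmetic", {
  set.seed(6)
  n <- 60
  d <- data.frame(a = rnorm(n))
  d$b <- 0.5 * d$a + rnorm(n)
  d$c <- 0.5 * d$b + rnorm(n)
  sat <- data.frame(from = c("a", "a", "b"), to = c("b", "c", "c"))
  fit_sat <- piecewise_sem(sat, d)
  expect_equal(fit_sat$fisher_c, 0)
  expect_equal(fit_sat$p_value, 1)
  expect_equal(nrow(fit_sat$claims), 0L)
  # chain a -> b -> c: one claim (a, c | b), df = 2
  chain <- data.frame(from = c("a", "b"), to = c("b", "c"))
  fit_chain <- piecewise_sem(chain, d)
  expect_equal(fit_chain$df, 2L)
  expect_equal(fit_chain$fisher_c, -2 * sum(log(fit_chain$claims$p)))
  # Fisher's C arithmetic for known p-values
  expect_equal(-2 * (log(0.5) + log(0.5)), 2.7726, tolerance = 1e-4)
  expect_error(piecewise_sem(data.frame(from = c("a", "b"), to = c("b", "a")),
                             d), "cyclic")
})

test_that("piecewise SEM recovers generative coefficients and is calibrated", {
  # DAG shaped like the fragmentation hypothesis: two exogenous drivers,
  # three structure variables, one stability response
  edges <- default_sem_edges()
  # recovery as a calibration check: the mean estimate over replicate
  # samples of n = 500 must sit within +-0.1 of the standardised truth for
  # every path (a single draw's worst-of-13 noise is itself ~0.1)
  set.seed(7)
  errs <- replicate(25, {
    d <- sem_generative(500)
    fit <- piecewise_sem(edges, d)
    mapply(function(fr, to, est) est - sem_std_truth(fr, to, d),
           fit$coefficients$from, fit$coefficients$to,
           fit$coefficients$estimate)
  })
  expect_lt(max(abs(rowMeans(errs))), 0.1)
  expect_equal(ncol(errs), 25L)
  # Fisher's C p-values ~ Uniform(0,1) under the true DAG
  set.seed(8)
  ps <- replicate(150, piecewise_sem(edges, sem_generative(60))$p_value)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})
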