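test_that("removal orders follow scenario semantics and are seeded", {
  M <- mat(rep(1, 9), 3, plants = c("A", "B", "C"))
  ab <- c(A = 10, B = 5, C = 1)
  expect_equal(removal_order("worst", M, abundances = ab)$order,
               c("A", "B", "C"))
  expect_equal(removal_order("best", M, abundances = ab)$order,
               c("C", "B", "A"))
  M2 <- mat(rep(1, 4), 2, birds = c("X", "Y"))
  mass <- c(X = 120, Y = 15)
  so <- removal_order("size", M2, body_masses = mass)
  expect_equal(so$order, c("X", "Y"))
  expect_equal(so$guild, "birds")
  r1 <- removal_order("random", M, seed = 77)$order
  expect_equal(removal_order("random", M, seed = 77)$order, r1)
  expect_error(removal_order("worst", M, abundances = ab[-2]), "B")
  expect_error(removal_order("size", M2, body_masses = mass[1]), "Y")
})

test_that("extinction curves match analytic cases and a hand-traced cascade", {
  D <- diag(5) * c(2, 1, 3, 1, 4)
  dimnames(D) <- list(paste0("P", 1:5), paste0("B", 1:5))
  cv <- coextinction_curve(D, sample(rownames(D)))
  expect_equal(cv$curve$fraction_surviving, 1 - (0:5) / 5)
  Fm <- mat(rep(1, 25), 5)
  cf <- coextinction_curve(Fm, rownames(Fm))
  expect_equal(cf$curve$fraction_surviving, c(rep(1, 5), 0))
  # hand-traced: B1 eats P1,P2; B2 eats P2; B3 eats P3
  M <- mat(c(1, 0, 0,
             2, 3, 0,
             0, 0, 4), 3)
  cv <- coextinction_curve(M, c("P2", "P1", "P3"))
  # drop P2: B2 starves -> 2/3; drop P1: B1 starves -> 1/3; drop P3 -> 0
  expect_equal(cv$curve$fraction_surviving, c(1, 2 / 3, 1 / 3, 0))
  expect_error(coextinction_curve(M, c("P1", "P2")), "permutation")
})

test_that("robustness area is the trapezoid under the curve", {
  expect_equal(robustness_area(data.frame(fraction_removed = c(0, 0.5, 1),
                                          fraction_surviving = c(1, 0.5, 0))),
               0.5)
  D <- diag(7)
  dimnames(D) <- list(paste0("P", 1:7), paste0("B", 1:7))
  expect_equal(robustness_area(coextinction_curve(D, rownames(D))), 0.5)
  for (n in c(3, 5)) {
    Fm <- mat(rep(1, n * n), n)
    expect_equal(robustness_area(coextinction_curve(Fm, rownames(Fm))),
                 1 - 1 / (2 * n))
  }
  expect_error(robustness_area(data.frame(fraction_removed = c(0, 0.4),
                                          fraction_surviving = c(1, 1))),
               "malformed")
})

test_that("repeated simulations average correctly over removal orders", {
  M <- mat(c(3, 1, 0, 0, 2, 5), 2, plants = c("A", "B"))
  ab <- c(A = 9, B = 2)
  sim <- simulate_robustness(M, "worst", abundances = ab, reps = 20, seed = 1)
  expect_equal(sim$sd_R, 0)
  D <- diag(5)
  dimnames(D) <- list(paste0("P", 1:5), paste0("B", 1:5))
  simd <- simulate_robustness(D, "random", reps = 50, seed = 2)
  expect_equal(simd$mean_R, 0.5)
  expect_equal(simd$sd_R, 0)
  # exact mean over all 2! plant orders on a 2x3 fixture: average of the
  # implementation's R over the enumerated orders equals the hand-cascade mean
  impl_mean <- mean(c(
    robustness_area(coextinction_curve(M, c("A", "B"))),
    robustness_area(coextinction_curve(M, c("B", "A")))))
  expect_equal(impl_mean, enumerate_random_R(M))
  sim2 <- simulate_robustness(M, "random", reps = 400, seed = 3)
  expect_lt(abs(sim2$mean_R - impl_mean),
            3 * max(sim2$sd_R, 1e-9) / sqrt(400))
  # 3-plant fixture: estimate within Monte Carlo error of enumeration
  M3 <- mat(c(1, 1, 0, 0, 2, 1, 3, 0, 0, 0, 0, 4), 3)
  sim3 <- simulate_robustness(M3, "random", reps = 600, seed = 4)
  exact <- enumerate_random_R(M3)
  expect_lt(abs(sim3$mean_R - exact), 3 * sim3$sd_R / sqrt(600))
})

test_that("adding an interaction never lowers the curve for a fixed order", {
  set.seed(21)
  for (rep in 1:10) {
    M <- matrix(rpois(20, 0.9), 4, 5)
    M[cbind(1:4, sample(5, 4, TRUE))] <- M[cbind(1:4, sample(5, 4, TRUE))] + 1
    M[cbind(sample(4, 5, TRUE), 1:5)] <- M[cbind(sample(4, 5, TRUE), 1:5)] + 1
    dimnames(M) <- list(paste0("P", 1:4), paste0("B", 1:5))
    ord <- sample(rownames(M))
    zero <- which(M == 0)
    if (!length(zero)) next
    M2 <- M
    M2[sample(zero, 1)] <- 1
    y1 <- coextinction_curve(M, ord)$curve$fraction_surviving
    y2 <- coextinction_curve(M2, ord)$curve$fraction_surviving
    expect_true(all(y2 >= y1))
  }
})

test_that("best-case beats worst-case when abundance rank equals degree rank", {
  # P1 most abundant and most connected, degrees strictly decreasing
  M <- mat(c(1, 1, 1, 1,
             1, 1, 1, 0,
             1, 1, 0, 0,
             1, 0, 0, 0), 4)
  ab <- c(P1 = 40, P2 = 30, P3 = 20, P4 = 10)
  Rw <- simulate_robustness(M, "worst", abundances = ab, reps = 2, seed = 1)$mean_R
  Rb <- simulate_robustness(M, "best", abundances = ab, reps = 2, seed = 1)$mean_R
  expect_gte(Rb, Rw)
})
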