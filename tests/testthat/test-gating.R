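# gating-spring and CAP fitting; N-z homeostasis

XGRID <- seq(-1500e-9, 1800e-9, length.out = 200)

test_that("noiseless gating-spring fit recovers all parameters to 1e-4 relative", {
  tr <- gating_truth(N_s = 80, z_s = 50e-15, N_i = 200, z_i = 15e-15,
                     K_steady = 30e-6, K_GS = 30e-6, X0_s = 0,
                     X0_i = 300e-9, noise_sd = 0)
  fit <- fit_gating_spring(simulate_stiffness_curve(tr, XGRID))
  expect_true(fit$converged)
  expect_lt(abs(fit$N_s - 80) / 80, 1e-4)
  expect_lt(abs(fit$z_s - 50e-15) / 50e-15, 1e-4)
  expect_lt(abs(fit$N_i - 200) / 200, 1e-4)
  expect_lt(abs(fit$z_i - 15e-15) / 15e-15, 1e-4)
  expect_lt(abs(fit$K_total - 60e-6) / 60e-6, 1e-4)
  expect_lt(abs(fit$X0_i - 300e-9) / 300e-9, 1e-3)
})

test_that("population labels follow the |z_s| > |z_i| convention regardless of truth order", {
  tr_a <- gating_truth(N_s = 80, z_s = 50e-15, X0_s = 0,
                       N_i = 800, z_i = 15e-15, X0_i = 300e-9, noise_sd = 0)
  # swap the populations in the truth: same curve, same labelled fit
  tr_b <- gating_truth(N_s = 800, z_s = 15e-15, X0_s = 300e-9,
                       N_i = 80, z_i = 50e-15, X0_i = 0, noise_sd = 0)
  fa <- fit_gating_spring(simulate_stiffness_curve(tr_a, XGRID))
  fb <- fit_gating_spring(simulate_stiffness_curve(tr_b, XGRID))
  expect_gt(fa$z_s, fa$z_i)
  expect_gt(fb$z_s, fb$z_i)
  expect_equal(fa$N_s, fb$N_s, tolerance = 1e-6)
  expect_equal(fa$z_i, fb$z_i, tolerance = 1e-6)
})

test_that("a channel-free curve fits to N = 0 with the constant level, no spurious dips", {
  tr <- gating_truth(N_s = 0, N_i = 0, z_s = 1e-15, z_i = 1e-15,
                     noise_sd = 0.5e-6, seed = 41)
  fit <- fit_gating_spring(simulate_stiffness_curve(tr, XGRID))
  expect_equal(fit$N_s, 0)
  expect_equal(fit$N_i, 0)
  expect_lt(abs(fit$K_total - 60e-6) / 60e-6, 0.02)
})

test_that("dip-depth identity: the fitted K deficit at X0_j equals N_j z_j^2 / (4 kB T)", {
  tr <- gating_truth(N_i = 800, noise_sd = 1.2e-6, seed = 42)
  fit <- fit_gating_spring(simulate_stiffness_curve(tr, XGRID))
  kT <- KB * T_ROOM
  for (j in c("s", "i")) {
    N <- fit[[paste0("N_", j)]]
    z <- fit[[paste0("z_", j)]]
    X0 <- fit[[paste0("X0_", j)]]
    # own-population deficit of the fitted curve at its set point
    other <- setdiff(c("s", "i"), j)
    K_at <- gating_spring_K(X0, fit$K_total, c(fit[[paste0("N_", other)]]),
                            c(fit[[paste0("z_", other)]]),
                            c(fit[[paste0("X0_", other)]]), T_ROOM)
    own_deficit <- K_at - gating_spring_K(
      X0, fit$K_total, c(N, fit[[paste0("N_", other)]]),
      c(z, fit[[paste0("z_", other)]]),
      c(X0, fit[[paste0("X0_", other)]]), T_ROOM)
    expect_equal(own_deficit, N * z^2 / (4 * kT), tolerance = 1e-10)
  }
})

test_that("K_total is stable (within 2%) with and without gating populations", {
  Kt <- 60e-6
  tr_gated <- gating_truth(N_i = 800, noise_sd = 1.2e-6, seed = 43)
  tr_flat <- gating_truth(N_s = 0, N_i = 0, z_s = 1e-15, z_i = 1e-15,
                          noise_sd = 1.2e-6, seed = 43)
  f_gated <- fit_gating_spring(simulate_stiffness_curve(tr_gated, XGRID))
  f_flat <- fit_gating_spring(simulate_stiffness_curve(tr_flat, XGRID))
  expect_lt(abs(f_gated$K_total - Kt) / Kt, 0.02)
  expect_lt(abs(f_flat$K_total - Kt) / Kt, 0.02)
})

test_that("noisy Monte-Carlo recovery: median estimates within 10% (N, z) and 2% (K_total)", {
  # reduced seed count; the 50-seed version runs in the acceptance suite
  Xg <- seq(-900e-9, 1500e-9, length.out = 200)
  est <- t(vapply(1:15, function(s) {
    tr <- gating_truth(N_i = 800, noise_sd = 0.02 * 60e-6, seed = s)
    f <- fit_gating_spring(simulate_stiffness_curve(tr, Xg))
    c(f$N_s, f$z_s, f$N_i, f$z_i, f$K_total)
  }, numeric(5)))
  tru <- c(80, 50e-15, 800, 15e-15, 60e-6)
  med <- apply(est, 2, median)
  expect_true(all(abs(med[1:4] - tru[1:4]) / tru[1:4] < 0.10))
  expect_lt(abs(med[5] - tru[5]) / tru[5], 0.02)
})

test_that("noiseless CAP double sigmoid is recovered exactly", {
  A <- c(1.5, 2.5)
  x50 <- c(150e-9, 600e-9)
  w <- c(40e-9, 120e-9)
  cv <- simulate_cap_curve(A, x50, w, seq(0, 2e-6, length.out = 60))
  fit <- fit_cap(cv)
  expect_true(fit$converged)
  expect_lt(abs(fit$A_s - A[1]) / A[1], 1e-6)
  expect_lt(abs(fit$A_i - A[2]) / A[2], 1e-6)
  expect_lt(abs(fit$X50_s - x50[1]) / x50[1], 1e-6)
  expect_lt(abs(fit$X50_i - x50[2]) / x50[2], 1e-6)
  expect_lt(abs(fit$w_s - w[1]) / w[1], 1e-6)
  expect_lt(abs(fit$w_i - w[2]) / w[2], 1e-6)
})

test_that("single-population CAP truth fits with A_i at most 5% of A_s", {
  cv <- simulate_cap_curve(c(3, 0), c(200e-9, 900e-9), c(50e-9, 50e-9),
                           seq(0, 2e-6, length.out = 40),
                           noise_sd = 0.02 * 3, replicates = 5, seed = 44)
  fit <- fit_cap(cv)
  expect_lte(fit$A_i, 0.05 * fit$A_s)
})

test_that("CAP fit computes per-level medians and recovers parameters from noisy replicates", {
  A <- c(1, 2)
  cv <- simulate_cap_curve(A, c(150e-9, 600e-9), c(40e-9, 120e-9),
                           seq(0, 2e-6, length.out = 30),
                           noise_sd = 0.02 * 3, replicates = 7, seed = 45)
  fit <- fit_cap(cv)
  # medians equal the level-wise sample medians by definition
  lev <- sort(unique(abs(cv$X_m)))
  expect_equal(fit$medians$cap_median,
               vapply(lev, function(l) median(cv$cap[abs(cv$X_m) == l]),
                      numeric(1)))
  # round-trip at 2% noise: parameters within 10%
  expect_lt(abs(fit$A_s - 1) / 1, 0.10)
  expect_lt(abs(fit$A_i - 2) / 2, 0.10)
  expect_lt(abs(fit$X50_s - 150e-9) / 150e-9, 0.10)
  expect_lt(abs(fit$X50_i - 600e-9) / 600e-9, 0.10)
})

test_that("CAP fit requires >= 8 levels and flags non-monotonic medians", {
  cv <- simulate_cap_curve(c(1, 1), c(100e-9, 500e-9), c(30e-9, 80e-9),
                           seq(0, 1e-6, length.out = 5))
  expect_error(fit_cap(cv), ">= 8")
  bad <- data.frame(X_m = seq(0, 1e-6, length.out = 12),
                    cap = c(0, 0.1, 0.5, 1, 2, 1, 2.5, 3, 3, 3, 3, 3))
  expect_warning(fit_cap(bad), "decrease")
})

test_that("N-z homeostasis: constant N z^2 family gives r = -1 exactly with zero CV", {
  z <- seq(10e-15, 60e-15, length.out = 12)
  N <- 4e-25 / z^2                     # N z^2 held exactly constant
  h <- nz_homeostasis(N, z)
  expect_equal(h$r, -1, tolerance = 1e-12)
  expect_equal(h$nz2_cv, 0, tolerance = 1e-12)
})

test_that("independent N and z are uncorrelated: |r| < 0.3 in >= 90% of seeds at n = 50", {
  ok <- vapply(1:40, function(s) {
    set.seed(s)
    abs(nz_homeostasis(rlnorm(50, log(100), 0.4),
                       rlnorm(50, log(40e-15), 0.3))$r) < 0.3
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("ageing with N halving and z scaled by sqrt(2) keeps the nonlinearity depth", {
  # direction of the homeostatic compensation: N down ~50%, z up, N z^2 flat
  N_young <- 120
  z_young <- 40e-15
  N_old <- N_young / 2
  z_old <- z_young * sqrt(2)
  expect_lt(N_old, N_young)
  expect_gt(z_old, z_young)
  expect_equal(N_old * z_old^2, N_young * z_young^2, tolerance = 1e-12)
  # and the correlation analysis sees the inverse relation
  ages <- seq(0, 1, length.out = 8)
  N <- N_young * (0.5 + 0.5 * (1 - ages))
  z <- z_young * sqrt(N_young / N)
  h <- nz_homeostasis(N, z)
  expect_equal(h$r, -1, tolerance = 1e-10)
})

test_that("homeostasis correlation requires at least 5 pairs", {
  expect_error(nz_homeostasis(c(1, 2, 3, 4), c(1, 2, 3, 4)), ">= 5")
})
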