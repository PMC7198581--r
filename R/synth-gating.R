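#' Ground-truth parameters for a gating-spring stiffness curve
#'
#' Two transducer-channel populations (sensitive `s`, insensitive `i`) each
#' contribute a gating compliance: a localized dip in the receiver's slope
#' stiffness of depth `N*z^2/(4*kB*T)` at the population's set point. `N_j` is
#' the channel count, `z_j` the single-channel gating force and `X0_j` the
#' set-point displacement. `K_steady` is the transducer-independent stiffness
#' of the antennal joint and `K_GS` the gating-spring stiffness; only their
#' sum enters the stiffness curve.
#'
#' @param K_steady,K_GS stiffnesses, N/m (> 0)
#' @param N_s,N_i channel counts (>= 0)
#' @param z_s,z_i single-channel gating forces, N (> 0 where N > 0)
#' @param X0_s,X0_i set-point displacements, m
#' @param temperature bath temperature, K
#' @param noise_sd additive Gaussian measurement noise on K, N/m
#' @param seed integer seed
#' @return an object of class `gating_truth`
#' @export
gating_truth <- function(K_steady = 30e-6, K_GS = 30e-6,
                         N_s = 80, z_s = 50e-15, X0_s = 0,
                         N_i = 800, z_i = 15e-15, X0_i = 300e-9,
                         temperature = T_ROOM, noise_sd = 0, seed = 1L) {
  stop_if_not_finite(c(K_steady, K_GS, N_s, N_i, X0_s, X0_i,
                       temperature, noise_sd), "gating truth")
  if (K_steady <= 0 || K_GS <= 0) stop("stiffnesses must be > 0")
  if (N_s < 0 || N_i < 0) stop("channel counts must be >= 0")
  if (N_s > 0 && z_s <= 0) stop("z_s must be > 0 when N_s > 0")
  if (N_i > 0 && z_i <= 0) stop("z_i must be > 0 when N_i > 0")
  kT <- KB * temperature
  dip <- N_s * z_s^2 / (4 * kT) + N_i * z_i^2 / (4 * kT)
  if (K_steady + K_GS - dip <= 0)
    stop("gating compliance exceeds linear stiffness: K(X) would go negative")
  structure(list(K_steady = K_steady, K_GS = K_GS,
                 N_s = N_s, z_s = z_s, X0_s = X0_s,
                 N_i = N_i, z_i = z_i, X0_i = X0_i,
                 temperature = temperature, noise_sd = noise_sd,
                 seed = seed),
            class = "gating_truth")
}

#' Closed-form gating-spring stiffness
#'
#' Evaluates `K(X) = K_total - sum_j N_j z_j^2/(kB T) p_j (1 - p_j)` with
#' `p_j` the two-state Boltzmann open probability; the deficit at a
#' population's set point is `N z^2 / (4 kB T)`.
#'
#' @param X displacements, m
#' @param K_total `K_steady + K_GS`, N/m
#' @param N,z,X0 per-population channel counts, gating forces (N) and set
#'   points (m); equal-length vectors
#' @param temperature bath temperature, K
#' @return stiffness values K(X), N/m
#' @export
gating_spring_K <- function(X, K_total, N, z, X0, temperature) {
  kT <- KB * temperature
  K <- rep(K_total, length(X))
  for (j in seq_along(N)) {
    if (N[j] <= 0) next
    p <- stats::plogis(z[j] * (X - X0[j]) / kT)
    K <- K - N[j] * z[j]^2 / kT * p * (1 - p)
  }
  K
}

#' Simulate a dynamic stiffness vs. displacement curve
#'
#' Evaluates the two-population gating-spring form
#' \deqn{K(X) = K_{steady} + K_{GS} - \sum_j \frac{N_j z_j^2}{k_B T} p_j(X)(1-p_j(X)),
#'   \quad p_j(X) = \frac{1}{1+e^{-z_j (X - X_{0,j})/k_B T}}}
#' on `X_grid` and adds Gaussian measurement noise of sd `noise_sd`.
#'
#' @param truth a [gating_truth()] object
#' @param X_grid peak displacements, m; must have >= 15 points and cover
#'   `[X0_j - 4 kB T/z_j, X0_j + 4 kB T/z_j]` for each active population
#' @return a `stiffness_curve` data.frame with columns `X_m`, `K_N_per_m`
#'   (attributes carry the truth and temperature)
#' @export
simulate_stiffness_curve <- function(truth, X_grid) {
  stopifnot(inherits(truth, "gating_truth"))
  if (length(X_grid) < 15) stop("X_grid must have >= 15 points")
  kT <- KB * truth$temperature
  for (j in c("s", "i")) {
    N <- truth[[paste0("N_", j)]]
    if (N <= 0) next
    z <- truth[[paste0("z_", j)]]
    X0 <- truth[[paste0("X0_", j)]]
    span <- 4 * kT / z
    if (min(X_grid) > X0 - span || max(X_grid) < X0 + span)
      stop("X_grid does not cover [X0 - 4 kBT/z, X0 + 4 kBT/z] for population ",
           j, " (unidentifiable)")
  }
  K0 <- gating_spring_K(X_grid, truth$K_steady + truth$K_GS,
                        c(truth$N_s, truth$N_i), c(truth$z_s, truth$z_i),
                        c(truth$X0_s, truth$X0_i), truth$temperature)
  noise <- if (truth$noise_sd > 0)
    with_seed(truth$seed, rnorm(length(X_grid), sd = truth$noise_sd))
  else 0
  out <- data.frame(X_m = X_grid, K_N_per_m = K0 + noise)
  attr(out, "truth") <- truth
  attr(out, "temperature") <- truth$temperature
  class(out) <- c("stiffness_curve", "data.frame")
  out
}

#' Simulate a compound action potential (CAP) response curve
#'
#' CAP amplitude vs. absolute antennal displacement is modelled as the sum of
#' two sigmoids, one per transducer population:
#' `CAP(|X|) = sum_j A_j / (1 + exp(-(|X| - X50_j)/w_j))`.
#'
#' @param amplitudes numeric length-2, saturation amplitudes `c(A_s, A_i)`
#'   (arbitrary units, >= 0); sensitive population first
#' @param half_points numeric length-2, half-activation displacements
#'   `c(X50_s, X50_i)` in m, with `X50_s < X50_i`
#' @param slopes numeric length-2, sigmoid widths `c(w_s, w_i)` in m (> 0)
#' @param X_grid stimulus displacements, m (absolute values are used)
#' @param noise_sd additive Gaussian noise per replicate, same units as CAP
#' @param replicates noisy replicates per level
#' @param seed integer seed
#' @return a `cap_curve` data.frame with columns `X_m`, `cap`
#' @export
simulate_cap_curve <- function(amplitudes, half_points, slopes, X_grid,
                               noise_sd = 0, replicates = 1L, seed = 1L) {
  stopifnot(length(amplitudes) == 2, length(half_points) == 2,
            length(slopes) == 2)
  if (any(amplitudes < 0)) stop("amplitudes must be >= 0")
  if (any(slopes <= 0)) stop("slopes must be > 0")
  if (half_points[1] >= half_points[2]) stop("X50_s must be < X50_i")
  aX <- rep(abs(X_grid), each = replicates)
  mu <- amplitudes[1] * stats::plogis((aX - half_points[1]) / slopes[1]) +
        amplitudes[2] * stats::plogis((aX - half_points[2]) / slopes[2])
  noise <- if (noise_sd > 0)
    with_seed(seed, rnorm(length(aX), sd = noise_sd)) else 0
  out <- data.frame(X_m = aX, cap = mu + noise)
  attr(out, "truth") <- list(amplitudes = amplitudes,
                             half_points = half_points, slopes = slopes)
  class(out) <- c("cap_curve", "data.frame")
  out
}
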