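#' Oscillator parameter set for free-fluctuation simulation
#'
#' Describes the antennal sound receiver as a damped harmonic oscillator with
#' total linear stiffness `K`, best frequency `f0` and quality factor `Q`,
#' driven by white thermal force noise at an effective temperature `T_eff`.
#' For a passive (e.g. dead) receiver `T_eff = T`; active energy injection by
#' the auditory neurons is modelled as `T_eff > T`, so that the receiver's
#' mean elastic energy is `kB*T_eff` instead of `kB*T`.
#'
#' @param f0 best frequency, Hz (> 0)
#' @param Q quality factor, dimensionless (> 0)
#' @param K total linear stiffness, N/m (> 0)
#' @param temperature bath temperature, K
#' @param T_eff effective temperature of the driven system, K; must be
#'   `>= temperature` (equality = passive receiver)
#' @param sample_rate output sampling rate, Hz; must be `>= 20 * f0`
#' @param duration recording duration, s
#' @param seed integer seed; simulation is bit-reproducible given the seed
#' @return an object of class `oscillator_params`
#' @export
oscillator_params <- function(f0 = 250, Q = 1.5, K = 50e-6,
                              temperature = T_ROOM, T_eff = temperature,
                              sample_rate = 10000, duration = 60, seed = 1L) {
  stop_if_not_finite(c(f0, Q, K, temperature, T_eff, sample_rate, duration),
                     "oscillator parameters")
  if (f0 <= 0) stop("f0 must be > 0")
  if (Q <= 0) stop("Q must be > 0")
  if (K <= 0) stop("K must be > 0")
  if (T_eff < temperature)
    stop("T_eff must be >= bath temperature (T_eff = T for a passive receiver)")
  if (sample_rate < 20 * f0)
    stop("sample_rate must be >= 20 * f0 (aliasing)")
  if (duration <= 0) stop("duration must be > 0")
  structure(list(f0 = f0, Q = Q, K = K, temperature = temperature,
                 T_eff = T_eff, sample_rate = sample_rate,
                 duration = duration, seed = seed),
            class = "oscillator_params")
}

#' Simulate free fluctuations of the antennal sound receiver
#'
#' Integrates the stochastic oscillator
#' \deqn{m \ddot x + \gamma \dot x + K x = \xi(t)}
#' with `m`, `gamma` derived from `(f0, Q, K)` via
#' `f0 = sqrt(K/m)/(2*pi)` and `Q = sqrt(m*K)/gamma`, and a white noise force
#' of one-sided spectral density `4*gamma*kB*T_eff`. The state `(x, v)` is
#' advanced with the exact Gaussian one-step update of the linear SDE
#' (matrix-exponential propagator plus the exact step-noise covariance), so
#' the stationary statistics are free of time-discretization bias at any step
#' size; the internal step is nevertheless kept `<= 1/(50*f0)`. The trace is
#' initialised from the stationary distribution and a burn-in of
#' `20*Q/f0` seconds is discarded, so only the stationary portion is returned.
#'
#' For a passive receiver equipartition holds: `K * <x^2> = kB * T`; for the
#' driven system `K * <x^2> = kB * T_eff`.
#'
#' @param params an [oscillator_params()] object
#' @return a `fluctuation_recording`: list with `time_s`, `displacement_m`,
#'   `velocity_m_s` and the generating `params`
#' @export
simulate_fluctuations <- function(params) {
  stopifnot(inherits(params, "oscillator_params"))
  p <- params
  fs <- p$sample_rate
  oversample <- max(1L, as.integer(ceiling(50 * p$f0 / fs)))
  fs_int <- fs * oversample
  dt <- 1 / fs_int

  m <- p$K / (2 * pi * p$f0)^2
  gam <- sqrt(m * p$K) / p$Q
  theta <- gam / m                      # velocity relaxation rate, 1/s
  w0 <- 2 * pi * p$f0

  # exact discretization: s_{n+1} = A s_n + w_n,  w ~ N(0, Sig_dt)
  M <- matrix(c(0, -w0^2, 1, -theta), 2, 2)
  A <- as.matrix(Matrix::expm(M * dt))
  sig_x2 <- KB * p$T_eff / p$K          # stationary <x^2>
  sig_v2 <- KB * p$T_eff / m            # stationary <v^2>
  Sinf <- diag(c(sig_x2, sig_v2))
  Sdt <- Sinf - A %*% Sinf %*% t(A)
  Sdt <- (Sdt + t(Sdt)) / 2
  ev <- eigen(Sdt, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 2)  # Sdt = L L'

  n_out <- round(p$duration * fs)
  n_burn <- as.integer(ceiling(20 * p$Q / p$f0 * fs_int))
  n_int <- n_burn + n_out * oversample + 1L

  with_seed(p$seed, {
    s0 <- c(rnorm(1, sd = sqrt(sig_x2)), rnorm(1, sd = sqrt(sig_v2)))
    z <- matrix(rnorm(2L * n_int), nrow = 2L)
  })
  w <- L %*% z                          # per-step noise, 2 x n_int

  # the position component of the 2-D recursion is an AR(2):
  #   x[n+2] = tr(A) x[n+1] - det(A) x[n] + u[n],
  #   u[n]   = w1[n+1] + a12 w2[n] - a22 w1[n]
  trA <- A[1, 1] + A[2, 2]
  detA <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
  x1 <- s0[1]
  v1 <- s0[2]
  x2 <- A[1, 1] * x1 + A[1, 2] * v1 + w[1, 1]
  nu <- n_int - 1L
  u <- w[1, 2:n_int] + A[1, 2] * w[2, 1:nu] - A[2, 2] * w[1, 1:nu]
  x <- c(x1, x2,
         as.numeric(stats::filter(u, c(trA, -detA), method = "recursive",
                                  init = c(x2, x1))))
  # exact velocity recovered from the position recursion
  v <- c(v1, (x[3:(n_int + 1L)] - A[1, 1] * x[2:n_int] - w[1, 2:n_int]) / A[1, 2])

  keep <- seq.int(n_burn + 1L, by = oversample, length.out = n_out)
  rec <- list(time_s = (seq_len(n_out) - 1L) / fs,
              displacement_m = x[keep],
              velocity_m_s = v[keep],
              params = p)
  class(rec) <- "fluctuation_recording"
  rec
}

#' @export
#' @method print fluctuation_recording
print.fluctuation_recording <- function(x, ...) {
  p <- x$params
  cat(sprintf("fluctuation_recording: %.3g s at %g Hz (f0 = %g Hz, Q = %g, T_eff/T = %.3g)\n",
              p$duration, p$sample_rate, p$f0, p$Q, p$T_eff / p$temperature))
  invisible(x)
}
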