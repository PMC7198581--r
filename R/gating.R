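#' Fit a gating-spring model to a stiffness vs. displacement curve
#'
#' Bounded nonlinear least squares on the two-population gating-spring form
#' (see [simulate_stiffness_curve()] for the closed form). `K_steady` and
#' `K_GS` enter the curve only through their sum, which is what a single
#' stiffness curve identifies; the fit therefore estimates `K_total =
#' K_steady + K_GS` plus per-population `(N_j, z_j, X0_j)`. Populations are
#' labelled by the convention that the sensitive population has the larger
#' single-channel gating force (`z_s > z_i`).
#'
#' Initialisation: gating-compliance dips are located on a running-median
#' smooth of the curve; `z` is initialised from the dip width (`z ~ 4 kB
#' T/width`), `N` from the dip depth (`depth = N z^2 / (4 kB T)`). If no dip
#' deeper than the noise floor is found, a constant (no-gating) fit with
#' `N = 0` is returned rather than a spurious compliance.
#'
#' @param curve a `stiffness_curve` data.frame (columns `X_m`, `K_N_per_m`)
#' @param temperature bath temperature, K
#' @param n_populations 1 or 2 transducer populations
#' @return a `gating_spring_fit`: list with `K_total` (N/m), `N_s`, `z_s`
#'   (N), `X0_s` (m), `N_i`, `z_i`, `X0_i`, `residual` (rms, N/m),
#'   `converged`, `identifiable`, `vcov` (scaled-parameter covariance, or a
#'   matrix of `Inf` when unidentifiable)
#' @export
fit_gating_spring <- function(curve, temperature = T_ROOM,
                              n_populations = 2) {
  stopifnot(all(c("X_m", "K_N_per_m") %in% names(curve)))
  if (!n_populations %in% c(1, 2)) stop("n_populations must be 1 or 2")
  if (nrow(curve) < 15) stop("need >= 15 stiffness points")
  kT <- KB * temperature

  # scaled working units: X in nm, K in uN/m, z in fN
  o <- order(curve$X_m)
  x <- curve$X_m[o] * 1e9
  k <- curve$K_N_per_m[o] * 1e6
  cc <- 1e-24 / kT   # (z_fN * x_nm) in J / kT; also N*z_fN^2*cc = dip in uN/m

  # --- locate dips on a smooth ---
  ks <- stats::runmed(k, k = min(9L, (length(k) %/% 2L) * 2L - 1L))
  k_top <- stats::quantile(ks, 0.95, names = FALSE)
  deficit <- k_top - ks
  noise_mad <- stats::mad(diff(k)) / sqrt(2)
  dips <- find_dips(x, deficit, n_populations)
  identifiable <- TRUE

  if (nrow(dips) == 0 || max(dips$depth) < 3 * max(noise_mad, 1e-9)) {
    # no gating compliance above the noise floor: constant fit, N = 0
    K_total <- mean(k)
    out <- list(K_total = K_total * 1e-6, N_s = 0, z_s = NA_real_,
                X0_s = NA_real_, N_i = 0, z_i = NA_real_, X0_i = NA_real_,
                residual = stats::sd(k) * 1e-6, converged = TRUE,
                identifiable = TRUE, vcov = matrix(0, 1, 1))
    class(out) <- "gating_spring_fit"
    return(out)
  }
  # candidate initialisations: when two populations are requested but only
  # one broad dip is resolved (overlapping compliances), seed the second
  # population on either shoulder of the found dip and keep the better fit
  d1 <- dips[1, ]
  # shoulder-split variants guard against overlapping compliances collapsing
  # into one detected dip; distinct depth/width for the copy, since identical
  # start values for two populations make the initial Jacobian degenerate
  left <- within(d1, {x0 <- x0 - width; depth <- depth / 2; width <- width * 2})
  right <- within(d1, {x0 <- x0 + width; depth <- depth / 2; width <- width * 2})
  dip_sets <- if (nrow(dips) >= n_populations) {
    list(dips, rbind(d1, right), rbind(d1, left))
  } else {
    list(rbind(dips, right), rbind(dips, left))
  }

  make_start <- function(dd) {
    start <- list(lK = log(k_top))
    lower <- c(lK = log(max(min(k) / 4, 1e-6)))
    upper <- c(lK = log(max(k) * 4))
    for (j in seq_len(n_populations)) {
      width <- max(dd$width[j], diff(range(x)) / 50)
      z0 <- 4 / (cc * width)             # z_fN via the 4 kT / width rule
      N0 <- max(4 * dd$depth[j] / (z0^2 * cc), 1)
      start[[paste0("lN", j)]] <- log(N0)
      start[[paste0("lz", j)]] <- log(z0)
      start[[paste0("x0", j)]] <- dd$x0[j]
      lower <- c(lower, log(1e-3), log(z0 / 100), min(x) - diff(range(x)))
      upper <- c(upper, log(1e7), log(z0 * 100), max(x) + diff(range(x)))
    }
    names(lower) <- names(upper) <- names(start)
    list(start = start, lower = lower, upper = upper)
  }

  form <- if (n_populations == 2) {
    kfit ~ exp(lK) -
      exp(lN1) * exp(lz1)^2 * cc * plogis(exp(lz1) * (x - x01) * cc) *
        (1 - plogis(exp(lz1) * (x - x01) * cc)) -
      exp(lN2) * exp(lz2)^2 * cc * plogis(exp(lz2) * (x - x02) * cc) *
        (1 - plogis(exp(lz2) * (x - x02) * cc))
  } else {
    kfit ~ exp(lK) -
      exp(lN1) * exp(lz1)^2 * cc * plogis(exp(lz1) * (x - x01) * cc) *
        (1 - plogis(exp(lz1) * (x - x01) * cc))
  }
  df <- data.frame(x = x, kfit = k, cc = cc)
  fit <- NULL
  best_ssr <- Inf
  for (dd in dip_sets) {
    st <- make_start(dd)
    cand <- try(minpack.lm::nlsLM(form, data = df, start = st$start,
                                  lower = st$lower, upper = st$upper,
                                  control = minpack.lm::nls.lm.control(
                                    maxiter = 1000, ftol = 1e-15,
                                    ptol = 1e-15)),
                silent = TRUE)
    if (inherits(cand, "try-error")) next
    ssr <- sum(stats::resid(cand)^2)
    if (ssr < best_ssr) {
      best_ssr <- ssr
      fit <- cand
    }
  }
  if (is.null(fit)) {
    out <- list(K_total = k_top * 1e-6, N_s = NA_real_, z_s = NA_real_,
                X0_s = NA_real_, N_i = NA_real_, z_i = NA_real_,
                X0_i = NA_real_, residual = NA_real_, converged = FALSE,
                identifiable = FALSE,
                vcov = matrix(Inf, length(start), length(start)))
    class(out) <- "gating_spring_fit"
    return(out)
  }
  cf <- stats::coef(fit)
  pops <- lapply(seq_len(n_populations), function(j) {
    list(N = exp(cf[[paste0("lN", j)]]),
         z = exp(cf[[paste0("lz", j)]]) * 1e-15,     # back to N
         X0 = cf[[paste0("x0", j)]] * 1e-9)          # back to m
  })
  if (n_populations == 2) {
    ord <- order(vapply(pops, `[[`, numeric(1), "z"), decreasing = TRUE)
    pops <- pops[ord]                                 # sensitive = larger z
  } else {
    pops <- c(pops, list(list(N = 0, z = NA_real_, X0 = NA_real_)))
  }
  # identifiability: data must cover [X0 -+ 4 kT/z] for each fitted population
  for (pp in pops) {
    if (pp$N < 0.5 || is.na(pp$z)) next
    span <- 4 * kT / pp$z
    if (min(curve$X_m) > pp$X0 - span || max(curve$X_m) < pp$X0 + span)
      identifiable <- FALSE
  }
  vc <- try(stats::vcov(fit), silent = TRUE)
  if (inherits(vc, "try-error") || !identifiable)
    vc <- matrix(Inf, length(cf), length(cf))
  out <- list(K_total = exp(cf[["lK"]]) * 1e-6,
              N_s = pops[[1]]$N, z_s = pops[[1]]$z, X0_s = pops[[1]]$X0,
              N_i = pops[[2]]$N, z_i = pops[[2]]$z, X0_i = pops[[2]]$X0,
              residual = sqrt(mean(stats::resid(fit)^2)) * 1e-6,
              converged = isTRUE(fit$convInfo$isConv),
              identifiable = identifiable, vcov = vc)
  class(out) <- "gating_spring_fit"
  out
}

# locate up to n dips (local maxima of the stiffness deficit) with their
# approximate depth and full width at half depth; x and deficit in scaled
# units; runs narrower than 3 grid spacings are noise blips, not compliances
find_dips <- function(x, deficit, n) {
  thr <- max(deficit) * 0.2
  above <- deficit > thr
  if (!any(above)) return(data.frame(x0 = numeric(), depth = numeric(),
                                     width = numeric()))
  spacing <- stats::median(diff(x))
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- data.frame(x0 = numeric(), depth = numeric(), width = numeric())
  for (r in which(runs$values)) {
    idx <- starts[r]:ends[r]
    if (length(idx) < 3L) next
    ipk <- idx[which.max(deficit[idx])]
    depth <- deficit[ipk]
    half <- idx[deficit[idx] >= depth / 2]
    width <- max(diff(range(x[half])), spacing * 3)
    if (width < spacing * 3) next
    out <- rbind(out, data.frame(x0 = x[ipk], depth = depth, width = width))
  }
  out[order(-out$depth), ][seq_len(min(n, nrow(out))), , drop = FALSE]
}

#' @export
#' @method print gating_spring_fit
print.gating_spring_fit <- function(x, ...) {
  cat(sprintf(paste0("gating_spring_fit: K_total = %.3g uN/m; sensitive N = %.3g,",
                     " z = %.3g fN; insensitive N = %.3g, z = %.3g fN (%s)\n"),
              x$K_total * 1e6, x$N_s, x$z_s * 1e15, x$N_i, x$z_i * 1e15,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

#' Fit a double-sigmoid CAP response curve
#'
#' Per-level medians are computed first, then
#' `CAP(|X|) = sum_j A_j/(1 + exp(-(|X| - X50_j)/w_j))` is fitted to the
#' medians by least squares. Populations are labelled by half-point order
#' (`X50_s < X50_i`).
#'
#' @param curve a `cap_curve` data.frame (columns `X_m`, `cap`), possibly
#'   with replicate rows per level
#' @param n_populations 1 or 2 sigmoids
#' @return a `cap_fit`: list with `A_s`, `A_i`, `X50_s`, `X50_i` (m), `w_s`,
#'   `w_i` (m), `residual`, `converged`, `monotonic_warning`, and the
#'   per-level `medians`
#' @export
fit_cap <- function(curve, n_populations = 2) {
  stopifnot(all(c("X_m", "cap") %in% names(curve)))
  lev <- sort(unique(abs(curve$X_m)))
  if (length(lev) < 8) stop("need >= 8 stimulus levels")
  med <- vapply(lev, function(l) stats::median(curve$cap[abs(curve$X_m) == l]),
                numeric(1))
  # non-monotonicity beyond noise: compare decreases against replicate spread
  spread <- stats::median(vapply(lev, function(l) {
    v <- curve$cap[abs(curve$X_m) == l]
    if (length(v) > 1) stats::sd(v) else 0
  }, numeric(1)))
  drops <- -diff(med)
  monotonic_warning <- any(drops > max(3 * spread, 1e-12) + 0)
  if (monotonic_warning)
    warning("CAP level medians decrease beyond noise tolerance")

  rng <- max(med) - min(med)
  x <- lev * 1e9   # nm working units
  A0 <- max(med)
  q25 <- x[which.min(abs(med - min(med) - 0.25 * rng))]
  q75 <- x[which.min(abs(med - min(med) - 0.75 * rng))]
  w0 <- max((max(x) - min(x)) / 20, 1e-3)
  df <- data.frame(x = x, y = med)
  if (n_populations == 2) {
    start <- list(A1 = A0 / 2, A2 = A0 / 2, m1 = q25, m2 = q75,
                  lw1 = log(w0), lw2 = log(w0))
    fit <- try(minpack.lm::nlsLM(
      y ~ A1 * plogis((x - m1) / exp(lw1)) + A2 * plogis((x - m2) / exp(lw2)),
      data = df, start = start,
      lower = c(0, 0, -Inf, -Inf, -Inf, -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                           ptol = 1e-15)), silent = TRUE)
  } else {
    fit <- try(minpack.lm::nlsLM(
      y ~ A1 * plogis((x - m1) / exp(lw1)),
      data = df, start = list(A1 = A0, m1 = q25, lw1 = log(w0)),
      lower = c(0, -Inf, -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                           ptol = 1e-15)), silent = TRUE)
  }
  if (inherits(fit, "try-error") && n_populations == 2) {
    # a near-zero second amplitude can make the 2-sigmoid Jacobian singular;
    # fall back to a single sigmoid with A_i = 0
    fit <- try(minpack.lm::nlsLM(
      y ~ A1 * plogis((x - m1) / exp(lw1)),
      data = df, start = list(A1 = A0, m1 = q25, lw1 = log(w0)),
      lower = c(0, -Inf, -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                           ptol = 1e-15)), silent = TRUE)
    if (!inherits(fit, "try-error")) n_populations <- 1
  }
  if (inherits(fit, "try-error")) {
    out <- list(A_s = NA_real_, A_i = NA_real_, X50_s = NA_real_,
                X50_i = NA_real_, w_s = NA_real_, w_i = NA_real_,
                residual = NA_real_, converged = FALSE,
                monotonic_warning = monotonic_warning,
                medians = data.frame(X_m = lev, cap_median = med))
    class(out) <- "cap_fit"
    return(out)
  }
  cf <- stats::coef(fit)
  if (n_populations == 2) {
    pops <- list(list(A = cf[["A1"]], m = cf[["m1"]], w = exp(cf[["lw1"]])),
                 list(A = cf[["A2"]], m = cf[["m2"]], w = exp(cf[["lw2"]])))
    pops <- pops[order(vapply(pops, `[[`, numeric(1), "m"))]  # X50_s < X50_i
  } else {
    pops <- list(list(A = cf[["A1"]], m = cf[["m1"]], w = exp(cf[["lw1"]])),
                 list(A = 0, m = NA_real_, w = NA_real_))
  }
  out <- list(A_s = pops[[1]]$A, A_i = pops[[2]]$A,
              X50_s = pops[[1]]$m * 1e-9, X50_i = pops[[2]]$m * 1e-9,
              w_s = pops[[1]]$w * 1e-9, w_i = pops[[2]]$w * 1e-9,
              residual = sqrt(mean(stats::resid(fit)^2)),
              converged = isTRUE(fit$convInfo$isConv),
              monotonic_warning = monotonic_warning,
              medians = data.frame(X_m = lev, cap_median = med))
  class(out) <- "cap_fit"
  out
}

#' Channel-number / gating-force homeostasis correlation
#'
#' Across individuals (or ages), transducer channel numbers and their
#' single-channel gating forces may co-vary so that the receiver's nonlinear
#' stiffness dip `N z^2 / (4 kB T)` stays constant. Because that compensation
#' law is multiplicative, the correlation is computed on log-transformed
#' values; the dispersion (coefficient of variation) of the product `N z^2`
#' is reported as the stabilized-nonlinearity statistic.
#'
#' @param N,z numeric vectors of channel counts and gating forces (one
#'   population, one entry per converged fit; >= 5 pairs)
#' @return a `homeostasis_correlation`: list with `r` (Pearson on logs),
#'   `p_value`, `n`, `nz2_cv` (coefficient of variation of `N z^2`)
#' @export
nz_homeostasis <- function(N, z) {
  keep <- is.finite(N) & is.finite(z) & N > 0 & z > 0
  N <- N[keep]
  z <- z[keep]
  if (length(N) < 5) stop("need >= 5 converged (N, z) pairs")
  ct <- stats::cor.test(log(N), log(z), method = "pearson")
  nz2 <- N * z^2
  structure(list(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(N), nz2_cv = stats::sd(nz2) / mean(nz2)),
            class = "homeostasis_correlation")
}
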