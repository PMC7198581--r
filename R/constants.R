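#' Physical constants and shared defaults
#'
#' Units are fixed package-wide: displacement in m, force in N, stiffness in
#' N/m, temperature in K, energy reported in units of kB*T.
#'
#' @name earspan-constants
#' @keywords internal
NULL

#' Boltzmann constant (J/K)
#' @export
KB <- 1.380649e-23

#' Default bath temperature, K (room temperature, 21 degrees C)
#' @export
T_ROOM <- 294.15

# run code under a fixed seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

stop_if_not_finite <- function(x, name) {
  if (!all(is.finite(x))) stop("non-finite value in ", name, call. = FALSE)
  invisible(x)
}
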