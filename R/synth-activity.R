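#' Specification for a synthetic locomotor-activity experiment
#'
#' Emulates beam-break activity monitors under an hourly sound-stimulation
#' schedule: the first 15 minutes of each hour are the stimulus window (sound
#' playing), the last 15 minutes the baseline window (silence preceding the
#' next stimulus). Per-minute counts are Poisson with rate
#' `lambda_base * rho` inside stimulus windows and `lambda_base` elsewhere.
#'
#' @param n_tubes number of monitor tubes
#' @param hours experiment length, h
#' @param lambda_base baseline beam-break rate, counts/min (> 0)
#' @param rho stimulus rate multiplier (>= 0; 1 = no sound response)
#' @param seed integer seed
#' @return an object of class `behavior_sim_spec`
#' @export
behavior_sim_spec <- function(n_tubes = 12, hours = 24, lambda_base = 1,
                              rho = 2, seed = 1L) {
  if (lambda_base <= 0) stop("lambda_base must be > 0")
  if (rho < 0) stop("rho must be >= 0")
  if (hours < 1) stop("hours must be >= 1")
  structure(list(n_tubes = n_tubes, hours = hours,
                 lambda_base = lambda_base, rho = rho, seed = seed),
            class = "behavior_sim_spec")
}

#' Minute-of-hour windows of the stimulation schedule
#'
#' Stimulus minutes are minutes 0-14 of each hour, baseline minutes 45-59;
#' minutes 15-44 are unanalysed.
#' @return list with integer vectors `stimulus` and `baseline` (minute of
#'   hour, 0-based)
#' @export
stimulus_schedule <- function() {
  list(stimulus = 0:14, baseline = 45:59)
}

#' Simulate an activity-monitor trace
#'
#' @param spec a [behavior_sim_spec()] object
#' @return an `activity_trace` data.frame with columns `minute_index`
#'   (0-based from the first light transition), `tube_id`, `count`; the
#'   schedule and spec are attached as attributes
#' @export
simulate_activity <- function(spec) {
  stopifnot(inherits(spec, "behavior_sim_spec"))
  sched <- stimulus_schedule()
  n_min <- spec$hours * 60L
  minute <- rep(0:(n_min - 1L), times = spec$n_tubes)
  tube <- rep(sprintf("tube%02d", seq_len(spec$n_tubes)), each = n_min)
  in_stim <- (minute %% 60L) %in% sched$stimulus
  lambda <- ifelse(in_stim, spec$lambda_base * spec$rho, spec$lambda_base)
  count <- with_seed(spec$seed, rpois(length(lambda), lambda))
  out <- data.frame(minute_index = minute, tube_id = tube, count = count,
                    stringsAsFactors = FALSE)
  attr(out, "schedule") <- sched
  attr(out, "spec") <- spec
  class(out) <- c("activity_trace", "data.frame")
  out
}

#' Simulate cohort death times under a constant daily hazard
#'
#' Each fly dies on day `d` with geometric hazard `hazard` per day; flies
#' surviving past `max_day` are right-censored at `max_day` (counted alive).
#'
#' @param cohort_size number of flies in the cohort
#' @param hazard daily death probability, in (0, 1)
#' @param max_day observation horizon, days
#' @param seed integer seed
#' @return integer vector of per-day death counts, length `max_day`
#' @export
simulate_deaths <- function(cohort_size = 25, hazard = 0.02, max_day = 120,
                            seed = 1L) {
  if (hazard <= 0 || hazard >= 1) stop("hazard must be in (0, 1)")
  day <- with_seed(seed, rgeom(cohort_size, hazard) + 1L)
  tabulate(day[day <= max_day], nbins = max_day)
}
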