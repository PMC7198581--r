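#' Relative quantification of qPCR plates (delta-delta-Ct)
#'
#' Technical-replicate Ct values of each target gene are paired with the
#' endogenous-control Ct of the same (condition, biological replicate); per
#' technical replicate
#' \deqn{\Delta Ct = Ct_{gene,control} - Ct_{endo,control}}
#' \deqn{\Delta\Delta Ct = \Delta Ct - (Ct_{gene,kd} - Ct_{endo,kd})}
#' \deqn{RQ = 2^{-\Delta\Delta Ct}}
#' and the RQ values are averaged per biological replicate with their
#' standard deviation, then across biological replicates.
#'
#' Note the sign convention: with `convention = "printed"` (the default,
#' the equations exactly as written above) a knockdown that RAISES the
#' target's Ct yields RQ > 1. `convention = "standard"` uses the
#' conventional \eqn{\Delta\Delta Ct = \Delta Ct_{kd} - \Delta Ct_{control}},
#' under which the same knockdown yields RQ < 1. Neither is silently
#' corrected; choose explicitly.
#'
#' @param plate data.frame with columns `target`, `condition` (`control` /
#'   `knockdown`), `bio_rep`, `tech_rep`, `ct`
#' @param endo_control endogenous control gene id (default `"SdhA"`)
#' @param convention `"printed"` or `"standard"` (see Details)
#' @return a `qpcr_result`: list with `per_bio_rep` (RQ mean and sd per
#'   target and biological replicate) and `per_target` (RQ mean and sd
#'   across biological replicates)
#' @export
relative_quantification <- function(plate, endo_control = "SdhA",
                                    convention = c("printed", "standard")) {
  convention <- match.arg(convention)
  need <- c("target", "condition", "bio_rep", "tech_rep", "ct")
  if (!all(need %in% names(plate)))
    stop("plate must have columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(plate$ct)) || any(plate$ct <= 0))
    stop("Ct values must be finite and > 0")
  conds <- unique(plate$condition)
  if (!all(c("control", "knockdown") %in% conds))
    stop("plate needs both 'control' and 'knockdown' conditions")
  targets <- setdiff(unique(plate$target), endo_control)
  if (length(targets) == 0) stop("no target genes on plate")

  endo_ct <- function(cond, br) {
    v <- plate$ct[plate$target == endo_control & plate$condition == cond &
                    plate$bio_rep == br]
    if (length(v) == 0)
      stop("endogenous control ", endo_control, " missing for ",
           cond, " bio_rep ", br)
    mean(v)
  }

  rows <- list()
  for (tg in targets) {
    sub <- plate[plate$target == tg, , drop = FALSE]
    for (br in unique(sub$bio_rep)) {
      ct_c <- sub$ct[sub$condition == "control" & sub$bio_rep == br]
      ct_k <- sub$ct[sub$condition == "knockdown" & sub$bio_rep == br]
      if (length(ct_c) == 0 || length(ct_k) == 0)
        stop("target ", tg, " bio_rep ", br, ": both conditions required")
      e_c <- endo_ct("control", br)
      e_k <- endo_ct("knockdown", br)
      # per technical replicate (knockdown reps paired by position; the
      # endogenous control enters as its per-(condition, bio-rep) mean)
      n_tech <- max(length(ct_c), length(ct_k))
      dct_c <- rep_len(ct_c, n_tech) - e_c
      dct_k <- rep_len(ct_k, n_tech) - e_k
      ddct <- if (convention == "printed") dct_c - dct_k else dct_k - dct_c
      rq <- 2^(-ddct)
      rows[[length(rows) + 1L]] <- data.frame(
        target = tg, bio_rep = br,
        delta_ct_control = mean(dct_c), delta_ct_kd = mean(dct_k),
        delta_delta_ct = mean(ddct),
        rq_mean = mean(rq),
        rq_sd = if (n_tech > 1) stats::sd(rq) else NA_real_,
        n_tech = n_tech, stringsAsFactors = FALSE)
    }
  }
  per_bio <- do.call(rbind, rows)
  per_target <- do.call(rbind, lapply(split(per_bio, per_bio$target),
    function(d) data.frame(target = d$target[1],
                           rq_mean = mean(d$rq_mean),
                           rq_sd = if (nrow(d) > 1) stats::sd(d$rq_mean)
                                   else NA_real_,
                           n_bio = nrow(d), stringsAsFactors = FALSE)))
  rownames(per_target) <- NULL
  structure(list(per_bio_rep = per_bio, per_target = per_target,
                 convention = convention),
            class = "qpcr_result")
}

#' Sound-evoked locomotor response analysis
#'
#' Per tube, the beam-break counts of each hour are summed over the stimulus
#' window (first 15 minutes) and the baseline window (last 15 minutes); the
#' hourly sums are collapsed into a single median per tube to cancel
#' circadian variation. Stimulus and baseline medians are then compared
#' across tubes with a paired test: a paired t-test when Shapiro-Wilk does
#' not reject normality of the paired differences (alpha = 0.05), otherwise
#' a Wilcoxon signed-rank test.
#'
#' @param trace an `activity_trace` data.frame (`minute_index`, `tube_id`,
#'   `count`); `minute_index` 0 is the first analysed minute (first light
#'   transition)
#' @param min_hours minimum number of complete hours required (default 12)
#' @param shapiro_alpha normality-gate alpha for test selection
#' @return a `sound_response`: list with `per_tube` (median stimulus and
#'   baseline sums), `effect` (median of paired differences), `p_value`,
#'   `test` ("paired t" or "wilcoxon"), `n_tubes`, `n_hours`
#' @export
sound_response <- function(trace, min_hours = 12, shapiro_alpha = 0.05) {
  stopifnot(all(c("minute_index", "tube_id", "count") %in% names(trace)))
  if (any(trace$count < 0)) stop("negative counts")
  sched <- attr(trace, "schedule") %||% stimulus_schedule()
  n_hours <- (max(trace$minute_index) + 1L) %/% 60L
  if (n_hours < min_hours)
    stop("need >= ", min_hours, " complete hours, got ", n_hours)
  trace <- trace[trace$minute_index < n_hours * 60L, , drop = FALSE]
  moh <- trace$minute_index %% 60L
  hr <- trace$minute_index %/% 60L

  sum_window <- function(window) {
    sel <- moh %in% window
    agg <- stats::aggregate(count ~ tube_id + hr_f,
                            data = data.frame(count = trace$count[sel],
                                              tube_id = trace$tube_id[sel],
                                              hr_f = hr[sel]),
                            FUN = sum)
    stats::aggregate(count ~ tube_id, data = agg, FUN = stats::median)
  }
  stim <- sum_window(sched$stimulus)
  base <- sum_window(sched$baseline)
  per_tube <- merge(stim, base, by = "tube_id",
                    suffixes = c("_stimulus", "_baseline"))
  all_zero <- per_tube$count_stimulus == 0 & per_tube$count_baseline == 0
  if (any(all_zero))
    warning(sum(all_zero), " all-zero tube(s): ",
            paste(per_tube$tube_id[all_zero], collapse = ", "))

  d <- per_tube$count_stimulus - per_tube$count_baseline
  if (stats::sd(d) == 0) {
    # degenerate: identical difference in every tube
    test <- "degenerate"
    p <- if (d[1] == 0) 1 else 0
  } else if (length(unique(d)) > 2 &&
             stats::shapiro.test(d)$p.value < shapiro_alpha) {
    test <- "wilcoxon"
    p <- suppressWarnings(stats::wilcox.test(d)$p.value)
  } else {
    test <- "paired t"
    p <- stats::t.test(d)$p.value
  }
  structure(list(per_tube = per_tube,
                 effect = stats::median(d),
                 p_value = p, test = test,
                 n_tubes = nrow(per_tube), n_hours = n_hours),
            class = "sound_response")
}

#' @export
#' @method print sound_response
print.sound_response <- function(x, ...) {
  cat(sprintf("sound_response: %d tubes, %d h; effect = %g counts/15 min (%s, p = %.3g)\n",
              x$n_tubes, x$n_hours, x$effect, x$test, x$p_value))
  invisible(x)
}

#' Survival curve and median lifespan from per-day death counts
#'
#' @param deaths integer vector of deaths per day (day 1, 2, ...), or a
#'   data.frame with columns `day` and `deaths`
#' @param cohort_size number of flies at day 0; `sum(deaths)` must not
#'   exceed it
#' @return a `survival_curve`: data.frame `day`, `deaths`, `fraction_alive`,
#'   plus attributes `median_lifespan` (days; `Inf` when more than half the
#'   cohort outlives the observation) and `cohort_size`
#' @export
survival_analysis <- function(deaths, cohort_size) {
  if (is.data.frame(deaths)) {
    d <- integer(max(deaths$day))
    d[deaths$day] <- deaths$deaths
    deaths <- d
  }
  if (any(deaths < 0)) stop("negative death counts")
  if (sum(deaths) > cohort_size)
    stop("total deaths exceed cohort size")
  alive <- (cohort_size - cumsum(deaths)) / cohort_size
  out <- data.frame(day = seq_along(deaths), deaths = deaths,
                    fraction_alive = alive)
  med <- if (any(alive < 0.5)) min(out$day[alive < 0.5]) else Inf
  attr(out, "median_lifespan") <- med
  attr(out, "cohort_size") <- cohort_size
  class(out) <- c("survival_curve", "data.frame")
  out
}
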