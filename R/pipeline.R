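#' Default pipeline configuration
#'
#' Thresholds default to the study's printed values: fold change 1.5, FDR
#' 10%, p 0.05, round-II expression 10,000 reads, round-III fold change 4,
#' NES 2.5; physical constants to room temperature and the SI Boltzmann
#' constant; analysis windows to the first/last 15 minutes of each hour.
#'
#' @param ... named overrides of the defaults
#' @return a `run_config` list
#' @export
default_config <- function(...) {
  cfg <- list(fc_threshold = 1.5, fdr_threshold = 0.10, p_threshold = 0.05,
              reads_threshold = 10000, fc_extreme = 4, nes_threshold = 2.5,
              temperature = T_ROOM, kB = KB,
              stimulus_minutes = 0:14, baseline_minutes = 45:59,
              sho_band = NULL, seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

MANIFEST_KINDS <- c("fluctuation", "stiffness", "cap", "counts", "qpcr",
                    "activity", "deaths")

#' Validate a pipeline manifest
#'
#' @param manifest data.frame with columns `id`, `age_day`, `sex`,
#'   `genotype`, `path`, `kind`
#' @return the manifest, invisibly; errors list every problem found
#' @export
validate_manifest <- function(manifest) {
  need <- c("id", "age_day", "sex", "genotype", "path", "kind")
  problems <- character()
  missing <- setdiff(need, names(manifest))
  if (length(missing) > 0)
    problems <- c(problems, paste("missing column(s):",
                                  paste(missing, collapse = ", ")))
  if (length(problems) == 0) {
    if (nrow(manifest) == 0)
      problems <- c(problems, paste("empty manifest; expected record kinds:",
                                    paste(MANIFEST_KINDS, collapse = ", ")))
    if (anyDuplicated(manifest$id))
      problems <- c(problems, "duplicate record ids")
    bad_kind <- setdiff(unique(manifest$kind), MANIFEST_KINDS)
    if (length(bad_kind) > 0)
      problems <- c(problems, paste("unknown kind(s):",
                                    paste(bad_kind, collapse = ", ")))
    gone <- manifest$path[!file.exists(manifest$path)]
    if (length(gone) > 0)
      problems <- c(problems, paste("unresolvable path(s):",
                                    paste(gone, collapse = ", ")))
  }
  if (length(problems) > 0)
    stop("manifest validation failed:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  invisible(manifest)
}

#' Run the full life-course pipeline over a manifest
#'
#' Executes every stage for which the manifest supplies records:
#' free-fluctuation SHO fits and life-course summary, gating-spring and CAP
#' fits with the N-z homeostasis correlation, pairwise DE and age-variable
#' classification, qPCR relative quantification, sound-evoked behaviour, and
#' survival. Stage failures are recorded in the report and the remaining
#' independent stages still run. The report is deterministic given identical
#' inputs and config.
#'
#' @param manifest validated manifest data.frame (see [validate_manifest()])
#' @param config a [default_config()] list
#' @param out_json optional path; when set, the report is written as JSON
#' @return the run report (nested list), invisibly when `out_json` is set
#' @export
run_pipeline <- function(manifest, config = default_config(),
                         out_json = NULL) {
  validate_manifest(manifest)
  report <- list(config = unclass(config),
                 n_records = nrow(manifest), stages = list())
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      list(error = conditionMessage(e)))
    report$stages[[name]] <<- res
  }

  fl <- manifest[manifest$kind == "fluctuation", , drop = FALSE]
  if (nrow(fl) > 0) stage("fluctuation", {
    fits <- do.call(rbind, lapply(seq_len(nrow(fl)), function(i) {
      rec <- read_fluctuation(fl$path[i])
      fit <- fit_sho(estimate_psd(rec), band = config$sho_band,
                     temperature = config$temperature)
      data.frame(id = fl$id[i], age_day = fl$age_day[i], f0 = fit$f0,
                 Q = fit$Q, gain = fit$gain, converged = fit$converged)
    }))
    out <- list(fits = fits)
    if (length(unique(fits$age_day)) > 1 &&
        min(table(fits$age_day)) >= 3) {
      lc <- summarize_lifecourse(fits)
      out$lifecourse <- list(medians = lc$medians, pairwise = lc$pairwise)
    }
    out
  })

  st <- manifest[manifest$kind == "stiffness", , drop = FALSE]
  if (nrow(st) > 0) stage("gating", {
    fits <- lapply(seq_len(nrow(st)), function(i) {
      cv <- read_table_schema(st$path[i],
                              c(X_m = "numeric", K_N_per_m = "numeric"))
      f <- fit_gating_spring(cv, temperature = config$temperature)
      c(list(id = st$id[i], age_day = st$age_day[i]),
        f[c("K_total", "N_s", "z_s", "X0_s", "N_i", "z_i", "X0_i",
            "residual", "converged")])
    })
    tab <- do.call(rbind, lapply(fits, function(f)
      as.data.frame(f, stringsAsFactors = FALSE)))
    out <- list(fits = tab)
    ok <- tab$converged & tab$N_s > 0 & is.finite(tab$z_s)
    if (sum(ok) >= 5)
      out$homeostasis <- unclass(nz_homeostasis(tab$N_s[ok], tab$z_s[ok]))
    out
  })

  cp <- manifest[manifest$kind == "cap", , drop = FALSE]
  if (nrow(cp) > 0) stage("cap", {
    lapply(seq_len(nrow(cp)), function(i) {
      cv <- read_table_schema(cp$path[i], c(X_m = "numeric", cap = "numeric"))
      f <- fit_cap(cv)
      c(list(id = cp$id[i]),
        f[c("A_s", "A_i", "X50_s", "X50_i", "w_s", "w_i", "converged")])
    })
  })

  cn <- manifest[manifest$kind == "counts", , drop = FALSE]
  if (nrow(cn) > 0) stage("transcriptome", {
    counts <- read_counts(cn$path[1])
    ages <- sort(unique(counts$samples$age_day))
    pairs <- Map(c, ages[-length(ages)], ages[-1])
    cmps <- lapply(pairs, function(pr) pairwise_de(counts, pr))
    av <- classify_age_variable(cmps,
                                fc_threshold = config$fc_threshold,
                                fdr_threshold = config$fdr_threshold,
                                p_threshold = config$p_threshold)
    list(n_expressed = length(av$expressed),
         n_variable = length(av$variable),
         n_constant = length(av$constant),
         pct_constant = round(100 * length(av$constant) /
                                length(av$expressed)),
         comparisons = vapply(cmps, attr, "", "pair"))
  })

  qp <- manifest[manifest$kind == "qpcr", , drop = FALSE]
  if (nrow(qp) > 0) stage("qpcr", {
    plate <- read_table_schema(qp$path[1],
                               c(target = "character", condition = "character",
                                 bio_rep = "integer", tech_rep = "integer",
                                 ct = "numeric"))
    rq <- relative_quantification(plate)
    list(per_target = rq$per_target, convention = rq$convention)
  })

  ac <- manifest[manifest$kind == "activity", , drop = FALSE]
  if (nrow(ac) > 0) stage("behaviour", {
    tr <- read_table_schema(ac$path[1],
                            c(minute_index = "integer", tube_id = "character",
                              count = "integer"))
    attr(tr, "schedule") <- list(stimulus = config$stimulus_minutes,
                                 baseline = config$baseline_minutes)
    sr <- sound_response(tr)
    sr[c("effect", "p_value", "test", "n_tubes", "n_hours")]
  })

  dt <- manifest[manifest$kind == "deaths", , drop = FALSE]
  if (nrow(dt) > 0) stage("survival", {
    lapply(seq_len(nrow(dt)), function(i) {
      d <- read_table_schema(dt$path[i],
                             c(day = "integer", deaths = "integer"))
      size <- sum(d$deaths)
      meta <- attr(d, "metadata")
      cs <- grep("^cohort_size=", meta, value = TRUE)
      if (length(cs) == 1) size <- as.integer(sub("cohort_size=", "", cs))
      sc <- survival_analysis(d, size)
      list(id = dt$id[i], median_lifespan = attr(sc, "median_lifespan"),
           cohort_size = size)
    })
  })

  if (!is.null(out_json)) {
    jsonlite::write_json(report, out_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
    return(invisible(report))
  }
  report
}
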