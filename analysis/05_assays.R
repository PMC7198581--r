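#!/usr/bin/env Rscript
# qPCR relative quantification, sound-evoked behaviour, survival, and the
# lifespan/auditory-healthspan alignment table.

suppressPackageStartupMessages(library(earspan))

# -- qPCR --------------------------------------------------------------------
plate <- read_table_schema("results/data/qpcr_plate.tsv",
                           c(target = "character", condition = "character",
                             bio_rep = "integer", tech_rep = "integer",
                             ct = "numeric"))
for (conv in c("printed", "standard")) {
  rq <- relative_quantification(plate, convention = conv)
  cat(sprintf("qPCR (%s convention): %s RQ = %.3f +- %.3f\n", conv,
              rq$per_target$target, rq$per_target$rq_mean,
              rq$per_target$rq_sd))
  if (conv == "standard")
    write_table_meta(rq$per_target, "results/qpcr_rq.tsv")
}
cat("  (a knockdown that raises the target Ct gives RQ > 1 under the printed convention,\n",
    "  RQ < 1 under the standard one; see the methods vignette)\n")

# -- sound-evoked behaviour --------------------------------------------------
tr <- read_table_schema("results/data/activity.tsv",
                        c(minute_index = "integer", tube_id = "character",
                          count = "integer"))
attr(tr, "schedule") <- stimulus_schedule()
sr <- sound_response(tr)
cat(sprintf("\nbehaviour: %d tubes, %d h; stimulus - baseline = %g counts/15 min (%s, p = %.3g)\n",
            sr$n_tubes, sr$n_hours, sr$effect, sr$test, sr$p_value))
write_table_meta(sr$per_tube, "results/behaviour_per_tube.tsv")

# -- survival and healthspan alignment ---------------------------------------
manifest <- read_table_schema("results/manifest.tsv")
dd <- manifest[manifest$kind == "deaths", ]
curves <- lapply(seq_len(nrow(dd)), function(i) {
  d <- read_table_schema(dd$path[i], c(day = "integer", deaths = "integer"))
  survival_analysis(d, 25)
})
meds <- vapply(curves, attr, numeric(1), "median_lifespan")
cat(sprintf("\nsurvival: median lifespans %s days (3 cohorts)\n",
            paste(meds, collapse = ", ")))

# alignment table: fraction alive (pooled cohorts) next to the normalised
# auditory gain trajectory from the receiver stage
lc <- read_table_schema("results/receiver_lifecourse.tsv")
pooled <- Reduce(`+`, lapply(curves, function(cv) cv$deaths))
surv <- survival_analysis(pooled, 75)
align <- data.frame(age_day = lc$age_day,
                    gain_pct_of_max = round(lc$gain_pct_of_max, 1),
                    fraction_alive = surv$fraction_alive[
                      pmin(lc$age_day, nrow(surv))])
write_table_meta(align, "results/healthspan_lifespan_alignment.tsv")
cat("\nauditory healthspan vs lifespan:\n")
print(align, row.names = FALSE)
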