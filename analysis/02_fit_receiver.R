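#!/usr/bin/env Rscript
# Fit SHO models to every free-fluctuation recording in the manifest and
# summarise the auditory life course: per-age median f0, Q and power gain,
# plus the gain trajectory in % of its maximum (the auditory healthspan).

suppressPackageStartupMessages(library(earspan))

manifest <- read_table_schema("results/manifest.tsv")
fl <- manifest[manifest$kind == "fluctuation", ]
fits <- do.call(rbind, lapply(seq_len(nrow(fl)), function(i) {
  rec <- read_fluctuation(fl$path[i])
  fit <- fit_sho(estimate_psd(rec), temperature = T_ROOM)
  data.frame(id = fl$id[i], age_day = as.numeric(fl$age_day[i]),
             f0 = fit$f0, Q = fit$Q, gain = fit$gain,
             converged = fit$converged)
}))
write_table_meta(fits, "results/receiver_fits.tsv")
cat(sprintf("%d recordings fitted; %d converged\n",
            nrow(fits), sum(fits$converged)))

lc <- summarize_lifecourse(fits)
write_table_meta(lc$medians, "results/receiver_lifecourse.tsv")
write_table_meta(lc$pairwise, "results/receiver_lifecourse_tests.tsv")

cat("\nper-age medians:\n")
print(lc$medians, row.names = FALSE)
cat("\nconsecutive-age Mann-Whitney (gain):\n")
print(lc$pairwise, row.names = FALSE)

drop <- lc$medians$gain_pct_of_max[nrow(lc$medians)]
cat(sprintf("\ngain at the oldest age is %.0f%% of its maximum (terminal decline %s)\n",
            drop, if (drop < 25) "reproduced" else "NOT seen"))
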