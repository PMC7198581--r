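#!/usr/bin/env Rscript
# Generate the full synthetic study dataset: free-fluctuation recordings of
# antennal receivers across the life course, stiffness and CAP curves, a
# gene-by-age count matrix, a qPCR plate, activity-monitor traces and
# lifespan cohorts. Writes plain-text tables plus a manifest under
# results/data/.

suppressPackageStartupMessages(library(earspan))

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
rows <- list()
add <- function(id, age, path, kind)
  rows[[length(rows) + 1L]] <<- data.frame(id = id, age_day = age, sex = "m",
                                           genotype = "CantonS", path = path,
                                           kind = kind)

# -- receiver fluctuations: active energy declines after day 50 ------------
ages <- c(1, 25, 50, 70)
teff_ratio <- c(6, 6, 5, 1.3)   # ~90% gain loss by day 70
f0s <- c(240, 245, 255, 330)    # best frequency rises towards the passive system
Qs <- c(1.9, 2.0, 1.8, 1.05)
for (i in seq_along(ages)) {
  for (ind in 1:5) {
    p <- oscillator_params(f0 = f0s[i], Q = Qs[i], K = 50e-6,
                           T_eff = teff_ratio[i] * T_ROOM,
                           duration = 20, seed = 1000 + 10 * i + ind)
    path <- file.path(out, sprintf("fluct_d%02d_i%d.tsv", ages[i], ind))
    write_fluctuation(simulate_fluctuations(p), path)
    add(sprintf("fl_d%02d_i%d", ages[i], ind), ages[i], path, "fluctuation")
  }
  cat(sprintf("day %2d: 5 recordings (f0 %g Hz, Q %g, T_eff/T %g)\n",
              ages[i], f0s[i], Qs[i], teff_ratio[i]))
}

# -- transducer mechanics: N falls, z rises, N z^2 roughly conserved -------
Xg <- seq(-900e-9, 1500e-9, length.out = 200)
for (i in seq_along(ages)) {
  shrink <- 1 - 0.5 * (i - 1) / (length(ages) - 1)   # N down to 50% by day 70
  for (ind in 1:3) {
    tr <- gating_truth(N_s = 80 * shrink, z_s = 50e-15 / sqrt(shrink),
                       N_i = 800 * shrink, z_i = 15e-15 / sqrt(shrink),
                       noise_sd = 1.2e-6, seed = 3000 + 10 * i + ind)
    cv <- simulate_stiffness_curve(tr, Xg)
    path <- file.path(out, sprintf("stiff_d%02d_i%d.tsv", ages[i], ind))
    write_table_meta(data.frame(X_m = cv$X_m, K_N_per_m = cv$K_N_per_m), path)
    add(sprintf("st_d%02d_i%d", ages[i], ind), ages[i], path, "stiffness")
  }
}
cat("stiffness curves written for", length(ages), "ages x 3 individuals\n")

cap <- simulate_cap_curve(c(1, 2), c(150e-9, 600e-9), c(40e-9, 120e-9),
                          seq(0, 2e-6, length.out = 30),
                          noise_sd = 0.06, replicates = 5, seed = 3999)
write_table_meta(data.frame(X_m = cap$X_m, cap = cap$cap),
                 file.path(out, "cap_d25.tsv"))
add("cap_d25", 25, file.path(out, "cap_d25.tsv"), "cap")

# -- transcriptome: 5 ages, spiked age-variable genes -----------------------
cs <- simulate_counts(count_sim_spec(n_genes = 4000,
                                     ages = c(1, 5, 10, 25, 50),
                                     reps_per_age = 3, spike_fraction = 0.2,
                                     spike_fc = 3, seed = 4001))
write_counts(cs, file.path(out, "counts.tsv"))
write_table_meta(cs$truth, file.path(out, "counts_truth.tsv"))
add("counts", NA, file.path(out, "counts.tsv"), "counts")
cat("count matrix:", nrow(cs$counts), "genes x", ncol(cs$counts), "samples\n")

# -- qPCR plate: knockdown raises the target's Ct by ~3 cycles --------------
set.seed(4002)
plate <- do.call(rbind, lapply(1:3, function(br) rbind(
  data.frame(target = "nan", condition = "control", bio_rep = br,
             tech_rep = 1:3, ct = rnorm(3, 20, 0.1)),
  data.frame(target = "nan", condition = "knockdown", bio_rep = br,
             tech_rep = 1:3, ct = rnorm(3, 23, 0.1)),
  data.frame(target = "SdhA", condition = "control", bio_rep = br,
             tech_rep = 1:3, ct = rnorm(3, 18, 0.1)),
  data.frame(target = "SdhA", condition = "knockdown", bio_rep = br,
             tech_rep = 1:3, ct = rnorm(3, 18, 0.1)))))
write_table_meta(plate, file.path(out, "qpcr_plate.tsv"))
add("qpcr", NA, file.path(out, "qpcr_plate.tsv"), "qpcr")

# -- behaviour and lifespan --------------------------------------------------
act <- simulate_activity(behavior_sim_spec(n_tubes = 12, hours = 48,
                                           lambda_base = 1, rho = 2,
                                           seed = 4003))
write_table_meta(as.data.frame(act), file.path(out, "activity.tsv"))
add("activity", 10, file.path(out, "activity.tsv"), "activity")

for (k in 1:3) {
  d <- simulate_deaths(cohort_size = 25, hazard = 0.013, max_day = 120,
                       seed = 4100 + k)
  path <- file.path(out, sprintf("deaths_cohort%d.tsv", k))
  write_table_meta(data.frame(day = seq_along(d), deaths = d), path,
                   metadata = "cohort_size=25")
  add(sprintf("cohort%d", k), NA, path, "deaths")
}

manifest <- do.call(rbind, rows)
write_table_meta(manifest, "results/manifest.tsv")
cat("manifest:", nrow(manifest), "records ->", "results/manifest.tsv\n")
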