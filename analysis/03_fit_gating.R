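#!/usr/bin/env Rscript
# Fit the two-population gating-spring model to every stiffness curve, fit
# the CAP response curve, and test the N-z homeostasis: channel numbers and
# single-channel gating forces should be inversely correlated on the log
# scale, with the nonlinearity depth N z^2 conserved.

suppressPackageStartupMessages(library(earspan))

manifest <- read_table_schema("results/manifest.tsv")
st <- manifest[manifest$kind == "stiffness", ]
fits <- do.call(rbind, lapply(seq_len(nrow(st)), function(i) {
  cv <- read_table_schema(st$path[i], c(X_m = "numeric",
                                        K_N_per_m = "numeric"))
  f <- fit_gating_spring(cv, temperature = T_ROOM)
  data.frame(id = st$id[i], age_day = as.numeric(st$age_day[i]),
             K_total_uN_m = f$K_total * 1e6, N_s = f$N_s,
             z_s_fN = f$z_s * 1e15, N_i = f$N_i, z_i_fN = f$z_i * 1e15,
             converged = f$converged)
}))
write_table_meta(fits, "results/gating_fits.tsv")
cat(sprintf("%d stiffness curves fitted; %d converged\n",
            nrow(fits), sum(fits$converged)))

agg <- aggregate(cbind(N_s, z_s_fN, N_i, z_i_fN, K_total_uN_m) ~ age_day,
                 fits[fits$converged, ], median)
cat("\nper-age medians:\n")
print(agg, row.names = FALSE)
cat(sprintf("\nN_s falls %.0f%% from day %g to day %g while z_s rises %.0f%%; K_total changes %.1f%%\n",
            100 * (1 - agg$N_s[nrow(agg)] / agg$N_s[1]), agg$age_day[1],
            agg$age_day[nrow(agg)],
            100 * (agg$z_s_fN[nrow(agg)] / agg$z_s_fN[1] - 1),
            100 * (agg$K_total_uN_m[nrow(agg)] / agg$K_total_uN_m[1] - 1)))

ok <- fits$converged & fits$N_s > 0
h <- nz_homeostasis(fits$N_s[ok], fits$z_s_fN[ok] * 1e-15)
cat(sprintf("\nN-z homeostasis (sensitive population): r = %.3f (p = %.2g), CV(N z^2) = %.2f\n",
            h$r, h$p_value, h$nz2_cv))
write_table_meta(data.frame(r = h$r, p_value = h$p_value, n = h$n,
                            nz2_cv = h$nz2_cv),
                 "results/nz_homeostasis.tsv")

cp <- manifest[manifest$kind == "cap", ]
cap <- read_table_schema(cp$path[1], c(X_m = "numeric", cap = "numeric"))
cf <- fit_cap(cap)
cat(sprintf("\nCAP double sigmoid: A_s %.2f at X50 %.0f nm, A_i %.2f at X50 %.0f nm\n",
            cf$A_s, cf$X50_s * 1e9, cf$A_i, cf$X50_i * 1e9))
write_table_meta(data.frame(A_s = cf$A_s, A_i = cf$A_i,
                            X50_s_nm = cf$X50_s * 1e9,
                            X50_i_nm = cf$X50_i * 1e9,
                            w_s_nm = cf$w_s * 1e9, w_i_nm = cf$w_i * 1e9),
                 "results/cap_fit.tsv")
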