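#!/usr/bin/env Rscript

# Stage 2: junction conservation J, 100-bp average conservation A, and the
# Junc/Avg ratio R = J/A for every event and side, plus the window-sweep
# profile showing how far into the intron conservation remains informative
# about inclusion.

library(spliceCons)

outdir <- "results"
cfg <- sim_config(n_exons = 3000L, seed = 20260924L)

run_pipeline(cfg, outdir, stages = c("features", "sweep"),
             settings = pipeline_settings(sweep_W = 200L))

feats <- read.delim(file.path(outdir, "features.tsv"))
cat("Feature table:", nrow(feats), "events.\n")
cat(sprintf("Median J_up = %.2f, A_up = %.2f, R_up = %.2f\n",
            median(feats$J_up), median(feats$A_up), median(feats$R_up)))

sw <- read.delim(file.path(outdir, "sweep.tsv"))
for (side in unique(sw$side)) {
  d <- sw[sw$side == side, ]
  cat(sprintf("%s sweep: peak Spearman rho %.3f at w = %d bp\n",
              side, max(abs(d$rho), na.rm = TRUE),
              d$w[which.max(abs(d$rho))]))
}
cat("Conserved regulation in this simulation lies within the 15-100 bp\n")
cat("region, so the peak is expected near w = 100.\n")
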