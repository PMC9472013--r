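#!/usr/bin/env Rscript
# Generate the synthetic study inputs used by the downstream analyses:
# a mixed aging cohort of per-oocyte timelines, one full indentation grid,
# an aging series of whole-cell relaxation holds, and two fluorescence
# stacks (bleaching control and CG-release). Raw curve files for one grid
# are written in the TSV dialect to results/curves/.

suppressPackageStartupMessages(library(ovomech))
dir.create("results/curves", showWarnings = FALSE, recursive = TRUE)

cfg <- synth_config(seed = 20261001)

cohort <- gen_cohort(cfg, seed = 1)
write_timelines(cohort$timelines, "results/cohort_timelines.csv")
jsonlite::write_json(cohort$truth, "results/cohort_truth.json",
                     auto_unbox = TRUE, digits = NA)
cat(sprintf("cohort: %d oocytes (%d degrade within 6 h)\n",
            length(cohort$timelines), sum(cohort$truth$degraded)))

grid <- gen_grid(cfg, seed = 2)
manifest <- data.frame(file = sprintf("curve_%02d.tsv", seq_along(grid)),
                       oocyte_id = "oo_demo",
                       row = sapply(grid, function(cv) cv$position$row),
                       col = sapply(grid, function(cv) cv$position$col),
                       replicate = sapply(grid, function(cv)
                         cv$position$replicate))
for (i in seq_along(grid))
  write_curve(grid[[i]], file.path("results/curves", manifest$file[i]))
write.csv(manifest, "results/curves/manifest.csv", row.names = FALSE)
cat(sprintf("grid: %d curves written to results/curves/\n", length(grid)))

# relaxation series: ZP relaxation time halves as the oocyte ages
zp_taus <- c(2.0, 2.0, 1.9, 1.0)
for (i in seq_along(zp_taus)) {
  cfg_i <- synth_config(seed = 30 + i, tau1_true = zp_taus[i],
                        tau2_true = 15)
  tr <- gen_relaxation(cfg_i, seed = 30 + i)
  write.csv(data.frame(t_s = tr$t, force_nN = tr$force),
            sprintf("results/relaxation_h%d.csv", i - 1),
            row.names = FALSE)
}
cat(sprintf("relaxation: %d hourly holds written\n", length(zp_taus)))

cat("done: synthetic inputs in results/\n")
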