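#!/usr/bin/env Rscript
# Quantify the cortical-granule fluorescence signal on two synthetic
# stacks: a bleaching-only negative control (no activator) and a stack
# with a CG-release event. Series are normalized to their first frame.

suppressPackageStartupMessages(library(ovomech))

cfg <- synth_config(seed = 20261001)

ctrl <- gen_fluor_stack(cfg, seed = 41)
ms_ctrl <- measure_stack(ctrl)
cat(sprintf(
  "control (no activator): normalized signal falls to %.3f after 90 min\n(photobleaching bound: ~20%% of the fluorophores)\n",
  tail(ms_ctrl$normalized, 1)))

onset <- 30
release <- gen_fluor_stack(cfg, seed = 42, bleach = FALSE,
                           cg_schedule = function(tm)
                             if (tm >= onset) 1 + 0.1 * (tm - onset) else 1)
ms_rel <- measure_stack(release)
first_up <- ms_rel$t_min[which(ms_rel$normalized >
  1 + 3 * sd(ms_rel$normalized[ms_rel$t_min < onset]))[1]]
cat(sprintf(
  "CG release: signal departs from baseline at t = %g min (onset %g min)\n",
  first_up, onset))

write.csv(data.frame(t_min = ms_ctrl$t_min,
                     control = ms_ctrl$normalized,
                     release = ms_rel$normalized),
          "results/fluorescence_series.csv", row.names = FALSE)
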