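#!/usr/bin/env Rscript
# Step 5: simulation-based power study.
#
# For completion-age differences of 0, 1 and 4 years at n = 200
# participants, simulates 30 studies each (inter curve = intra curve with
# the midpoint age shifted), refits the model, and records how often the
# posterior probability of a positive inter-minus-intra contrast exceeds
# the 0.75 support threshold. Expect the 1-year difference to be detected
# about as rarely as the 0-year null and the 4-year difference to be
# detected in most studies. Runtime is a few minutes on one CPU.

library(normtraj)

dir.create("results", showWarnings = FALSE)

SEED <- 20260925 %% 2147483647
cfg <- sampler_config(chains = 2, iterations = 3000, seed = 1)

rows <- lapply(c(0, 1, 4), function(delta) {
  pw <- power_study(delta_years = delta, n_participants = 200,
                    replicates = 30, seed = SEED, config = cfg)
  cat(sprintf("delta = %d years: detection fraction %.2f\n",
              delta, pw$detection_fraction))
  data.frame(delta_years = delta, n_participants = 200, replicates = 30,
             detection_fraction = pw$detection_fraction)
})
power <- do.call(rbind, rows)
write.csv(power, "results/power.csv", row.names = FALSE)
cat("wrote results/power.csv\n")
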