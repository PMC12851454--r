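#!/usr/bin/env Rscript
# Step 1: generate the synthetic study.
#
# Builds a study-sized cohort (205 participants: 122 children 5-16, 83
# adults 17-70, two societies, both Dictator Game conditions each in
# counterbalanced order) with choices drawn from the logistic trajectory
# model at the study-sized generative truth, plus the exclusion fixture
# with the four rules in counts 5/5/11/5. Writes the trial and flag CSVs
# under results/.

library(normtraj)

SEED <- 20260925 %% 2147483647
dir.create("results", showWarnings = FALSE)

trials <- simulate_trials(default_truth(), default_design(), seed = SEED)
write_trials(trials, "results/trials.csv")
cat(sprintf("wrote results/trials.csv: %d records, %d participants\n",
            nrow(trials), length(unique(trials$participant_id))))

fx <- exclusion_fixture(seed = SEED)
write_exclusion_flags(fx$flags, "results/exclusion_flags.csv")
excl <- apply_exclusions(fx$participants, fx$flags)
cat("exclusion accounting:\n")
print(excl$report$rule_counts)
cat(sprintf("retained %d of %d participants\n",
            excl$report$n_retained, excl$report$n_total))
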