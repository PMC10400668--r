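#!/usr/bin/env Rscript
# Stage 5: parameter-recovery check (reduced replicate count).
#
# Repeats the full chain on independently seeded synthetic experiments and
# compares the mean recovered estimates to the generating truth. The
# acceptance script (scripts/acceptance.R) runs the full 200-replicate
# version; this driver uses 25 replicates for a quick look.

library(thermacclim)

study <- recovery_study(n_seeds = 25, base_seed = 1)
s <- summarize_recovery(study)
dir.create("results", showWarnings = FALSE)
write.csv(s, "results/recovery_summary.csv", row.names = FALSE)
print(s, digits = 3, row.names = FALSE)
cat("\nfull-precision study: Rscript scripts/acceptance.R --seed 1",
    "--out results/acceptance.json\n")
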