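#!/usr/bin/env Rscript
# Signal quality control.
#
# Applies the saturation (electronic clipping) check to every channel of the
# simulated cohort and writes the per-channel QC table. Participants with a
# failing channel would be flagged for exclusion here, mirroring the
# protocol's visual-analysis exclusions; the synthetic cohort is expected to
# pass throughout.

suppressPackageStartupMessages(library(ppgssc))

proto <- desk_protocol()
cohort <- read_cohort("results/cohort", proto)

qc <- qc_cohort(cohort)
utils::write.csv(qc, "results/qc.csv", row.names = FALSE)

n_fail <- sum(!qc$pass)
cat(sprintf("QC: %d of %d channel traces pass (%d flagged)\n",
            sum(qc$pass), nrow(qc), n_fail))
if (n_fail > 0) {
  cat("Flagged participants:\n")
  print(unique(qc$participant_id[!qc$pass]))
} else {
  cat("No participant excluded.\n")
}
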