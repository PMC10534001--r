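#!/usr/bin/env Rscript
# Participant-wise stratified 10-fold partition.
#
# One plan is built from the manifest and serialised; both classification
# branches consume this same file, which is what guarantees the fair
# inter-branch comparison and that no participant's data ever straddles
# training and test.

suppressPackageStartupMessages(library(ppgssc))

manifest <- utils::read.csv("results/cohort/manifest.csv")
plan <- make_folds(manifest, k = 10, seed = 1)
write_fold_plan(plan, "results/folds.json")

print(plan)
ssc <- manifest$participant_id[manifest$class_label == "SSc"]
cat("SSc per fold:", tabulate(plan$assignments[ssc], plan$k), "\n")
cat("Plan written to results/folds.json\n")
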