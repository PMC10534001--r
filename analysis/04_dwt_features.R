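#!/usr/bin/env Rscript
# Comparator feature stage.
#
# Ten-level db4 DWT per gain-normalised channel over the whole recording,
# band selection (d6-d10 + ap) and the four per-band features, giving the
# 144-column participant feature table used by LDA and KNN.

suppressPackageStartupMessages(library(ppgssc))

proto <- desk_protocol()
cohort <- read_cohort("results/cohort", proto)

feats <- cohort_features(cohort)
utils::write.csv(feats, "results/features.csv", row.names = FALSE)

cat(sprintf("Feature table: %d participants x %d features\n",
            nrow(feats), ncol(feats) - 2))
# quick class contrast on total selected-band energy
en <- rowSums(feats[, grep("_energy$", colnames(feats))])
cat("Median total band energy by class:\n")
print(tapply(en, feats$class_label, median))
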