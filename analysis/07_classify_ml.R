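#!/usr/bin/env Rscript
# Feature branch: LDA and KNN (K = 9) on the 144-feature table, using the
# identical fold plan as the deep-learning branch.

suppressPackageStartupMessages(library(ppgssc))

feats <- utils::read.csv("results/features.csv")
plan <- read_fold_plan("results/folds.json")

for (cls in c("lda", "knn")) {
  pred <- run_cv_features(feats, plan, classifier = cls)
  utils::write.csv(pred, sprintf("results/predictions_%s.csv", cls),
                   row.names = FALSE)
  cat(sprintf("%s participant accuracy: %.1f%%\n", toupper(cls),
              100 * mean(pred$truth == pred$predicted)))
}
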