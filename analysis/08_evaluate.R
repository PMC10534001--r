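#!/usr/bin/env Rscript
# Evaluation: combined confusion matrices, image- and participant-level
# diagnostic metrics with exact 95% CIs, and the crosshair-plot data export
# (sensitivity versus false positive rate) across all classifiers.

suppressPackageStartupMessages(library(ppgssc))

dl <- utils::read.csv("results/predictions_dl.csv")
ev_dl <- evaluate_predictions(dl)

feature_eval <- function(path) {
  pred <- utils::read.csv(path)
  metrics(confusion_matrix(pred$truth, pred$predicted))
}
m_lda <- feature_eval("results/predictions_lda.csv")
m_knn <- feature_eval("results/predictions_knn.csv")

cat("== CNN, image-based ==\n"); print(ev_dl$image$metrics)
cat("== CNN, participant-based (majority vote) ==\n")
print(ev_dl$participant$metrics)
cat("== LDA, participant-based ==\n"); print(m_lda)
cat("== KNN, participant-based ==\n"); print(m_knn)

sets <- list(cnn_participant = ev_dl$participant$metrics,
             lda = m_lda, knn = m_knn)
crosshair_export(sets, file = "results/crosshair.csv")

to_row <- function(m, branch, level) {
  cm <- m$cm
  data.frame(branch = branch, level = level, tp = cm$tp, fn = cm$fn,
             fp = cm$fp, tn = cm$tn,
             accuracy = round_half_up(m$accuracy[["value"]]),
             sensitivity = round_half_up(m$sensitivity[["value"]]),
             specificity = round_half_up(m$specificity[["value"]]))
}
summary <- rbind(to_row(ev_dl$image$metrics, "cnn", "image"),
                 to_row(ev_dl$participant$metrics, "cnn", "participant"),
                 to_row(m_lda, "lda", "participant"),
                 to_row(m_knn, "knn", "participant"))
utils::write.csv(summary, "results/metrics_summary.csv", row.names = FALSE)
cat("Summary written to results/metrics_summary.csv and crosshair.csv\n")
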