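#!/usr/bin/env Rscript
# Deep-learning branch: 10-fold CV of the compact scalogram-image CNN.
#
# Each fold trains a freshly seeded network (SGD, learning rate 0.005,
# momentum 0.9, 10 minibatches, 10 epochs) on the training participants'
# images and predicts every held-out image; image-level predictions are
# written for the evaluation stage.

suppressPackageStartupMessages(library(ppgssc))

tn <- readRDS("scratch/tensors.rds")
plan <- read_fold_plan("results/folds.json")

t0 <- Sys.time()
pred <- run_cv_images(tn$tensors, tn$meta, plan, train_config(seed = 1))
cat(sprintf("CV over %d images in %s\n", nrow(pred),
            format(round(Sys.time() - t0))))

utils::write.csv(pred, "results/predictions_dl.csv", row.names = FALSE)
cat(sprintf("Image-level accuracy: %.1f%%\n",
            100 * mean(pred$truth == pred$predicted)))
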