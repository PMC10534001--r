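#!/usr/bin/env Rscript
# Scalogram image stage.
#
# Gain-normalises each recording, cuts consecutive 30-s windows per channel,
# computes Morse-CWT percent-energy scalograms, renders 224x224x3 images and
# pools them to classifier tensors. Tensors plus the provenance index are
# written under results/; a handful of example PNGs are exported for visual
# inspection.

suppressPackageStartupMessages(library(ppgssc))

proto <- desk_protocol()
cohort <- read_cohort("results/cohort", proto)

t0 <- Sys.time()
tn <- cohort_tensors(cohort)
cat(sprintf("Computed %d scalogram tensors in %s\n", nrow(tn$tensors),
            format(round(Sys.time() - t0))))

utils::write.csv(tn$meta, "results/image_index.csv", row.names = FALSE)
dir.create("scratch", showWarnings = FALSE)
saveRDS(tn, "scratch/tensors.rds")  # scratch: large intermediate

# example images: first baseline, occlusion and flush window of the
# occluded channel for one participant of each class
if (requireNamespace("png", quietly = TRUE)) {
  dir.create("results/example_images", showWarnings = FALSE)
  for (i in c(1, which(cohort$manifest$class_label == "Control")[1])) {
    rec <- cohort$recordings[[i]]
    rt <- recording_tensors(rec, keep_images = TRUE)
    keep <- which(rt$meta$channel == "left_finger")[c(1, 6, 9)]
    for (k in keep) {
      m <- rt$meta[k, ]
      write_scalogram_png(rt$images[[k]], sprintf(
        "results/example_images/%s_%s_w%02d.png",
        m$participant_id, m$channel, m$window_index))
    }
  }
  cat("Example PNGs in results/example_images/\n")
}
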