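# End-to-end drivers tying the stages together: recording -> windows ->
# scalogram images -> classifier tensors, and the full synthetic benchmark
# used by the analysis scripts and the acceptance checks.

#' Scalogram tensors for every window of a recording
#'
#' Gain-normalises the recording, cuts consecutive 30-s windows per channel,
#' computes the Morse-CWT percent-energy scalogram of each, renders the
#' fixed-size RGB image and pools it to the classifier input tensor.
#' Degenerate zero-energy windows are excluded with a warning.
#'
#' @param recording A `ppg_recording`.
#' @param window_seconds Window length (default 30 s).
#' @param voices_per_octave CWT voices per octave (default 12).
#' @param freq_range Image frequency crop in Hz (default 0-20).
#' @param colormap Colour map name.
#' @param keep_images Keep the rendered 224 x 224 x 3 images in the result
#'   (memory-heavy; default `FALSE`).
#' @return List with `meta` (data frame: participant, channel, window_index,
#'   start_time, class_label) and `tensors` (matrix, one image per row);
#'   `images` when `keep_images = TRUE`.
#' @export
recording_tensors <- function(recording, window_seconds = 30,
                              voices_per_octave = 12,
                              freq_range = c(0, 20),
                              colormap = "viridis",
                              keep_images = FALSE) {
  rec <- if (isTRUE(recording$normalized)) recording
         else gain_normalize(recording)
  windows <- window_signal(rec, window_seconds)
  meta <- list()
  tensors <- list()
  images <- list()
  for (w in windows) {
    cw <- cwt_morse(w, voices_per_octave = voices_per_octave)
    sm <- to_scalogram(cw)
    if (is.null(sm)) next
    img <- render_image(sm, colormap = colormap, freq_range = freq_range)
    k <- length(meta) + 1
    meta[[k]] <- data.frame(participant_id = w$participant_id,
                            class_label = w$class_label,
                            channel = w$channel,
                            window_index = w$window_index,
                            start_time = w$start_time,
                            stringsAsFactors = FALSE)
    tensors[[k]] <- cnn_input_tensor(img)
    if (keep_images) images[[k]] <- img
  }
  out <- list(meta = do.call(rbind, meta),
              tensors = do.call(rbind, tensors))
  if (keep_images) out$images <- images
  out
}

#' Scalogram tensors for a whole cohort
#'
#' @param cohort Cohort from [generate_cohort()] (or list of recordings).
#' @param ... Passed to [recording_tensors()].
#' @return List with stacked `meta` and `tensors`.
#' @export
cohort_tensors <- function(cohort, ...) {
  recs <- if (!is.null(cohort$recordings)) cohort$recordings else cohort
  parts <- lapply(recs, recording_tensors, ...)
  list(meta = do.call(rbind, lapply(parts, `[[`, "meta")),
       tensors = do.call(rbind, lapply(parts, `[[`, "tensors")))
}

#' Full synthetic benchmark of both classification branches
#'
#' Generates a seeded synthetic cohort, builds one participant-wise
#' stratified fold plan, and runs both branches on the identical partition:
#' the deep-learning branch (scalogram images, compact CNN, image-level and
#' majority-vote participant-level evaluation) and the feature branch
#' (144-element DWT feature vectors into LDA and KNN, participant-level
#' evaluation).
#'
#' @param n_ssc,n_control Cohort composition (default 10 / 25).
#' @param protocol Acquisition protocol; defaults to the desk-scale protocol
#'   (200 Hz, 300 s with the 2:1:1 phase structure).
#' @param separation Phenotype preset (default `"strong"`; see
#'   [phenotype_defaults()]).
#' @param k Cross-validation folds (default 10).
#' @param config Image-classifier [train_config()].
#' @param knn_k Neighbour count for KNN (default 9).
#' @param seed Master seed driving cohort generation, fold assignment and
#'   classifier training.
#' @return List: `cohort_manifest`, `plan`, `dl` (image predictions plus
#'   image- and participant-level metrics), `lda` and `knn` (participant
#'   predictions and metrics).
#' @export
synthetic_benchmark <- function(n_ssc = 10, n_control = 25,
                                protocol = desk_protocol(),
                                separation = "strong",
                                k = 10,
                                config = NULL,
                                knn_k = 9,
                                seed = 1) {
  if (is.null(config)) config <- train_config(seed = seed)
  cohort <- generate_cohort(n_ssc, n_control, protocol,
                            separation = separation, seed = seed)
  plan <- make_folds(cohort$manifest, k = k, seed = seed)

  tn <- cohort_tensors(cohort)
  img_pred <- run_cv_images(tn$tensors, tn$meta, plan, config)
  dl_eval <- evaluate_predictions(img_pred)

  feats <- cohort_features(cohort)
  feat_eval <- function(classifier) {
    pred <- run_cv_features(feats, plan, classifier = classifier, k = knn_k)
    cm <- confusion_matrix(pred$truth, pred$predicted)
    list(predictions = pred, cm = cm, metrics = metrics(cm))
  }
  list(cohort_manifest = cohort$manifest,
       plan = plan,
       dl = c(list(image_predictions = img_pred), dl_eval),
       lda = feat_eval("lda"),
       knn = feat_eval("knn"))
}
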