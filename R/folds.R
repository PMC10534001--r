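#' Participant-wise stratified k-fold partition
#'
#' Assigns every participant to exactly one test fold. Within each class the
#' participants are shuffled (seeded) and dealt round-robin to folds, with
#' the dealing pointer continuing across classes, so per-fold class counts
#' differ by at most one and fold sizes differ by at most one. Because
#' assignment is by participant, all of a participant's windows, images and
#' features travel together - the partition shared by the deep-learning and
#' feature branches guarantees data from one subject never appears in
#' training and test simultaneously.
#'
#' @param manifest Data frame with `participant_id` and `class_label`
#'   columns (e.g. the cohort manifest).
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the within-class shuffles.
#' @return Object of class `ppg_fold_plan`: `k`, `seed`, `assignments`
#'   (named integer vector, participant -> fold).
#' @export
#' @examples
#' m <- data.frame(participant_id = sprintf("P%02d", 1:12),
#'                 class_label = rep(c("SSc", "Control"), c(4, 8)))
#' table(make_folds(m, k = 4, seed = 1)$assignments)
make_folds <- function(manifest, k = 10, seed = 1) {
  ids <- as.character(manifest$participant_id)
  labels <- as.character(manifest$class_label)
  n <- length(ids)
  if (anyDuplicated(ids)) stop("duplicate participant ids in manifest")
  if (k < 2 || k > n) stop("k must be between 2 and the participant count")
  set.seed(seed)
  assignments <- integer(n)
  names(assignments) <- ids
  ptr <- 0L
  classes <- unique(c("SSc", sort(unique(labels))))
  classes <- classes[classes %in% labels]
  for (cl in classes) {
    members <- ids[labels == cl]
    members <- members[sample.int(length(members))]
    for (m in members) {
      assignments[m] <- (ptr %% k) + 1L
      ptr <- ptr + 1L
    }
  }
  plan <- structure(list(k = as.integer(k), seed = as.integer(seed),
                         assignments = assignments),
                    class = "ppg_fold_plan")
  validate_fold_plan(plan, manifest)
  plan
}

validate_fold_plan <- function(plan, manifest) {
  a <- plan$assignments
  sizes <- tabulate(a, plan$k)
  if (diff(range(sizes)) > 1) stop("fold sizes differ by more than 1")
  for (cl in unique(manifest$class_label)) {
    cc <- tabulate(a[as.character(
      manifest$participant_id[manifest$class_label == cl])], plan$k)
    if (diff(range(cc)) > 1)
      stop("per-fold class counts differ by more than 1 for class ", cl)
  }
  invisible(plan)
}

#' @export
print.ppg_fold_plan <- function(x, ...) {
  cat(sprintf("Participant-wise fold plan: %d participants in %d folds (seed %d)\n",
              length(x$assignments), x$k, x$seed))
  print(tabulate(x$assignments, x$k))
  invisible(x)
}

#' Serialise / read a fold plan as JSON
#'
#' The plan file is the single source of truth shared by both classification
#' branches.
#'
#' @param plan A `ppg_fold_plan`.
#' @param path File path.
#' @return `path` (writer) or the plan (reader).
#' @export
write_fold_plan <- function(plan, path) {
  jsonlite::write_json(list(k = plan$k, seed = plan$seed,
                            assignments = as.list(plan$assignments)),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_fold_plan
#' @export
read_fold_plan <- function(path) {
  j <- jsonlite::read_json(path)
  structure(list(k = as.integer(j$k), seed = as.integer(j$seed),
                 assignments = unlist(j$assignments)),
            class = "ppg_fold_plan")
}

#' Assert that training and test participants are disjoint
#'
#' Runtime leakage guard called by every cross-validation executor; a
#' participant present on both sides is a hard error.
#'
#' @param train_ids,test_ids Participant id vectors.
#' @return `TRUE`, invisibly.
#' @export
assert_no_leakage <- function(train_ids, test_ids) {
  common <- intersect(unique(train_ids), unique(test_ids))
  if (length(common) > 0)
    stop("participant leakage between training and test sets: ",
         paste(common, collapse = ", "))
  invisible(TRUE)
}

#' Cross-validate the feature branch (LDA or KNN)
#'
#' For each fold, fits the classifier on the training participants' feature
#' vectors and predicts the held-out participants, so every participant is
#' predicted exactly once.
#'
#' @param features Feature table from [cohort_features()].
#' @param plan A `ppg_fold_plan` covering all participants present.
#' @param classifier `"lda"` or `"knn"`.
#' @param k Neighbour count for KNN (default 9).
#' @param ridge Diagonal loading for LDA.
#' @return Data frame: `participant_id`, `truth`, `predicted`, `fold`.
#' @export
run_cv_features <- function(features, plan,
                            classifier = c("lda", "knn"),
                            k = 9, ridge = 1e-4) {
  classifier <- match.arg(classifier)
  ids <- as.character(features$participant_id)
  if (!all(ids %in% names(plan$assignments)))
    stop("participant missing from fold plan: ",
         paste(setdiff(ids, names(plan$assignments)), collapse = ", "))
  fcols <- setdiff(colnames(features), c("participant_id", "class_label"))
  x <- as.matrix(features[, fcols])
  y <- as.character(features$class_label)
  fold_of <- plan$assignments[ids]
  out <- list()
  for (f in seq_len(plan$k)) {
    test <- fold_of == f
    if (!any(test)) next
    assert_no_leakage(ids[!test], ids[test])
    model <- if (classifier == "lda")
      fit_lda(x[!test, , drop = FALSE], y[!test], ridge = ridge)
    else
      fit_knn(x[!test, , drop = FALSE], y[!test], k = k)
    pred <- if (classifier == "lda")
      predict(model, x[test, , drop = FALSE])$class
    else
      predict(model, x[test, , drop = FALSE])
    out[[f]] <- data.frame(participant_id = ids[test], truth = y[test],
                           predicted = pred, fold = f,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cross-validate the image branch
#'
#' For each fold, trains a freshly initialised image classifier on the
#' training participants' scalogram tensors (per-fold seed derived from the
#' configuration seed) and predicts every test image, producing image-level
#' predictions for majority-vote aggregation.
#'
#' @param tensors Matrix of input tensors (one image per row, from
#'   [cnn_input_tensor()]).
#' @param meta Data frame aligned with `tensors` rows: `participant_id`,
#'   `channel`, `window_index`, `class_label`.
#' @param plan A `ppg_fold_plan`.
#' @param config A [train_config()].
#' @return Data frame: provenance columns, `truth`, `predicted`,
#'   `score_ssc`, `fold`.
#' @export
run_cv_images <- function(tensors, meta, plan, config = train_config()) {
  ids <- as.character(meta$participant_id)
  if (!all(ids %in% names(plan$assignments)))
    stop("participant missing from fold plan: ",
         paste(unique(setdiff(ids, names(plan$assignments))), collapse = ", "))
  fold_of <- plan$assignments[ids]
  out <- list()
  for (f in seq_len(plan$k)) {
    test <- fold_of == f
    if (!any(test)) next
    assert_no_leakage(ids[!test], ids[test])
    cfg <- config
    cfg$seed <- config$seed + f
    model <- build_model(cfg)
    model <- train_model(model, tensors[!test, , drop = FALSE],
                         meta$class_label[!test], cfg)
    p <- predict(model, tensors[test, , drop = FALSE])
    pred <- colnames(p)[max.col(p, ties.method = "first")]
    out[[f]] <- data.frame(
      participant_id = ids[test],
      channel = meta$channel[test],
      window_index = meta$window_index[test],
      truth = meta$class_label[test],
      predicted = pred,
      score_ssc = if ("SSc" %in% colnames(p)) p[, "SSc"] else NA_real_,
      fold = f, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
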