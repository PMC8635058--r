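# Leave-one-subject-out CNN classification of topogram stacks. Each fold
# trains on all images of all subjects but one and tests on the held-out
# subject's images, emulating a pre-trained decoder applied to a naive
# user. HA is the positive class throughout (LA = 0, HA = 1).

#' Build leave-one-subject-out splits
#'
#' One split per subject: that subject's images form the test set, all
#' remaining images the training set. With the full study emulation
#' (20 subjects x 600 images) every fold holds 11,400 training and 600
#' test images.
#'
#' @param stacks named or unnamed list of per-subject `topogram_stack`s.
#' @return list of `loso_split`s with fields `test_subject`,
#'   `train_subjects`, `train_size`, `test_size`.
#' @export
build_loso_splits <- function(stacks) {
  stopifnot(length(stacks) >= 2)
  sizes <- vapply(stacks, stack_size, numeric(1))
  if (any(sizes == 0)) stop("subject with zero images")
  ids <- vapply(stacks, function(s) s$subject_id, numeric(1))
  lapply(seq_along(stacks), function(i) {
    structure(list(test_subject = ids[i], train_subjects = ids[-i],
                   test_index = i, train_index = seq_along(stacks)[-i],
                   train_size = sum(sizes[-i]), test_size = sizes[i]),
              class = "loso_split")
  })
}

# flatten a list of stacks into one image array + labels + provenance ids
.gather_images <- function(stacks) {
  sz <- dim(stacks[[1]]$images)[3]
  n <- sum(vapply(stacks, stack_size, numeric(1)))
  images <- array(NA_real_, c(n, sz, sz))
  labels <- character(n); image_id <- character(n)
  trial_key <- character(n)
  pos <- 0L
  for (s in stacks) {
    dm <- dim(s$images)
    for (ci in seq_len(dm[2])) {
      sel <- pos + seq_len(dm[1])
      images[sel, , ] <- s$images[, ci, , ]
      labels[sel] <- s$labels
      image_id[sel] <- sprintf("s%s_t%d_c%d", s$subject_id, s$trial_ids, ci)
      trial_key[sel] <- sprintf("s%s_t%d", s$subject_id, s$trial_ids)
      pos <- pos + dm[1]
    }
  }
  list(images = images, labels = labels, image_id = image_id,
       trial_key = trial_key)
}

#' Train the CNN on one LOSO fold
#'
#' Gathers the training subjects' images and fits the small CNN with a
#' seeded run; early stopping uses a held-out slice of the training
#' images (never the test subject).
#'
#' @param split a `loso_split`.
#' @param stacks the per-subject stack list the split was built from.
#' @param config a [cnn_config()].
#' @return a `cnn_model` with the fold's training image ids attached.
#' @export
train_cnn <- function(split, stacks, config = cnn_config()) {
  tr <- .gather_images(stacks[split$train_index])
  model <- cnn_fit(tr$images, tr$labels, config)
  model$train_image_ids <- tr$image_id
  model$test_subject <- split$test_subject
  model
}

#' Evaluate a fold
#'
#' Predicts the held-out subject's images and reports the confusion counts
#' and derived metrics with HA as the positive class. An image-id check
#' asserts that no test image was seen in training. Alongside the primary
#' image-level metrics, trial-level results (mean HA probability across a
#' trial's cluster images) are reported as an extension.
#'
#' @param model a model from [train_cnn()].
#' @param split the corresponding `loso_split`.
#' @param stacks the per-subject stack list.
#' @param threshold decision threshold on the HA probability (default 0.5).
#' @return an `eval_report`: `confusion` (TP/FP/TN/FN), `accuracy`,
#'   `precision`, `recall`, `n`, `trial_level` (same metrics after fusion),
#'   `test_subject`.
#' @export
evaluate <- function(model, split, stacks, threshold = 0.5) {
  te <- .gather_images(stacks[split$test_index])
  if (length(intersect(te$image_id, model$train_image_ids)) > 0)
    stop("leakage: test images present in the training set")
  prob <- predict(model, te$images)
  rep_img <- .metrics(te$labels, prob[, "HA"] >= threshold)
  fused <- tapply(prob[, "HA"], te$trial_key, mean)
  fused_lab <- tapply(te$labels, te$trial_key, function(l) l[1])
  rep_tr <- .metrics(as.character(fused_lab), as.vector(fused) >= threshold)
  structure(c(rep_img, list(trial_level = rep_tr,
                            test_subject = split$test_subject)),
            class = "eval_report")
}

# confusion counts and metric identities; pred is logical "predicted HA"
.metrics <- function(labels, pred_ha) {
  truth <- labels == "HA"
  TP <- sum(pred_ha & truth); FP <- sum(pred_ha & !truth)
  FN <- sum(!pred_ha & truth); TN <- sum(!pred_ha & !truth)
  list(confusion = c(TP = TP, FP = FP, TN = TN, FN = FN),
       accuracy = (TP + TN) / length(truth),
       precision = if (TP + FP > 0) TP / (TP + FP) else NA_real_,
       recall = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
       n = length(truth))
}

#' Run the full LOSO evaluation
#'
#' Trains and evaluates every fold and aggregates the per-fold metrics.
#'
#' @param stacks per-subject `topogram_stack` list.
#' @param config a [cnn_config()]; each fold derives its seed from
#'   `config$seed` plus the fold number so folds are independent but
#'   reproducible.
#' @param folds optional subset of fold indices to run.
#' @return a `loso_result`: `per_fold` data frame (subject, accuracy,
#'   precision, recall, image counts), `mean_accuracy`, `sd_accuracy`,
#'   `reports`.
#' @export
run_loso <- function(stacks, config = cnn_config(), folds = NULL) {
  splits <- build_loso_splits(stacks)
  folds <- folds %||% seq_along(splits)
  reports <- list()
  rows <- list()
  for (i in folds) {
    cfg <- config
    cfg$seed <- config$seed + i
    model <- train_cnn(splits[[i]], stacks, cfg)
    rep <- evaluate(model, splits[[i]], stacks)
    reports[[length(reports) + 1]] <- rep
    rows[[length(rows) + 1]] <- data.frame(
      test_subject = rep$test_subject, accuracy = rep$accuracy,
      precision = rep$precision, recall = rep$recall, n_images = rep$n,
      trial_accuracy = rep$trial_level$accuracy)
  }
  per_fold <- do.call(rbind, rows)
  structure(list(per_fold = per_fold,
                 mean_accuracy = mean(per_fold$accuracy),
                 sd_accuracy = sd(per_fold$accuracy),
                 reports = reports), class = "loso_result")
}
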