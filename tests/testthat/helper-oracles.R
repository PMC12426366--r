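# Independent brute-force oracles. Each rebuilds the per-image surviving
# and confirmed label sets and classifies one image at a time, a
# different route from the implementation's whole-column set arithmetic.

# Per-class image-level TP/FP/FN by walking every image in the union of
# truth and predictions.
oracle_tallies <- function(predictions, truth, class, threshold) {
  imgs <- unique(c(truth$image_id, predictions$image_id))
  keep <- predictions$score >= threshold
  surviving <- split(predictions$class[keep], predictions$image_id[keep])
  confirmed <- split(truth$class, truth$image_id)
  tp <- 0L; fp <- 0L; fn <- 0L
  for (img in imgs) {
    in_truth <- class %in% confirmed[[img]]
    in_pred <- class %in% surviving[[img]]
    if (in_truth) {
      if (in_pred) tp <- tp + 1L else fn <- fn + 1L
    } else if (in_pred) {
      fp <- fp + 1L
    }
  }
  c(TP = tp, FP = fp, FN = fn)
}

# Binary confusion by walking per-image records at one threshold.
oracle_binary_confusion <- function(binary, threshold) {
  tp <- 0L; fp <- 0L; fn <- 0L; tn <- 0L
  for (i in seq_len(nrow(binary))) {
    pred_animal <- !is.na(binary$max_animal_score[i]) &&
      binary$max_animal_score[i] >= threshold
    truly_animal <- binary$true_state[i] == "animal"
    if (truly_animal && pred_animal) tp <- tp + 1L
    else if (truly_animal) fn <- fn + 1L
    else if (pred_animal) fp <- fp + 1L
    else tn <- tn + 1L
  }
  c(TP = tp, FP = fp, FN = fn, TN = tn)
}

# Random small instance: <= `max_images` images, <= `n_classes` classes,
# <= 3 predictions per image, scores on a coarse random grid so exact
# ties with thresholds are common.
random_instance <- function(max_images = 50L, n_classes = 5L) {
  n_img <- sample.int(max_images, 1L)
  classes <- paste0("sp", seq_len(sample.int(n_classes, 1L)))
  imgs <- sprintf("im%03d", seq_len(n_img))
  score_grid <- sort(unique(round(stats::runif(8), 2)))
  preds <- list()
  truths <- list()
  for (img in imgs) {
    k <- sample.int(4L, 1L) - 1L   # 0..3 predictions
    if (k > 0) {
      preds[[length(preds) + 1L]] <- data.frame(
        image_id = img, class = sample(classes, k, replace = TRUE),
        score = sample(score_grid, k, replace = TRUE),
        stringsAsFactors = FALSE)
    }
    m <- sample.int(min(3L, length(classes) + 1L), 1L) - 1L  # 0..2 true classes
    if (m > 0) {
      truths[[length(truths) + 1L]] <- data.frame(
        image_id = img, class = sample(classes, m),
        count = sample.int(4L, m, replace = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  predictions <- if (length(preds)) {
    p <- do.call(rbind, preds)
    pred_df(p$image_id, p$class, p$score)
  } else pred_df()
  truth <- if (length(truths)) do.call(rbind, truths) else truth_df()
  list(predictions = predictions, truth = truth, classes = classes,
       images = imgs,
       thresholds = sort(unique(c(score_grid,
                                  pmin(1, score_grid + 0.005), 0, 1))))
}
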