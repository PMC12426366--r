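# Empty-image filtering evaluation: collapse all species classes to a
# single "animal" label, tally image-level confusion across score
# thresholds, compare two detectors, and plan manual review subsets.

#' Collapse predictions and truth to per-image animal/empty records
#'
#' Every reviewed image in the manifest yields one record with its true
#' state (`"animal"` if any verified annotation carries an animal-role
#' label, `"empty"` if it has none) and `max_animal_score`, the maximum
#' score over that image's predictions whose label has the animal role
#' (NA when there are none). Images whose only content — true or
#' predicted — is human or vehicle, and images whose truth holds more
#' than one class, are excluded by default, mirroring the usual practice
#' of scoring the animal/blank discrimination on single-class animal and
#' confirmed-empty images only.
#'
#' @param predictions predictions data.frame.
#' @param truth truth data.frame (verified annotations).
#' @param manifest manifest data.frame; only `reviewed == TRUE` images
#'   enter the result.
#' @param vocabulary a [class_vocabulary()].
#' @param keep_excluded keep human/vehicle-only and multi-class images,
#'   treating non-animal content as empty (default FALSE).
#' @return data.frame with columns `image_id`, `true_state`
#'   (`"animal"`/`"empty"`), `max_animal_score` (NA when no animal
#'   prediction).
#' @export
collapse_to_binary <- function(predictions, truth, manifest, vocabulary,
                               keep_excluded = FALSE) {
  stopifnot(inherits(vocabulary, "class_vocabulary"))
  check_images_in_manifest(predictions, manifest, "predictions")
  check_images_in_manifest(truth, manifest, "truth")
  check_vocabulary_labels(predictions$class, vocabulary)
  check_vocabulary_labels(truth$class, vocabulary)
  animal_labels <- vocabulary_labels(vocabulary, "animal")
  hv_labels <- vocabulary_labels(vocabulary, c("human", "vehicle"))

  imgs <- manifest$image_id[manifest$reviewed]
  true_animal <- imgs %in% truth$image_id[truth$class %in% animal_labels]

  ap <- predictions[predictions$class %in% animal_labels, , drop = FALSE]
  max_score <- rep(NA_real_, length(imgs))
  if (nrow(ap)) {
    mx <- tapply(ap$score, ap$image_id, max)
    hit <- match(imgs, names(mx))
    max_score[!is.na(hit)] <- as.numeric(mx[hit[!is.na(hit)]])
  }

  keep <- rep(TRUE, length(imgs))
  if (!keep_excluded) {
    # human/vehicle-only content (true or predicted), and multi-class truth
    content_any <- imgs %in% c(truth$image_id, predictions$image_id)
    non_hv <- unique(c(truth$image_id[!truth$class %in% hv_labels],
                       predictions$image_id[!predictions$class %in% hv_labels]))
    hv_only <- content_any & !imgs %in% non_hv
    n_true_classes <- tapply(truth$class, truth$image_id,
                             function(x) length(unique(x)))
    multi <- imgs %in% names(n_true_classes)[n_true_classes > 1]
    keep <- !(hv_only | multi)
  }
  data.frame(image_id = imgs[keep],
             true_state = ifelse(true_animal[keep], "animal", "empty"),
             max_animal_score = max_score[keep],
             stringsAsFactors = FALSE)
}

#' Image-level confusion across score thresholds
#'
#' At each threshold `t` an image is predicted to contain an animal iff
#' its `max_animal_score >= t`. TP/FP/FN/TN are tallied against the true
#' state, and sensitivity `TP/(TP+FN)` and specificity `TN/(TN+FP)`
#' computed (NA when a denominator is zero).
#'
#' @param binary per-image records from [collapse_to_binary()].
#' @param thresholds strictly increasing score thresholds in \[0,1\];
#'   defaults to the 0.25–0.95 by 0.10 grid.
#' @return data.frame with columns `threshold`, `TP`, `FP`, `FN`, `TN`,
#'   `sensitivity`, `specificity`.
#' @export
binary_confusion_sweep <- function(binary,
                                   thresholds = threshold_grid(0.25, 0.95,
                                                               0.10)) {
  check_threshold_grid(thresholds)
  if (nrow(binary) == 0L) stop("no images to evaluate")
  is_animal <- binary$true_state == "animal"
  score <- binary$max_animal_score
  out <- lapply(thresholds, function(t) {
    pred_animal <- !is.na(score) & score >= t
    data.frame(threshold = t,
               TP = sum(pred_animal & is_animal),
               FP = sum(pred_animal & !is_animal),
               FN = sum(!pred_animal & is_animal),
               TN = sum(!pred_animal & !is_animal))
  })
  out <- do.call(rbind, out)
  out$sensitivity <- ifelse(out$TP + out$FN > 0,
                            out$TP / (out$TP + out$FN), NA_real_)
  out$specificity <- ifelse(out$TN + out$FP > 0,
                            out$TN / (out$TN + out$FP), NA_real_)
  out
}

#' Agreement between two detectors at a threshold
#'
#' Cross-tabulates predicted-animal status under detectors A and B at one
#' threshold, stratified by the true image state. Both record sets must
#' cover exactly the same images.
#'
#' @param binary_a,binary_b per-image records from [collapse_to_binary()]
#'   for the two detectors.
#' @param threshold score threshold.
#' @return data.frame with columns `threshold`, `a_animal`, `b_animal`
#'   (logicals), `true_state`, and `n`; the eight cells sum to the number
#'   of jointly evaluated images.
#' @export
compare_detectors <- function(binary_a, binary_b, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  diff_n <- length(setdiff(binary_a$image_id, binary_b$image_id)) +
    length(setdiff(binary_b$image_id, binary_a$image_id))
  if (diff_n > 0) {
    stop("detectors evaluated on different image sets (symmetric ",
         "difference of ", diff_n, " images)")
  }
  b <- binary_b[match(binary_a$image_id, binary_b$image_id), ]
  if (any(binary_a$true_state != b$true_state)) {
    stop("true image state disagrees between the two record sets")
  }
  a_pred <- !is.na(binary_a$max_animal_score) &
    binary_a$max_animal_score >= threshold
  b_pred <- !is.na(b$max_animal_score) & b$max_animal_score >= threshold
  cells <- expand.grid(a_animal = c(TRUE, FALSE), b_animal = c(TRUE, FALSE),
                       true_state = c("animal", "empty"),
                       stringsAsFactors = FALSE)
  cells$n <- mapply(function(a, bb, ts) {
    sum(a_pred == a & b_pred == bb & binary_a$true_state == ts)
  }, cells$a_animal, cells$b_animal, cells$true_state)
  cells$threshold <- threshold
  cells[, c("threshold", "a_animal", "b_animal", "true_state", "n")]
}

score_bin <- function(score) {
  # review bins 0-0.25, 0.26-0.50, 0.51-0.75, 0.76-1.0
  cut(score, breaks = c(0, 0.25, 0.50, 0.75, 1.0),
      labels = c("0-0.25", "0.26-0.50", "0.51-0.75", "0.76-1.0"),
      include.lowest = TRUE, right = TRUE)
}

#' Plan a manual review subset
#'
#' Selects images for manual verification following the review protocol
#' of large camera-trap evaluations: (a) every image with an animal
#' prediction at or above `threshold_floor` — except that in any
#' deployment-by-class stratum holding more than `overflow_trigger` such
#' images, a random `bin_sample_target` images per confidence-score bin
#' (0–0.25, 0.26–0.50, 0.51–0.75, 0.76–1.0) are taken instead — and (b) a
#' random `empty_sample_target` predicted-empty images per deployment
#' (all of them when fewer exist). An image is assigned to the stratum of
#' its highest-scoring animal prediction. Deterministic given the seed.
#'
#' @param predictions predictions data.frame.
#' @param manifest manifest data.frame.
#' @param vocabulary a [class_vocabulary()]; only animal-role predictions
#'   qualify an image as predicted-animal.
#' @param threshold_floor minimum score for an animal prediction to
#'   trigger review (default 0.25).
#' @param empty_sample_target predicted-empty images to sample per
#'   deployment (default 100).
#' @param overflow_trigger stratum size above which bin sampling replaces
#'   exhaustive review (default 2000).
#' @param bin_sample_target images per score bin for overflowing strata
#'   (default 50).
#' @param seed integer seed for the random samples.
#' @return data.frame with columns `image_id`, `deployment_id`, `reason`
#'   (`"animal-prediction"`, `"bin-sample"`, or `"empty-sample"`); no
#'   image appears twice.
#' @export
plan_review <- function(predictions, manifest, vocabulary,
                        threshold_floor = 0.25,
                        empty_sample_target = 100L,
                        overflow_trigger = 2000L,
                        bin_sample_target = 50L,
                        seed = 1L) {
  stopifnot(empty_sample_target >= 1, overflow_trigger >= 1,
            bin_sample_target >= 1)
  check_images_in_manifest(predictions, manifest, "predictions")
  animal_labels <- vocabulary_labels(vocabulary, "animal")
  ap <- predictions[predictions$class %in% animal_labels &
                      predictions$score >= threshold_floor, , drop = FALSE]
  plan <- list()
  with_seed(seed, {
    if (nrow(ap)) {
      # top animal prediction per image defines its (deployment, class) stratum
      ap <- ap[order(ap$image_id, -ap$score, ap$class), ]
      top <- ap[!duplicated(ap$image_id), ]
      top$deployment_id <- manifest$deployment_id[match(top$image_id,
                                                        manifest$image_id)]
      strata <- split(top, list(top$deployment_id, top$class), drop = TRUE)
      for (key in sort(names(strata))) {
        st <- strata[[key]]
        if (nrow(st) > overflow_trigger) {
          bins <- score_bin(st$score)
          for (b in levels(bins)) {
            in_bin <- which(bins == b)
            take <- in_bin[sample.int(length(in_bin),
                                      min(bin_sample_target,
                                          length(in_bin)))]
            if (length(take)) {
              plan[[length(plan) + 1L]] <- data.frame(
                image_id = st$image_id[take],
                deployment_id = st$deployment_id[take],
                reason = "bin-sample", stringsAsFactors = FALSE)
            }
          }
        } else {
          plan[[length(plan) + 1L]] <- data.frame(
            image_id = st$image_id, deployment_id = st$deployment_id,
            reason = "animal-prediction", stringsAsFactors = FALSE)
        }
      }
    }
    pred_empty <- setdiff(manifest$image_id,
                          if (nrow(ap)) unique(ap$image_id) else character())
    pe <- manifest[manifest$image_id %in% pred_empty, ]
    for (dep in sort(unique(pe$deployment_id))) {
      ids <- pe$image_id[pe$deployment_id == dep]
      take <- if (length(ids) > empty_sample_target)
        ids[sample.int(length(ids), empty_sample_target)] else ids
      if (length(take)) {
        plan[[length(plan) + 1L]] <- data.frame(
          image_id = take, deployment_id = dep,
          reason = "empty-sample", stringsAsFactors = FALSE)
      }
    }
  })
  out <- if (length(plan)) do.call(rbind, plan) else
    data.frame(image_id = character(), deployment_id = character(),
               reason = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  stopifnot(!anyDuplicated(out$image_id))
  out
}
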