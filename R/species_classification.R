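# Image-level multiclass evaluation: per-class TP/FP/FN tallies over a
# confidence-score threshold sweep, threshold-averaged per-class metrics,
# macro-averages with small-class exclusion, and regressions of
# performance on training-set size.
#
# Tallying rule, per species s and threshold t: an image confirmed to
# contain s is a TP if s is among its surviving (score >= t) predicted
# labels, otherwise an FN; any other image whose surviving predicted
# labels include s is an FP for s. True negatives are not defined.

#' Per-image per-class maximum score
#'
#' When an image holds several predictions of the same class, the highest
#' confidence score among them is the one used for thresholding.
#'
#' @param predictions predictions data.frame.
#' @return data.frame `image_id`, `class`, `score` with one row per
#'   (image, class) pair that has at least one prediction.
#' @export
image_scores <- function(predictions) {
  if (nrow(predictions) == 0L) {
    return(data.frame(image_id = character(), class = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(score ~ image_id + class, data = predictions,
                          FUN = max)
  agg[order(agg$image_id, agg$class), c("image_id", "class", "score")]
}

#' Maximum score of one class on one image
#'
#' @param predictions predictions restricted to a single image.
#' @param class class label.
#' @return the maximum score of that class on the image, or NA when the
#'   class is not predicted there.
#' @export
image_score <- function(predictions, class) {
  s <- predictions$score[predictions$class == class]
  if (length(s)) max(s) else NA_real_
}

#' Image-level TP/FP/FN for one class at one threshold
#'
#' @param predictions predictions data.frame.
#' @param truth truth data.frame covering the reviewed test set.
#' @param class species class label.
#' @param threshold score threshold; predictions with scores below it are
#'   discarded (comparison inclusive, `score >= threshold`).
#' @param vocabulary optional [class_vocabulary()]; when given, `class`
#'   must belong to it.
#' @return named integer vector `c(TP, FP, FN)`.
#' @export
image_level_tallies <- function(predictions, truth, class, threshold,
                                vocabulary = NULL) {
  if (!is.null(vocabulary)) check_vocabulary_labels(class, vocabulary)
  confirmed <- unique(truth$image_id[truth$class == class])
  predicted <- unique(predictions$image_id[predictions$class == class &
                                             predictions$score >= threshold])
  tp <- sum(confirmed %in% predicted)
  c(TP = tp,
    FP = length(predicted) - tp,
    FN = length(confirmed) - tp)
}

prf_from_tallies <- function(TP, FP, FN) {
  precision <- ifelse(TP + FP > 0, TP / (TP + FP), NA_real_)
  recall <- ifelse(TP + FN > 0, TP / (TP + FN), NA_real_)
  f1 <- ifelse(!is.na(precision) & !is.na(recall) & precision + recall > 0,
               2 * precision * recall / (precision + recall), NA_real_)
  list(precision = precision, recall = recall, f1 = f1)
}

#' Threshold sweep of image-level metrics for one class
#'
#' Recomputes TP, FP, FN, precision, recall and F1 at each threshold of
#' the grid (default 0.25 to 1.0 by 0.05, endpoints inclusive; the
#' `t = 1` point keeps only predictions scoring exactly 1).
#'
#' @inheritParams image_level_tallies
#' @param thresholds strictly increasing grid in \[0,1\].
#' @return data.frame with columns `class`, `threshold`, `TP`, `FP`,
#'   `FN`, `precision`, `recall`, `f1`. Undefined metrics are NA.
#' @export
threshold_sweep <- function(predictions, truth, class,
                            thresholds = threshold_grid(0.25, 1.0, 0.05),
                            vocabulary = NULL) {
  check_threshold_grid(thresholds)
  # the per-(image, class) max score determines survival at any threshold
  sc <- image_scores(predictions)
  sc <- sc[sc$class == class, , drop = FALSE]
  confirmed <- unique(truth$image_id[truth$class == class])
  if (!is.null(vocabulary)) check_vocabulary_labels(class, vocabulary)
  rows <- lapply(thresholds, function(t) {
    predicted <- sc$image_id[sc$score >= t]
    tp <- sum(confirmed %in% predicted)
    data.frame(class = class, threshold = t, TP = tp,
               FP = length(predicted) - tp,
               FN = length(confirmed) - tp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  m <- prf_from_tallies(out$TP, out$FP, out$FN)
  out$precision <- m$precision
  out$recall <- m$recall
  out$f1 <- m$f1
  out
}

#' Threshold sweep for every class of a vocabulary
#'
#' @param predictions,truth data.frames.
#' @param vocabulary a [class_vocabulary()]; classes with the animal role
#'   are evaluated.
#' @param thresholds score-threshold grid.
#' @return row-bound [threshold_sweep()] results, one block per class.
#' @export
all_class_sweeps <- function(predictions, truth, vocabulary,
                             thresholds = threshold_grid(0.25, 1.0, 0.05)) {
  classes <- vocabulary_labels(vocabulary, "animal")
  do.call(rbind, lapply(classes, function(cl) {
    threshold_sweep(predictions, truth, cl, thresholds)
  }))
}

#' Threshold-averaged per-class summary
#'
#' The threshold-independent summary of one class: the unweighted mean of
#' precision, recall and F1 over the grid points where each is defined
#' (thresholds at which a metric's denominator is zero are omitted from
#' that metric's average; set `undefined_as_zero = TRUE` to count them as
#' zero instead). Classes with fewer than `min_class_images` images in
#' the training or the test set are flagged for exclusion from
#' macro-averaging.
#'
#' @param sweep one class's [threshold_sweep()] result.
#' @param n_train,n_test training- and test-set image counts for the
#'   class.
#' @param min_class_images exclusion cutoff (default 10).
#' @param undefined_as_zero treat undefined metric points as 0.
#' @return one-row data.frame: `class`, `average_precision`,
#'   `average_recall`, `average_f1`, `n_train_images`, `n_test_images`,
#'   `included_in_macro`.
#' @export
average_metrics <- function(sweep, n_train, n_test,
                            min_class_images = 10L,
                            undefined_as_zero = FALSE) {
  stopifnot(length(unique(sweep$class)) == 1L)
  avg <- function(x) {
    if (undefined_as_zero) x[is.na(x)] <- 0
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  }
  data.frame(class = sweep$class[[1]],
             average_precision = avg(sweep$precision),
             average_recall = avg(sweep$recall),
             average_f1 = avg(sweep$f1),
             n_train_images = as.integer(n_train),
             n_test_images = as.integer(n_test),
             # unknown training size (NA) does not exclude a class
             included_in_macro = (is.na(n_train) ||
                                    n_train >= min_class_images) &&
               n_test >= min_class_images,
             stringsAsFactors = FALSE)
}

#' Per-class summaries for every class
#'
#' @inheritParams all_class_sweeps
#' @param train_counts named integer vector (or data.frame with columns
#'   `class`, `n_train`) of training images per class; classes absent
#'   from it get 0. `NULL` means training sizes are unknown: no class is
#'   then excluded on training size.
#' @param min_class_images exclusion cutoff for macro-averaging.
#' @param undefined_as_zero see [average_metrics()].
#' @return row-bound [average_metrics()] summaries. Test-set size per
#'   class is the number of images confirmed to contain it.
#' @export
class_summaries <- function(predictions, truth, vocabulary, train_counts,
                            thresholds = threshold_grid(0.25, 1.0, 0.05),
                            min_class_images = 10L,
                            undefined_as_zero = FALSE) {
  if (is.data.frame(train_counts)) {
    train_counts <- stats::setNames(train_counts$n_train, train_counts$class)
  }
  classes <- vocabulary_labels(vocabulary, "animal")
  do.call(rbind, lapply(classes, function(cl) {
    sw <- threshold_sweep(predictions, truth, cl, thresholds)
    n_test <- length(unique(truth$image_id[truth$class == cl]))
    n_train <- if (is.null(train_counts)) NA_integer_ else
      if (cl %in% names(train_counts)) train_counts[[cl]] else 0L
    average_metrics(sw, n_train, n_test, min_class_images,
                    undefined_as_zero)
  }))
}

#' Macro-averaged metrics over included classes
#'
#' The unweighted mean of the threshold-averaged precision, recall and F1
#' over classes not excluded by the small-class rule.
#'
#' @param summaries [class_summaries()] result.
#' @return one-row data.frame: `macro_precision`, `macro_recall`,
#'   `macro_f1`, `n_classes`.
#' @export
macro_average <- function(summaries) {
  inc <- summaries[summaries$included_in_macro, , drop = FALSE]
  if (nrow(inc) == 0L) stop("no classes eligible for macro-averaging")
  data.frame(macro_precision = mean(inc$average_precision, na.rm = TRUE),
             macro_recall = mean(inc$average_recall, na.rm = TRUE),
             macro_f1 = mean(inc$average_f1, na.rm = TRUE),
             n_classes = nrow(inc))
}

#' Linear models of performance against training-set size
#'
#' Ordinary least-squares fits of each threshold-averaged metric
#' (precision, recall, F1) on the number of training images per class and
#' on its log10, six fits in all, with the 95% confidence half-width of
#' the slope from the t distribution on n - 2 degrees of freedom.
#'
#' @param summaries [class_summaries()] result; classes with NA averages
#'   are dropped per metric.
#' @param predictors which predictor forms to fit.
#' @return data.frame with columns `metric`, `predictor`, `slope`,
#'   `intercept`, `r_squared`, `slope_ci_half_width`, `n`.
#' @export
fit_size_effect <- function(summaries,
                            predictors = c("n_train", "log10_n_train")) {
  predictors <- match.arg(predictors, several.ok = TRUE)
  metric_cols <- c(precision = "average_precision",
                   recall = "average_recall", f1 = "average_f1")
  rows <- list()
  for (pred in predictors) {
    for (m in names(metric_cols)) {
      df <- data.frame(y = summaries[[metric_cols[[m]]]],
                       n_train = summaries$n_train_images)
      if (pred == "log10_n_train") {
        df <- df[df$n_train > 0, , drop = FALSE]
        df$x <- log10(df$n_train)
      } else {
        df$x <- df$n_train
      }
      df <- df[!is.na(df$y), , drop = FALSE]
      if (nrow(df) < 3L) {
        stop("need >= 3 classes with defined ", m, " to fit the ",
             pred, " model")
      }
      if (stats::var(df$x) == 0) {
        stop("zero variance in predictor ", pred)
      }
      fit <- stats::lm(y ~ x, data = df)
      co <- stats::coef(fit)
      # slope SE and R^2 computed directly (summary.lm warns on an
      # exact fit)
      rss <- sum(stats::residuals(fit)^2)
      sxx <- sum((df$x - mean(df$x))^2)
      se <- sqrt(rss / (nrow(df) - 2L) / sxx)
      tss <- sum((df$y - mean(df$y))^2)
      rsq <- if (tss == 0) 0 else 1 - rss / tss
      rows[[length(rows) + 1L]] <- data.frame(
        metric = m, predictor = pred,
        slope = unname(co[["x"]]), intercept = unname(co[["(Intercept)"]]),
        r_squared = rsq,
        slope_ci_half_width = stats::qt(0.975, nrow(df) - 2L) * se,
        n = nrow(df), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
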