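# Ecological concordance metrics: site-level species richness from
# verified vs. predicted detections with a regression of predicted on
# observed at each score threshold, and per-image animal-count bias
# models (additive difference, proportional ratio, and a Poisson GLM of
# true count on log predicted count with class-specific curves).

RICHNESS_EXCLUDE_DEFAULT <- c("human", "vehicle", "unknown")

#' Species richness per station
#'
#' The number of distinct species labels (after removing
#' `excluded_labels`) with at least one qualifying detection at any image
#' of the station. Verified annotations qualify unconditionally; model
#' predictions qualify when their score is at or above `threshold`
#' (required for predictions). Stations with no qualifying detections
#' report 0.
#'
#' @param detections predictions data.frame (with a `score` column) or
#'   truth data.frame (without one).
#' @param manifest manifest data.frame mapping images to stations.
#' @param threshold score threshold; required when `detections` carries
#'   scores, ignored otherwise.
#' @param excluded_labels labels that never count toward richness
#'   (default human, vehicle, unknown).
#' @return named integer vector, one entry per station in the manifest.
#' @export
site_richness <- function(detections, manifest, threshold = NULL,
                          excluded_labels = RICHNESS_EXCLUDE_DEFAULT) {
  check_images_in_manifest(detections, manifest, "detections")
  has_scores <- "score" %in% names(detections)
  if (has_scores && is.null(threshold)) {
    stop("a score threshold is required for predicted richness")
  }
  keep <- !detections$class %in% excluded_labels
  if (has_scores) keep <- keep & detections$score >= threshold
  d <- detections[keep, , drop = FALSE]
  d$station_id <- manifest$station_id[match(d$image_id, manifest$image_id)]
  stations <- sort(unique(manifest$station_id))
  rich <- stats::setNames(integer(length(stations)), stations)
  if (nrow(d)) {
    r <- tapply(d$class, d$station_id, function(x) length(unique(x)))
    rich[names(r)] <- as.integer(r)
  }
  rich
}

#' Concordance of predicted and observed richness
#'
#' Ordinary least-squares regression of model-predicted richness on
#' observed (verified) richness over stations, with per-station bias
#' (predicted minus observed) summarized by its mean and standard
#' deviation.
#'
#' @param observed,predicted named station-to-richness vectors over the
#'   same station set (see [site_richness()]).
#' @param threshold the score threshold the predicted richness was
#'   computed at (recorded in the output).
#' @return one-row data.frame: `threshold`, `slope`, `intercept`,
#'   `r_squared`, `mean_abs_bias`, `sd_abs_bias`, `n_stations`.
#' @export
richness_concordance <- function(observed, predicted, threshold = NA_real_) {
  if (length(observed) != length(predicted) ||
      !setequal(names(observed), names(predicted))) {
    stop("observed and predicted richness must cover the same stations")
  }
  predicted <- predicted[names(observed)]
  if (length(observed) < 3L) stop("need >= 3 stations")
  if (stats::var(observed) == 0) {
    stop("observed richness has zero variance; regression undefined")
  }
  fit <- stats::lm(predicted ~ observed)
  co <- stats::coef(fit)
  # R^2 computed directly (summary.lm warns on an exact fit)
  tss <- sum((predicted - mean(predicted))^2)
  rsq <- if (tss == 0) 0 else 1 - sum(stats::residuals(fit)^2) / tss
  bias <- predicted - observed
  data.frame(threshold = threshold,
             slope = unname(co[["observed"]]),
             intercept = unname(co[["(Intercept)"]]),
             r_squared = rsq,
             mean_abs_bias = mean(bias),
             sd_abs_bias = stats::sd(bias),
             n_stations = length(observed))
}

#' Richness concordance across a threshold grid
#'
#' @param predictions,truth,manifest data.frames.
#' @param thresholds score thresholds (default 0.25–0.95 by 0.10).
#' @param excluded_labels see [site_richness()].
#' @return list with `records` (station-level observed/predicted richness
#'   per threshold) and `fits` (one [richness_concordance()] row per
#'   threshold).
#' @export
richness_sweep <- function(predictions, truth, manifest,
                           thresholds = threshold_grid(0.25, 0.95, 0.10),
                           excluded_labels = RICHNESS_EXCLUDE_DEFAULT) {
  check_threshold_grid(thresholds)
  obs <- site_richness(truth, manifest, excluded_labels = excluded_labels)
  records <- list()
  fits <- list()
  for (t in thresholds) {
    pred <- site_richness(predictions, manifest, threshold = t,
                          excluded_labels = excluded_labels)
    records[[length(records) + 1L]] <- data.frame(
      station_id = names(obs), threshold = t,
      observed_richness = as.integer(obs),
      predicted_richness = as.integer(pred[names(obs)]),
      stringsAsFactors = FALSE)
    fits[[length(fits) + 1L]] <- richness_concordance(obs, pred, t)
  }
  list(records = do.call(rbind, records), fits = do.call(rbind, fits))
}

#' Extract count records for the count-bias models
#'
#' One record per true-positive single-species image: the image's truth
#' must hold exactly one species and the surviving (score >= threshold)
#' predictions must include that species. `count_pred` is the number of
#' surviving predicted boxes of the true species on the image (boxes of
#' other species are ignored); `count_true` comes from the annotation.
#'
#' @param predictions,truth data.frames.
#' @param threshold score threshold.
#' @return data.frame `image_id`, `class`, `count_true`, `count_pred`.
#' @export
extract_count_records <- function(predictions, truth, threshold) {
  if (nrow(truth) == 0L) {
    return(data.frame(image_id = character(), class = character(),
                      count_true = integer(), count_pred = integer(),
                      stringsAsFactors = FALSE))
  }
  n_sp <- tapply(truth$class, truth$image_id, function(x) length(unique(x)))
  single <- names(n_sp)[n_sp == 1]
  tr <- truth[truth$image_id %in% single, , drop = FALSE]
  pr <- predictions[predictions$score >= threshold, , drop = FALSE]
  key_p <- paste(pr$image_id, pr$class, sep = "\r")
  key_t <- paste(tr$image_id, tr$class, sep = "\r")
  n_boxes <- table(key_p)
  count_pred <- as.integer(n_boxes[key_t])
  count_pred[is.na(count_pred)] <- 0L
  keep <- count_pred >= 1L   # TP images only
  data.frame(image_id = tr$image_id[keep], class = tr$class[keep],
             count_true = as.integer(tr$count[keep]),
             count_pred = count_pred[keep],
             stringsAsFactors = FALSE, row.names = NULL)
}

# Cell-means fit of `response` on species class: coefficients are the
# per-class means, CIs from the pooled residual variance (t distribution).
# The fit is done through lm on the no-intercept factor design (a plain
# mean model when only one class is present, where the factor design is
# rank-degenerate for model.matrix).
cell_means_fit <- function(records, response, model_form) {
  if (nrow(records) == 0L) stop("no count records to fit")
  df <- data.frame(y = response, class = factor(records$class))
  k <- nlevels(df$class)
  fit <- if (k > 1L) stats::lm(y ~ 0 + class, data = df) else
    stats::lm(y ~ 1, data = df)
  est <- unname(stats::coef(fit))
  n_i <- as.integer(table(df$class))
  resid_df <- stats::df.residual(fit)
  if (resid_df > 0) {
    # pooled residual variance, avoiding summary.lm's perfect-fit warning
    sigma2 <- sum(stats::residuals(fit)^2) / resid_df
    half <- stats::qt(0.975, resid_df) * sqrt(sigma2 / n_i)
  } else {
    half <- rep(NA_real_, k)
  }
  data.frame(model_form = model_form,
             class = levels(df$class),
             estimate = est,
             ci_half_width = half,
             n_records = n_i,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Additive count bias per species class
#'
#' Cell-means linear model of `count_true - count_pred` on species class:
#' each coefficient is the class mean difference, with a 95% CI from the
#' pooled residual variance. A coefficient above zero means the detector
#' undercounts that class.
#'
#' @param records [extract_count_records()] output.
#' @return data.frame `model_form`, `class`, `estimate`,
#'   `ci_half_width`, `n_records`.
#' @export
fit_count_difference <- function(records) {
  cell_means_fit(records, records$count_true - records$count_pred,
                 "difference")
}

#' Proportional count bias per species class
#'
#' As [fit_count_difference()] with response `count_pred / count_true`: a
#' coefficient of 0.78 means a 22% mean undercount for that class.
#'
#' @inheritParams fit_count_difference
#' @return data.frame as in [fit_count_difference()].
#' @export
fit_count_ratio <- function(records) {
  cell_means_fit(records, records$count_pred / records$count_true, "ratio")
}

#' Poisson GLM of true count on log predicted count, by class
#'
#' Fits `count_true ~ Poisson(exp(a_i + b_i * ln(count_pred)))` with a
#' separate intercept and slope per species class (the nested
#' parameterization of the class-by-log-count interaction), via
#' iteratively reweighted least squares. The predicted true count for
#' class i at predicted count x is `exp(a_i + b_i * ln x)`.
#'
#' @inheritParams fit_count_difference
#' @param epsilon IRLS relative convergence tolerance.
#' @param maxit maximum IRLS iterations.
#' @return list with `coefficients` (data.frame `class`, `intercept`,
#'   `slope`, `intercept_ci_half_width`, `slope_ci_half_width`,
#'   `n_records`), `deviance`, and `fit` (the `glm` object).
#' @export
fit_count_glm <- function(records, epsilon = 1e-8, maxit = 100L) {
  if (nrow(records) == 0L) stop("no count records to fit")
  df <- data.frame(y = records$count_true,
                   log_pred = log(records$count_pred),
                   class = factor(records$class))
  spread <- tapply(df$log_pred, df$class, function(x) length(unique(x)))
  flat <- names(spread)[spread < 2]
  if (length(flat)) {
    stop("slope inestimable (all predicted counts equal) for class(es): ",
         paste(flat, collapse = ", "))
  }
  classes <- levels(df$class)
  form <- if (length(classes) > 1L) y ~ 0 + class + class:log_pred else
    y ~ log_pred
  fit <- stats::glm(form, data = df,
                    family = stats::poisson(link = "log"),
                    control = stats::glm.control(epsilon = epsilon,
                                                 maxit = maxit))
  if (!fit$converged) {
    stop("Poisson GLM did not converge within ", maxit, " iterations")
  }
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  if (length(classes) > 1L) {
    int_names <- paste0("class", classes)
    slope_names <- paste0("class", classes, ":log_pred")
  } else {
    int_names <- "(Intercept)"
    slope_names <- "log_pred"
  }
  z <- stats::qnorm(0.975)
  coefficients <- data.frame(
    class = classes,
    intercept = unname(co[int_names]),
    slope = unname(co[slope_names]),
    intercept_ci_half_width = z * unname(se[int_names]),
    slope_ci_half_width = z * unname(se[slope_names]),
    n_records = as.integer(table(df$class)),
    stringsAsFactors = FALSE, row.names = NULL)
  list(coefficients = coefficients, deviance = stats::deviance(fit),
       fit = fit)
}

#' Exact truncated-binomial mean for count-recovery oracles
#'
#' For a group of `size` animals each detected independently with
#' probability `p`, conditioned on the image being a true positive (at
#' least one detection), the expected number of predicted boxes is
#' `E[X | X >= 1]`, `X ~ Binomial(size, p)`, computed by direct summation
#' over the binomial support. Dividing by `size` gives the expected ratio
#' coefficient of [fit_count_ratio()] under perfect classification.
#'
#' @param size group size (positive integer).
#' @param p per-animal detection probability.
#' @return the conditional expectation.
#' @export
truncated_binomial_mean <- function(size, p) {
  stopifnot(size >= 1, p > 0, p <= 1)
  k <- seq_len(size)
  probs <- stats::dbinom(k, size, p)
  sum(k * probs) / sum(probs)
}
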