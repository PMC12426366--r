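# Synthetic camera-trap study generator: a multi-station truth layer
# (long-tailed species abundance, per-species group sizes, a fraction of
# empty images) and a parametric detector-error model (per-animal
# detection probability, inter-class confusion, Poisson false boxes on
# empty images, Beta-distributed scores separating true from false
# detections). Closed-form expected metrics make recovery tests possible.

#' Score distribution for simulated detections
#'
#' Detector confidence scores for true and false detections are modelled
#' either as a Beta distribution or as a point mass (useful for exact
#' perfect-detector identities).
#'
#' @param shape1,shape2 positive Beta shape parameters.
#' @return an object of class `score_dist`.
#' @examples
#' score_beta(5, 1)    # right-skewed, typical of true positives
#' score_fixed(1.0)    # degenerate, every score exactly 1
#' @export
score_beta <- function(shape1, shape2) {
  stopifnot(is.finite(shape1), is.finite(shape2), shape1 > 0, shape2 > 0)
  structure(list(type = "beta", shape1 = shape1, shape2 = shape2),
            class = "score_dist")
}

#' @rdname score_beta
#' @param value the constant score in \[0,1\].
#' @export
score_fixed <- function(value) {
  stopifnot(is.finite(value), value >= 0, value <= 1)
  structure(list(type = "fixed", value = value), class = "score_dist")
}

draw_scores <- function(dist, n) {
  stopifnot(inherits(dist, "score_dist"))
  if (n == 0L) return(numeric(0))
  switch(dist$type,
         beta = stats::rbeta(n, dist$shape1, dist$shape2),
         fixed = rep(dist$value, n))
}

#' Upper tail probability of a score distribution
#'
#' `P(score >= t)`; thresholding is inclusive throughout the package.
#'
#' @param dist a [score_beta()] or [score_fixed()] object.
#' @param t threshold in \[0,1\].
#' @return probability.
#' @export
score_survival <- function(dist, t) {
  stopifnot(inherits(dist, "score_dist"))
  switch(dist$type,
         beta = stats::pbeta(t, dist$shape1, dist$shape2,
                             lower.tail = FALSE),
         fixed = as.numeric(dist$value >= t))
}

#' Specify a species for the synthetic study
#'
#' @param label species class label.
#' @param abundance_weight positive relative abundance weight; occupied
#'   images are assigned a species with probability proportional to it.
#' @param group_size_mean mean group size (number of individuals per
#'   occupied image) of a zero-truncated geometric distribution on
#'   \{1, 2, ...\}; must be >= 1. With `group_size_dist = "fixed"` every
#'   group has exactly `group_size_mean` individuals (then it must be a
#'   positive integer).
#' @param group_size_dist `"ztgeom"` (default) or `"fixed"`.
#' @return an object of class `species_spec`.
#' @export
species_spec <- function(label, abundance_weight = 1,
                         group_size_mean = 1,
                         group_size_dist = c("ztgeom", "fixed")) {
  group_size_dist <- match.arg(group_size_dist)
  stopifnot(is.character(label), nzchar(label),
            is.finite(abundance_weight), abundance_weight > 0,
            is.finite(group_size_mean), group_size_mean >= 1)
  if (group_size_dist == "fixed" &&
      group_size_mean != round(group_size_mean)) {
    stop("fixed group size must be a positive integer for class ", label)
  }
  structure(list(label = label, abundance_weight = abundance_weight,
                 group_size_mean = group_size_mean,
                 group_size_dist = group_size_dist),
            class = "species_spec")
}

draw_group_sizes <- function(spec, n) {
  if (n == 0L) return(integer(0))
  if (spec$group_size_dist == "fixed") {
    rep(as.integer(spec$group_size_mean), n)
  } else {
    # zero-truncated geometric on {1, 2, ...} with mean m: X = G + 1,
    # G ~ Geometric(p = 1/m), so E[X] = (1-p)/p + 1 = 1/p = m
    stats::rgeom(n, prob = 1 / spec$group_size_mean) + 1L
  }
}

#' Parametric detector-error model
#'
#' Encodes the three failure modes observed in camera-trap detectors:
#' missed animals (per-animal detection probability below 1),
#' misclassification (a row-stochastic confusion matrix between true
#' species and predicted labels), and false triggers (a Poisson number of
#' false boxes on empty images). Scores for true and false detections are
#' drawn from separate distributions so that score-threshold filtering has
#' the qualitative behaviour seen in practice (true detections score
#' higher than false ones).
#'
#' @param p_det named numeric vector: per-species probability that an
#'   individual animal is detected at all.
#' @param confusion row-stochastic matrix; `confusion[s, l]` is the
#'   probability a detected individual of species `s` is labelled `l`.
#'   Row names are true species, column names predicted labels.
#' @param fp_rate_empty mean number of false boxes per empty image
#'   (Poisson rate, >= 0).
#' @param fp_class_weights named numeric vector of label weights for false
#'   boxes; defaults to uniform over the confusion matrix's columns.
#' @param tp_score,fp_score [score_beta()]/[score_fixed()] distributions
#'   for true- and false-detection scores.
#' @return an object of class `detector_error_model`.
#' @export
detector_error_model <- function(p_det, confusion,
                                 fp_rate_empty = 0,
                                 fp_class_weights = NULL,
                                 tp_score = score_beta(5, 1.5),
                                 fp_score = score_beta(1.2, 3)) {
  stopifnot(is.numeric(p_det), !is.null(names(p_det)),
            all(p_det >= 0 & p_det <= 1))
  stopifnot(is.matrix(confusion), !is.null(rownames(confusion)),
            !is.null(colnames(confusion)))
  if (any(confusion < 0)) stop("confusion entries must be nonnegative")
  rs <- rowSums(confusion)
  if (any(abs(rs - 1) > 1e-9)) {
    stop("confusion rows must sum to 1 (off by up to ",
         format(max(abs(rs - 1))), ")")
  }
  missing_rows <- setdiff(names(p_det), rownames(confusion))
  if (length(missing_rows)) {
    stop("species missing from confusion rows: ",
         paste(missing_rows, collapse = ", "))
  }
  stopifnot(is.finite(fp_rate_empty), fp_rate_empty >= 0)
  if (is.null(fp_class_weights)) {
    fp_class_weights <- stats::setNames(
      rep(1, ncol(confusion)), colnames(confusion))
  }
  stopifnot(is.numeric(fp_class_weights), !is.null(names(fp_class_weights)),
            all(fp_class_weights >= 0), sum(fp_class_weights) > 0)
  stopifnot(inherits(tp_score, "score_dist"), inherits(fp_score, "score_dist"))
  structure(list(p_det = p_det, confusion = confusion,
                 fp_rate_empty = fp_rate_empty,
                 fp_class_weights = fp_class_weights,
                 tp_score = tp_score, fp_score = fp_score),
            class = "detector_error_model")
}

#' Identity (perfect) detector-error model
#'
#' Every animal detected, never misclassified, no false boxes, every score
#' exactly 1. Used for exact end-to-end identities.
#'
#' @param species character vector of species labels.
#' @return a [detector_error_model()].
#' @export
perfect_detector_model <- function(species) {
  conf <- diag(length(species))
  dimnames(conf) <- list(species, species)
  detector_error_model(
    p_det = stats::setNames(rep(1, length(species)), species),
    confusion = conf,
    fp_rate_empty = 0,
    tp_score = score_fixed(1),
    fp_score = score_fixed(1))
}

#' Full parameterization of a synthetic camera-trap study
#'
#' @param n_stations,deployments_per_station,images_per_deployment
#'   positive integers defining the manifest layout.
#' @param empty_fraction fraction of images with no animals, in \[0,1\].
#' @param species list of [species_spec()] objects.
#' @param detector a [detector_error_model()].
#' @param seed integer seed recorded in the config and used by
#'   [simulate_study()].
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_stations, deployments_per_station,
                         images_per_deployment, empty_fraction,
                         species, detector, seed = 1L) {
  stopifnot(n_stations >= 1, deployments_per_station >= 1,
            images_per_deployment >= 1,
            empty_fraction >= 0, empty_fraction <= 1)
  if (!length(species) || !all(vapply(species, inherits, TRUE, "species_spec")))
    stop("`species` must be a nonempty list of species_spec objects")
  labels <- vapply(species, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("duplicate species labels")
  stopifnot(inherits(detector, "detector_error_model"))
  missing_sp <- setdiff(labels, names(detector$p_det))
  if (length(missing_sp)) {
    stop("species missing from detector p_det: ",
         paste(missing_sp, collapse = ", "))
  }
  structure(list(n_stations = as.integer(n_stations),
                 deployments_per_station = as.integer(deployments_per_station),
                 images_per_deployment = as.integer(images_per_deployment),
                 empty_fraction = empty_fraction,
                 species = species, detector = detector,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Default synthetic study configuration
#'
#' A desk-scale study emulating the structure of a multi-year protected
#' area survey: 15 stations with 2 deployments of 60 images each (1800
#' images), 55% of images empty (false triggers dominate raw camera-trap
#' output), six species with long-tailed abundance, group-living species
#' with zero-truncated-geometric group sizes, per-species detection
#' probabilities between 0.6 and 0.95, modest inter-class confusion, 0.4
#' false boxes per empty image, and Beta(5, 1.5) vs Beta(1.2, 3) score
#' distributions separating true from false detections.
#'
#' @param seed integer seed.
#' @return a [synth_config()].
#' @export
default_synth_config <- function(seed = 1L) {
  sp <- list(
    species_spec("baboon",      abundance_weight = 40, group_size_mean = 2.5),
    species_spec("bushbuck",    abundance_weight = 20, group_size_mean = 1.2),
    species_spec("elephant",    abundance_weight = 10, group_size_mean = 2.0),
    species_spec("guineafowl",  abundance_weight = 8,  group_size_mean = 2.3),
    species_spec("zebra",       abundance_weight = 4,  group_size_mean = 1.8),
    species_spec("leopard",     abundance_weight = 1,  group_size_mean = 1,
                 group_size_dist = "fixed"))
  labels <- vapply(sp, `[[`, "", "label")
  k <- length(labels)
  diag_p <- c(0.95, 0.85, 0.97, 0.88, 0.92, 0.80)
  conf <- matrix(0, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k)) {
    conf[i, ] <- (1 - diag_p[i]) / (k - 1)
    conf[i, i] <- diag_p[i]
  }
  det <- detector_error_model(
    p_det = stats::setNames(c(0.90, 0.70, 0.95, 0.60, 0.85, 0.65), labels),
    confusion = conf,
    fp_rate_empty = 0.4,
    tp_score = score_beta(5, 1.5),
    fp_score = score_beta(1.2, 3))
  synth_config(n_stations = 15, deployments_per_station = 2,
               images_per_deployment = 60, empty_fraction = 0.55,
               species = sp, detector = det, seed = seed)
}

#' Generate the truth layer of a synthetic study
#'
#' Lays out `n_stations x deployments_per_station x images_per_deployment`
#' images; marks each empty with probability `empty_fraction`; assigns
#' each occupied image one species by abundance weight and a group size
#' from that species' distribution. Deterministic given the seed.
#'
#' @param config a [synth_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return list with `manifest` and `truth` data.frames.
#' @export
generate_truth <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  n_img <- config$n_stations * config$deployments_per_station *
    config$images_per_deployment
  station <- rep(sprintf("ST%03d", seq_len(config$n_stations)),
                 each = config$deployments_per_station *
                   config$images_per_deployment)
  dep_idx <- rep(rep(seq_len(config$deployments_per_station),
                     each = config$images_per_deployment),
                 times = config$n_stations)
  deployment <- paste0(station, "-D", dep_idx)
  image_id <- paste0(deployment, "-I",
                     formatC(sequence(rep(config$images_per_deployment,
                                          config$n_stations *
                                            config$deployments_per_station)),
                             width = 5, flag = "0"))
  manifest <- data.frame(image_id = image_id, station_id = station,
                         deployment_id = deployment,
                         timestamp = NA_character_, reviewed = TRUE,
                         stringsAsFactors = FALSE)
  labels <- vapply(config$species, `[[`, "", "label")
  weights <- vapply(config$species, `[[`, 0, "abundance_weight")
  truth <- with_seed(seed, {
    occupied <- stats::runif(n_img) >= config$empty_fraction
    n_occ <- sum(occupied)
    if (n_occ == 0L) {
      empty_truth()
    } else {
      sp_idx <- sample.int(length(labels), n_occ, replace = TRUE,
                           prob = weights / sum(weights))
      counts <- integer(n_occ)
      for (i in seq_along(config$species)) {
        sel <- sp_idx == i
        counts[sel] <- draw_group_sizes(config$species[[i]], sum(sel))
      }
      data.frame(image_id = image_id[occupied], class = labels[sp_idx],
                 count = counts, stringsAsFactors = FALSE)
    }
  })
  list(manifest = manifest, truth = truth)
}

#' Simulate detector output on a synthetic truth layer
#'
#' Each individual animal (an annotation contributes `count` independent
#' individuals) is detected with its species' `p_det`; a detected
#' individual's label is drawn from the species' confusion row and its
#' score from the true-detection score distribution. Each empty image
#' receives a Poisson(`fp_rate_empty`) number of false boxes with labels
#' from `fp_class_weights` and scores from the false-detection
#' distribution. Deterministic given the seed.
#'
#' @param manifest,truth as returned by [generate_truth()].
#' @param model a [detector_error_model()].
#' @param seed integer seed.
#' @param fp_on_occupied also draw false boxes on occupied images
#'   (default FALSE: false triggers only on empty images).
#' @return predictions data.frame.
#' @export
simulate_detector <- function(manifest, truth, model, seed,
                              fp_on_occupied = FALSE) {
  stopifnot(inherits(model, "detector_error_model"))
  check_images_in_manifest(truth, manifest, "truth")
  missing_sp <- setdiff(unique(truth$class), names(model$p_det))
  if (length(missing_sp)) {
    stop("species in truth missing from detector model: ",
         paste(missing_sp, collapse = ", "))
  }
  with_seed(seed, {
    parts <- list(empty_predictions())
    if (nrow(truth)) {
      n_det <- stats::rbinom(nrow(truth), truth$count,
                             model$p_det[truth$class])
      exp_img <- rep(truth$image_id, n_det)
      exp_sp <- rep(truth$class, n_det)
      lab <- character(length(exp_sp))
      pred_labels <- colnames(model$confusion)
      for (sp in sort(unique(exp_sp))) {
        sel <- exp_sp == sp
        lab[sel] <- pred_labels[sample.int(length(pred_labels), sum(sel),
                                           replace = TRUE,
                                           prob = model$confusion[sp, ])]
      }
      if (length(exp_img)) {
        parts[[length(parts) + 1L]] <- as_predictions(
          exp_img, lab, draw_scores(model$tp_score, length(exp_img)))
      }
    }
    if (model$fp_rate_empty > 0) {
      fp_imgs <- if (fp_on_occupied) manifest$image_id else
        setdiff(manifest$image_id, unique(truth$image_id))
      if (length(fp_imgs)) {
        n_fp <- stats::rpois(length(fp_imgs), model$fp_rate_empty)
        exp_img <- rep(fp_imgs, n_fp)
        if (length(exp_img)) {
          w <- model$fp_class_weights
          lab <- names(w)[sample.int(length(w), length(exp_img),
                                     replace = TRUE, prob = w / sum(w))]
          parts[[length(parts) + 1L]] <- as_predictions(
            exp_img, lab, draw_scores(model$fp_score, length(exp_img)))
        }
      }
    }
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    out
  })
}

#' Generate a complete synthetic study
#'
#' Runs [generate_truth()] with the config seed and [simulate_detector()]
#' with the following seed value, so (config, seed) fully determines the
#' study.
#'
#' @param config a [synth_config()].
#' @return list of class `synth_study` with `manifest`, `truth`,
#'   `predictions`, and `config`.
#' @export
simulate_study <- function(config) {
  gt <- generate_truth(config, seed = config$seed)
  preds <- simulate_detector(gt$manifest, gt$truth, config$detector,
                             seed = config$seed + 1L)
  structure(list(manifest = gt$manifest, truth = gt$truth,
                 predictions = preds, config = config),
            class = "synth_study")
}

#' Vocabulary implied by a synthetic configuration
#'
#' All species labels plus any extra labels appearing as confusion
#' columns or false-positive classes, every one tagged with the animal
#' role.
#'
#' @param config a [synth_config()].
#' @return a [class_vocabulary()].
#' @export
synth_vocabulary <- function(config) {
  labels <- unique(c(vapply(config$species, `[[`, "", "label"),
                     colnames(config$detector$confusion),
                     names(config$detector$fp_class_weights)))
  class_vocabulary(labels)
}

#' Closed-form expected image-level recall under the error model
#'
#' For an image holding `group_size` individuals of one species, the
#' probability that at least one is detected, labelled correctly, and
#' scores at or above the threshold:
#' `1 - (1 - p_det * C[s,s] * S_tp(t))^group_size`,
#' where `S_tp` is the upper tail of the true-detection score
#' distribution. This is the analytic oracle used by the parameter
#' recovery tests.
#'
#' @param model a [detector_error_model()].
#' @param species species label.
#' @param group_size number of individuals in the image.
#' @param threshold score threshold in \[0,1\].
#' @return probability.
#' @export
expected_image_recall <- function(model, species, group_size, threshold) {
  stopifnot(inherits(model, "detector_error_model"),
            threshold >= 0, threshold <= 1, group_size >= 1)
  if (!species %in% names(model$p_det)) {
    stop("unknown species: ", species)
  }
  c_ss <- if (species %in% colnames(model$confusion))
    model$confusion[species, species] else 0
  p1 <- model$p_det[[species]] * c_ss * score_survival(model$tp_score,
                                                       threshold)
  1 - (1 - p1)^group_size
}
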