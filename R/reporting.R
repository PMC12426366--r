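# End-to-end orchestration: run every evaluation stage on one study and
# emit a machine-readable summary plus per-stage CSV tables, and write or
# reload a synthetic study as the canonical CSV bundle with a provenance
# record.

#' Run the full evaluation pipeline
#'
#' Executes the four evaluation stages on one study — empty-image
#' filtering (binary confusion sweep), species classification (per-class
#' threshold sweep, summaries, macro-averages, and, when training counts
#' are supplied, size-effect regressions), species richness concordance,
#' and animal-count bias models — and returns them as one bundle.
#' Identical inputs give identical outputs. When `out_dir` is given, the
#' stage tables are written as CSVs plus a JSON summary; on any stage
#' error partial outputs are removed.
#'
#' @param predictions,truth,manifest data.frames (see package overview).
#' @param vocabulary a [class_vocabulary()].
#' @param train_counts optional named vector or data.frame
#'   (`class`, `n_train`) of training images per class; without it the
#'   size-effect stage is skipped with a warning.
#' @param binary_thresholds,class_thresholds,richness_thresholds
#'   score-threshold grids per stage.
#' @param count_threshold single threshold for the count models.
#' @param min_class_images macro-exclusion cutoff (default 10).
#' @param excluded_labels labels excluded from richness.
#' @param out_dir optional output directory.
#' @param seed seed recorded in the provenance header (the evaluation
#'   itself is deterministic).
#' @return list of class `camtrap_report` with elements `binary`,
#'   `sweeps`, `summaries`, `macro`, `size_effect` (NULL when skipped),
#'   `richness`, `count_records`, `count_difference`, `count_ratio`,
#'   `count_glm`, and `summary` (flat named list mirrored to JSON).
#' @export
run_full_evaluation <- function(predictions, truth, manifest, vocabulary,
                                train_counts = NULL,
                                binary_thresholds =
                                  threshold_grid(0.25, 0.95, 0.10),
                                class_thresholds =
                                  threshold_grid(0.25, 1.00, 0.05),
                                richness_thresholds =
                                  threshold_grid(0.25, 0.95, 0.10),
                                count_threshold = 0.25,
                                min_class_images = 10L,
                                excluded_labels = RICHNESS_EXCLUDE_DEFAULT,
                                out_dir = NULL, seed = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  binary <- stage("binary-filter", {
    rec <- collapse_to_binary(predictions, truth, manifest, vocabulary)
    binary_confusion_sweep(rec, binary_thresholds)
  })
  message(sprintf("binary filter: %d reviewed images, %d thresholds",
                  binary$TP[1] + binary$FN[1] + binary$FP[1] + binary$TN[1],
                  nrow(binary)))
  sweeps <- stage("classification",
                  all_class_sweeps(predictions, truth, vocabulary,
                                   class_thresholds))
  summaries <- stage("classification",
                     class_summaries(predictions, truth, vocabulary,
                                     train_counts, class_thresholds,
                                     min_class_images))
  macro <- stage("classification", macro_average(summaries))
  size_effect <- NULL
  if (is.null(train_counts)) {
    warning("no training counts supplied; size-effect regressions skipped")
  } else {
    size_effect <- stage("size-effect", fit_size_effect(summaries))
  }
  richness <- stage("richness",
                    richness_sweep(predictions, truth, manifest,
                                   richness_thresholds, excluded_labels))
  count_records <- stage("counts",
                         extract_count_records(predictions, truth,
                                               count_threshold))
  message(sprintf("counts: %d TP single-species records at t=%.2f",
                  nrow(count_records), count_threshold))
  count_difference <- stage("counts", fit_count_difference(count_records))
  count_ratio <- stage("counts", fit_count_ratio(count_records))
  count_glm <- stage("counts", tryCatch(fit_count_glm(count_records),
                                        error = function(e) NULL))

  best_rich <- richness$fits[which.max(richness$fits$r_squared), ]
  summary <- list(
    n_images = nrow(manifest),
    n_predictions = nrow(predictions),
    macro_precision = macro$macro_precision,
    macro_recall = macro$macro_recall,
    macro_f1 = macro$macro_f1,
    n_macro_classes = macro$n_classes,
    sensitivity_at_lowest_threshold = binary$sensitivity[[1]],
    specificity_at_lowest_threshold = binary$specificity[[1]],
    best_richness_threshold = best_rich$threshold,
    best_richness_r_squared = best_rich$r_squared,
    best_richness_slope = best_rich$slope,
    n_count_records = nrow(count_records),
    seed = if (is.null(seed)) NA else seed)

  report <- structure(list(binary = binary, sweeps = sweeps,
                           summaries = summaries, macro = macro,
                           size_effect = size_effect, richness = richness,
                           count_records = count_records,
                           count_difference = count_difference,
                           count_ratio = count_ratio,
                           count_glm = count_glm, summary = summary),
                      class = "camtrap_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  on_fail <- function(e) {
    unlink(written)
    stop("failed writing report to ", out_dir, ": ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    put <- function(df, name) {
      p <- file.path(out_dir, name)
      write_results_table(df, p)
      written <<- c(written, p)
    }
    put(report$binary, "binary_confusion.csv")
    put(report$sweeps, "class_sweeps.csv")
    put(report$summaries, "class_summaries.csv")
    put(report$macro, "macro_metrics.csv")
    if (!is.null(report$size_effect)) put(report$size_effect,
                                          "size_effect.csv")
    put(report$richness$records, "richness_records.csv")
    put(report$richness$fits, "richness_fits.csv")
    put(report$count_records, "count_records.csv")
    put(rbind(report$count_difference, report$count_ratio),
        "count_coefficients.csv")
    if (!is.null(report$count_glm)) put(report$count_glm$coefficients,
                                        "count_glm_coefficients.csv")
    sp <- file.path(out_dir, "summary.json")
    jsonlite::write_json(report$summary, sp, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    written <- c(written, sp)
  }, error = on_fail)
  invisible(out_dir)
}

# Compact provenance record: config echo, seed, and a hash of the
# serialized configuration so reruns can assert identity.
config_provenance <- function(config) {
  echo <- list(
    n_stations = config$n_stations,
    deployments_per_station = config$deployments_per_station,
    images_per_deployment = config$images_per_deployment,
    empty_fraction = config$empty_fraction,
    species = lapply(config$species, function(s) {
      list(label = s$label, abundance_weight = s$abundance_weight,
           group_size_mean = s$group_size_mean,
           group_size_dist = s$group_size_dist)
    }),
    detector = list(
      p_det = as.list(config$detector$p_det),
      confusion = apply(config$detector$confusion, 1, as.list,
                        simplify = FALSE),
      fp_rate_empty = config$detector$fp_rate_empty,
      fp_class_weights = as.list(config$detector$fp_class_weights),
      tp_score = unclass(config$detector$tp_score),
      fp_score = unclass(config$detector$fp_score)),
    seed = config$seed)
  json <- jsonlite::toJSON(echo, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(fileext = ".json")
  writeLines(json, tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  list(config = echo, config_hash = hash, seed = config$seed)
}

#' Write a synthetic study as the canonical CSV bundle
#'
#' Writes `detections.csv`, `verified.csv` and `manifest.csv` plus a
#' `provenance.json` echoing the full configuration, its hash, and the
#' seed.
#'
#' @param study a [simulate_study()] result.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_synthetic_study <- function(study, out_dir) {
  stopifnot(inherits(study, "synth_study"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_results_table(study$predictions, file.path(out_dir,
                                                   "detections.csv"))
  write_results_table(study$truth, file.path(out_dir, "verified.csv"))
  write_results_table(study$manifest, file.path(out_dir, "manifest.csv"))
  jsonlite::write_json(config_provenance(study$config),
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Read a study bundle written by [write_synthetic_study()]
#'
#' @param dir bundle directory.
#' @param vocabulary a [class_vocabulary()] used to validate labels.
#' @return list with `predictions`, `truth`, `manifest`.
#' @export
read_study_bundle <- function(dir, vocabulary) {
  list(predictions = read_detection_table(file.path(dir, "detections.csv"),
                                          vocabulary),
       truth = read_verified_table(file.path(dir, "verified.csv"),
                                   vocabulary),
       manifest = read_manifest(file.path(dir, "manifest.csv")))
}
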