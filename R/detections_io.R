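# Data model and readers/writers for detector predictions, verified
# annotations, image manifests and result tables.
#
# Internal containers are plain data.frames:
#   predictions: image_id, class, score, x_center, y_center, width, height
#                (the four box columns may be NA; coordinates are fractions of
#                image size in the YOLO normalized-center convention)
#   truth:       image_id, class, count
#   manifest:    image_id, station_id, deployment_id, timestamp, reviewed

#' Construct a class vocabulary
#'
#' A vocabulary is the ordered set of class labels a detector can emit,
#' each tagged with a role. Roles drive the binary (animal vs. empty)
#' collapse and the exclusion of non-species labels from richness.
#'
#' @param labels character vector of unique, nonempty class labels.
#' @param roles character vector of the same length; each element one of
#'   `"animal"`, `"human"`, `"vehicle"`, `"empty-marker"`, `"other"`.
#'   Defaults to `"animal"` for every label.
#' @return A data.frame of class `class_vocabulary` with columns `label`
#'   and `role`.
#' @examples
#' class_vocabulary(c("baboon", "elephant", "human"),
#'                  c("animal", "animal", "human"))
#' @export
class_vocabulary <- function(labels, roles = rep("animal", length(labels))) {
  labels <- as.character(labels)
  roles <- as.character(roles)
  if (length(labels) == 0L) stop("vocabulary must contain at least one label")
  if (anyDuplicated(labels)) {
    stop("duplicate labels in vocabulary: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  if (any(!nzchar(labels))) stop("vocabulary labels must be nonempty")
  if (length(roles) != length(labels)) {
    stop("`roles` must have one entry per label")
  }
  allowed <- c("animal", "human", "vehicle", "empty-marker", "other")
  bad <- setdiff(unique(roles), allowed)
  if (length(bad)) {
    stop("unknown role(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(allowed, collapse = ", "))
  }
  out <- data.frame(label = labels, role = roles, stringsAsFactors = FALSE)
  class(out) <- c("class_vocabulary", "data.frame")
  out
}

#' Labels of a vocabulary having one of the given roles
#' @param vocabulary a [class_vocabulary()].
#' @param roles character vector of roles to keep.
#' @return character vector of labels.
#' @export
vocabulary_labels <- function(vocabulary, roles = NULL) {
  stopifnot(inherits(vocabulary, "class_vocabulary"))
  if (is.null(roles)) return(vocabulary$label)
  vocabulary$label[vocabulary$role %in% roles]
}

# Validate a normalized-center bounding box; NA boxes pass (box optional).
validate_boxes <- function(df, tol = 1e-9) {
  cols <- c("x_center", "y_center", "width", "height")
  has_box <- stats::complete.cases(df[, cols, drop = FALSE])
  if (!any(has_box)) return(invisible(df))
  b <- df[has_box, cols, drop = FALSE]
  ok <- is.finite(b$x_center) & is.finite(b$y_center) &
    is.finite(b$width) & is.finite(b$height) &
    b$width > 0 & b$height > 0 &
    b$x_center - b$width / 2 >= -tol & b$x_center + b$width / 2 <= 1 + tol &
    b$y_center - b$height / 2 >= -tol & b$y_center + b$height / 2 <= 1 + tol
  if (any(!ok)) {
    stop("invalid bounding box (outside unit square or nonpositive size) in ",
         sum(!ok), " row(s)")
  }
  invisible(df)
}

empty_predictions <- function() {
  data.frame(image_id = character(), class = character(), score = numeric(),
             x_center = numeric(), y_center = numeric(),
             width = numeric(), height = numeric(),
             stringsAsFactors = FALSE)
}

empty_truth <- function() {
  data.frame(image_id = character(), class = character(), count = integer(),
             stringsAsFactors = FALSE)
}

as_predictions <- function(image_id, class, score,
                           x_center = NA_real_, y_center = NA_real_,
                           width = NA_real_, height = NA_real_) {
  data.frame(image_id = as.character(image_id), class = as.character(class),
             score = as.numeric(score),
             x_center = as.numeric(x_center), y_center = as.numeric(y_center),
             width = as.numeric(width), height = as.numeric(height),
             stringsAsFactors = FALSE)
}

check_scores <- function(score, where = "score") {
  if (any(!is.finite(score) | score < 0 | score > 1)) {
    bad <- which(!is.finite(score) | score < 0 | score > 1)
    stop(where, " outside [0,1] in row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) " ..." else "")
  }
  invisible(score)
}

check_vocabulary_labels <- function(labels, vocabulary, what = "class label") {
  unknown <- setdiff(unique(labels), vocabulary$label)
  if (length(unknown)) {
    stop("unknown ", what, "(s): ", paste(unknown, collapse = ", "),
         "; vocabulary: ", paste(vocabulary$label, collapse = ", "))
  }
  invisible(labels)
}

#' Read a detection CSV
#'
#' The canonical interchange dialect: UTF-8, comma-separated, header row
#' required, columns `image_id`, `class`, `score` mandatory and
#' `x_center`, `y_center`, `width`, `height` optional (YOLO normalized
#' center convention). Every class label must be in the vocabulary and
#' every score in \[0,1\].
#'
#' @param path path to the CSV file.
#' @param vocabulary a [class_vocabulary()].
#' @return predictions data.frame (see package overview for columns).
#' @export
read_detection_table <- function(path, vocabulary) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(image_id = "character"))
  required <- c("image_id", "class", "score")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("detection table ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0L) return(empty_predictions())
  check_scores(df$score)
  check_vocabulary_labels(df$class, vocabulary)
  for (col in c("x_center", "y_center", "width", "height")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
    df[[col]] <- as.numeric(df[[col]])
  }
  out <- df[, names(empty_predictions())]
  validate_boxes(out)
  out
}

#' Read a verified-annotation CSV
#'
#' Columns `image_id`, `class`, `count`; one row per (image, class) pair
#' with `count` the number of individuals of that class in the image.
#'
#' @inheritParams read_detection_table
#' @return truth data.frame with columns image_id, class, count.
#' @export
read_verified_table <- function(path, vocabulary) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(image_id = "character"))
  required <- c("image_id", "class", "count")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("verified table ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0L) return(empty_truth())
  check_vocabulary_labels(df$class, vocabulary)
  if (any(df$count < 1 | df$count != round(df$count))) {
    stop("verified counts must be positive integers")
  }
  if (anyDuplicated(df[, c("image_id", "class")])) {
    stop("duplicate (image_id, class) pairs in verified table")
  }
  df$count <- as.integer(df$count)
  df[, c("image_id", "class", "count")]
}

#' Read an image manifest CSV
#'
#' Columns `image_id`, `station_id`, `deployment_id`, optional `timestamp`
#' (ISO 8601) and `reviewed` (true/false; defaults to TRUE when absent).
#' Image ids must be unique and every deployment must map to exactly one
#' station.
#'
#' @param path path to the CSV file.
#' @return manifest data.frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(image_id = "character"))
  required <- c("image_id", "station_id", "deployment_id")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("manifest ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (!"timestamp" %in% names(df)) df$timestamp <- NA_character_
  if (!"reviewed" %in% names(df)) df$reviewed <- TRUE
  df$reviewed <- as.logical(df$reviewed)
  validate_manifest(df)
  df[, c("image_id", "station_id", "deployment_id", "timestamp", "reviewed")]
}

validate_manifest <- function(manifest) {
  if (anyDuplicated(manifest$image_id)) {
    stop("duplicate image_id in manifest")
  }
  dep <- unique(manifest[, c("deployment_id", "station_id")])
  if (anyDuplicated(dep$deployment_id)) {
    bad <- dep$deployment_id[duplicated(dep$deployment_id)]
    stop("deployment(s) mapped to more than one station: ",
         paste(unique(bad), collapse = ", "))
  }
  invisible(manifest)
}

# Predictions (or truth) must not reference images missing from the manifest.
check_images_in_manifest <- function(df, manifest, what = "detections") {
  extra <- setdiff(unique(df$image_id), manifest$image_id)
  if (length(extra)) {
    stop(length(extra), " image id(s) in ", what,
         " absent from the manifest (e.g., ",
         paste(utils::head(extra, 3L), collapse = ", "), ")")
  }
  invisible(df)
}

#' Parse a directory of YOLO label files
#'
#' Each file `<image_id>.txt` holds one object per line:
#' `class_index x_center y_center width height [score]`, with coordinates
#' normalized to image size and `class_index` 0-based into `class_map`.
#' Lines with the optional sixth field become predictions; lines without
#' it are ground-truth boxes, aggregated to per-image per-class counts.
#'
#' @param label_dir directory containing `.txt` label files.
#' @param class_map character vector of labels; index = line position
#'   (0-based), as in a YOLO `classes.txt`.
#' @return list with elements `predictions` (predictions data.frame, with
#'   boxes) and `annotations` (truth data.frame).
#' @export
parse_yolo_labels <- function(label_dir, class_map) {
  if (!dir.exists(label_dir)) stop("directory not found: ", label_dir)
  files <- sort(list.files(label_dir, pattern = "\\.txt$", full.names = TRUE))
  preds <- list()
  annots <- list()
  for (f in files) {
    image_id <- sub("\\.txt$", "", basename(f))
    lines <- readLines(f, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    for (i in seq_along(lines)) {
      fields <- strsplit(trimws(lines[[i]]), "[[:space:]]+")[[1]]
      if (!length(fields) %in% c(5L, 6L)) {
        stop("malformed line ", i, " in ", f, ": expected 5 or 6 fields")
      }
      num <- suppressWarnings(as.numeric(fields))
      if (any(is.na(num))) {
        stop("non-numeric field on line ", i, " in ", f)
      }
      idx <- num[[1]]
      if (idx != round(idx) || idx < 0 || idx >= length(class_map)) {
        stop("class_index ", fields[[1]], " out of range on line ", i,
             " in ", f)
      }
      label <- class_map[[idx + 1L]]
      if (length(fields) == 6L) {
        check_scores(num[[6]], where = paste0("score (", f, " line ", i, ")"))
        preds[[length(preds) + 1L]] <- as_predictions(
          image_id, label, num[[6]], num[[2]], num[[3]], num[[4]], num[[5]])
      } else {
        annots[[length(annots) + 1L]] <- data.frame(
          image_id = image_id, class = label, stringsAsFactors = FALSE)
      }
    }
  }
  predictions <- if (length(preds)) do.call(rbind, preds) else
    empty_predictions()
  validate_boxes(predictions)
  if (length(annots)) {
    a <- do.call(rbind, annots)
    agg <- stats::aggregate(list(count = rep(1L, nrow(a))),
                            by = a[, c("image_id", "class")], FUN = sum)
    agg <- agg[order(agg$image_id, agg$class), ]
    rownames(agg) <- NULL
    agg$count <- as.integer(agg$count)
    annotations <- agg
  } else {
    annotations <- empty_truth()
  }
  list(predictions = predictions, annotations = annotations)
}

#' Read a MegaDetector-style batch output JSON
#'
#' Ingests the v5 batch dialect: a top-level `images` array whose entries
#' carry a `file` name and a `detections` array of
#' `{category, conf, bbox}` objects. Bounding boxes are converted from the
#' corner-origin fractional `[x, y, width, height]` convention to the
#' normalized center convention used internally. The category map defaults
#' to the standard `1 = animal, 2 = person, 3 = vehicle` but an embedded
#' `detection_categories` object, when present, takes precedence.
#'
#' @param path path to the JSON file.
#' @param category_map named character vector mapping category ids to
#'   labels; overridden by the file's own `detection_categories`.
#' @return list with `predictions` (predictions data.frame) and
#'   `image_ids` (character vector of every image in the file, including
#'   those with zero detections).
#' @export
read_megadetector_json <- function(path,
                                   category_map = c("1" = "animal",
                                                    "2" = "person",
                                                    "3" = "vehicle")) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("malformed JSON in ", path, ": ",
                                           conditionMessage(e)))
  if (is.null(doc$images)) stop("no top-level 'images' array in ", path)
  if (!is.null(doc$detection_categories)) {
    category_map <- unlist(doc$detection_categories)
  }
  rows <- list()
  image_ids <- character(length(doc$images))
  for (i in seq_along(doc$images)) {
    img <- doc$images[[i]]
    id <- if (!is.null(img$file)) img$file else img$id
    if (is.null(id)) stop("image entry ", i, " has no 'file' or 'id' field")
    image_ids[[i]] <- id
    for (det in img$detections) {
      cat_id <- as.character(det$category)
      if (!cat_id %in% names(category_map)) {
        stop("unknown detection category \"", cat_id, "\" in ", path)
      }
      bb <- unlist(det$bbox)
      if (length(bb) != 4L) stop("bbox of length != 4 for image ", id)
      rows[[length(rows) + 1L]] <- as_predictions(
        id, category_map[[cat_id]], as.numeric(det$conf),
        x_center = bb[[1]] + bb[[3]] / 2, y_center = bb[[2]] + bb[[4]] / 2,
        width = bb[[3]], height = bb[[4]])
    }
  }
  predictions <- if (length(rows)) do.call(rbind, rows) else
    empty_predictions()
  check_scores(predictions$score)
  validate_boxes(predictions)
  list(predictions = predictions, image_ids = image_ids)
}

#' Convert a corner-origin fractional box to the center convention
#'
#' @param x,y corner-origin fractional coordinates of the top-left corner.
#' @param w,h fractional width and height.
#' @return data.frame with `x_center`, `y_center`, `width`, `height`.
#' @export
box_corner_to_center <- function(x, y, w, h) {
  data.frame(x_center = x + w / 2, y_center = y + h / 2,
             width = w, height = h)
}

#' Convert a center-convention box back to corner-origin fractional
#'
#' @param x_center,y_center center coordinates as fractions of image size.
#' @param width,height fractional width and height.
#' @return data.frame with `x`, `y`, `w`, `h`.
#' @export
box_center_to_corner <- function(x_center, y_center, width, height) {
  data.frame(x = x_center - width / 2, y = y_center - height / 2,
             w = width, h = height)
}

#' Write a result table to CSV with deterministic ordering
#'
#' Rows are sorted by `class` then `threshold` when those columns exist;
#' numbers are written with enough digits that a read-back reproduces the
#' values to at least 12 significant digits.
#'
#' @param records a data.frame of homogeneous result records (may have
#'   zero rows).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_results_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  ord_cols <- intersect(c("class", "class_label", "threshold"),
                        names(records))
  if (length(ord_cols) && nrow(records) > 1L) {
    records <- records[do.call(order, records[ord_cols]), , drop = FALSE]
  }
  out <- records
  for (col in names(out)) {
    if (is.numeric(out[[col]]) && !is.integer(out[[col]])) {
      s <- trimws(formatC(out[[col]], digits = 15, format = "g"))
      s[is.na(out[[col]])] <- NA
      out[[col]] <- s
    }
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
    TRUE
  }, error = function(e) {
    stop("cannot write results table to ", path, ": ", conditionMessage(e))
  })
  invisible(path)
}

#' Read back a result table written by [write_results_table()]
#' @param path path to the CSV.
#' @return data.frame.
#' @export
read_results_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
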