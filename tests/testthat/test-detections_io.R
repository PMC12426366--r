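vocab <- class_vocabulary(c("baboon", "bushbuck", "elephant", "human"),
                          c("animal", "animal", "animal", "human"))

test_that("detection CSV reading maps fields, validates, and handles degenerate files", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("image_id,class,score", "img1,baboon,0.90",
               "img2,bushbuck,0.25"), p)
  d <- read_detection_table(p, vocab)
  expect_equal(d$image_id, c("img1", "img2"))
  expect_equal(d$class, c("baboon", "bushbuck"))
  expect_equal(d$score, c(0.90, 0.25))
  expect_true(all(is.na(d$x_center)))

  writeLines(c("image_id,class,score", "img1,baboon,1.7"), p)
  expect_error(read_detection_table(p, vocab), "outside \\[0,1\\]")

  writeLines("image_id,class,score", p)
  expect_equal(nrow(read_detection_table(p, vocab)), 0L)

  writeLines(c("image_id,class", "img1,baboon"), p)
  expect_error(read_detection_table(p, vocab), "score")

  writeLines(c("image_id,class,score", "img1,aardvark,0.5"), p)
  expect_error(read_detection_table(p, vocab), "aardvark")
})

test_that("vocabulary construction enforces uniqueness and roles", {
  expect_error(class_vocabulary(c("a", "a")), "duplicate")
  expect_error(class_vocabulary("a", "alien"), "unknown role")
  expect_equal(vocabulary_labels(vocab, "human"), "human")
  expect_setequal(vocabulary_labels(vocab, "animal"),
                  c("baboon", "bushbuck", "elephant"))
})

test_that("YOLO label parsing distinguishes annotations from predictions and aggregates counts", {
  dir <- withr::local_tempdir()
  class_map <- c("baboon", "bushbuck", "elephant", "zebra")
  writeLines(c("3 0.5 0.5 0.2 0.3", "3 0.2 0.2 0.1 0.1",
               "0 0.5 0.5 0.4 0.4"), file.path(dir, "imgA.txt"))
  writeLines("3 0.5 0.5 0.2 0.3 0.87", file.path(dir, "imgB.txt"))
  out <- parse_yolo_labels(dir, class_map)
  ann <- out$annotations
  expect_equal(ann$count[ann$image_id == "imgA" & ann$class == "zebra"], 2L)
  expect_equal(ann$count[ann$image_id == "imgA" & ann$class == "baboon"], 1L)
  expect_equal(nrow(out$predictions), 1L)
  expect_equal(out$predictions$image_id, "imgB")
  expect_equal(out$predictions$score, 0.87)
  expect_equal(out$predictions$class, "zebra")

  writeLines("9 0.5 0.5 0.2 0.3", file.path(dir, "imgC.txt"))
  expect_error(parse_yolo_labels(dir, class_map), "out of range")
  writeLines("1 0.5 x 0.2 0.3", file.path(dir, "imgC.txt"))
  expect_error(parse_yolo_labels(dir, class_map), "non-numeric")
})

test_that("YOLO annotation counts survive a write/read round trip exactly", {
  dir <- withr::local_tempdir()
  set.seed(42)
  class_map <- c("baboon", "bushbuck")
  for (i in 1:6) {
    n <- sample.int(5L, 1L)
    lines <- sprintf("%d 0.5 0.5 0.2 0.2", sample(0:1, n, replace = TRUE))
    writeLines(lines, file.path(dir, sprintf("im%02d.txt", i)))
  }
  ann <- parse_yolo_labels(dir, class_map)$annotations
  p <- withr::local_tempfile(fileext = ".csv")
  write_results_table(ann, p)
  back <- read_verified_table(p, class_vocabulary(class_map))
  expect_equal(back[order(back$image_id, back$class), ],
               ann[order(ann$image_id, ann$class), ],
               ignore_attr = TRUE)
})

test_that("MegaDetector JSON ingestion converts coordinates and validates categories", {
  p <- withr::local_tempfile(fileext = ".json")
  doc <- list(images = list(
    list(file = "a.jpg", detections = list(
      list(category = "1", conf = 0.92, bbox = c(0.1, 0.2, 0.4, 0.4)))),
    list(file = "b.jpg", detections = list())))
  jsonlite::write_json(doc, p, auto_unbox = TRUE, digits = NA)
  out <- read_megadetector_json(p)
  expect_equal(out$image_ids, c("a.jpg", "b.jpg"))
  expect_equal(nrow(out$predictions), 1L)
  expect_equal(out$predictions$class, "animal")
  expect_equal(out$predictions$score, 0.92)
  expect_equal(out$predictions$x_center, 0.3)
  expect_equal(out$predictions$y_center, 0.4)
  expect_equal(out$predictions$width, 0.4)

  doc$images[[1]]$detections[[1]]$category <- "7"
  jsonlite::write_json(doc, p, auto_unbox = TRUE, digits = NA)
  expect_error(read_megadetector_json(p), "\"7\"")

  writeLines("{not json", p)
  expect_error(read_megadetector_json(p), "malformed JSON")
})

test_that("corner/center box conversion is an involution to 1e-12", {
  set.seed(7)
  w <- runif(50, 0.05, 0.5); h <- runif(50, 0.05, 0.5)
  x <- runif(50, 0, 1 - w); y <- runif(50, 0, 1 - h)
  ctr <- box_corner_to_center(x, y, w, h)
  back <- box_center_to_corner(ctr$x_center, ctr$y_center,
                               ctr$width, ctr$height)
  expect_equal(back$x, x, tolerance = 1e-12)
  expect_equal(back$y, y, tolerance = 1e-12)
  expect_equal(back$w, w, tolerance = 1e-12)
})

test_that("result tables round-trip through CSV to 12 significant digits", {
  df <- data.frame(class = c("b", "a"), threshold = c(0.3, 0.25),
                   TP = c(3L, 1L),
                   precision = c(1 / 3, 0.123456789012345),
                   stringsAsFactors = FALSE)
  p <- withr::local_tempfile(fileext = ".csv")
  write_results_table(df, p)
  back <- read_results_table(p)
  # deterministic row order: sorted by class then threshold
  expect_equal(back$class, c("a", "b"))
  expect_equal(back$precision, c(0.123456789012345, 1 / 3),
               tolerance = 1e-12)

  write_results_table(df[0, ], p)
  expect_equal(nrow(read_results_table(p)), 0L)
})

test_that("manifest validation rejects broken station mappings and off-manifest images", {
  m <- manifest_df(c("i1", "i2"))
  m$station_id <- c("S1", "S2")   # one deployment, two stations
  p <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(m, p, row.names = FALSE)
  expect_error(read_manifest(p), "more than one station")

  ok <- manifest_df(c("i1", "i2"))
  expect_error(
    collapse_to_binary(pred_df("i9", "baboon", 0.5), truth_df(), ok, vocab),
    "absent from the manifest")
})
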