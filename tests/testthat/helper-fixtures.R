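# Shared builders for small in-memory fixtures.

pred_df <- function(image_id = character(), class = character(),
                    score = numeric()) {
  n <- length(image_id)
  data.frame(image_id = as.character(image_id),
             class = as.character(class),
             score = as.numeric(score),
             x_center = rep(NA_real_, n), y_center = rep(NA_real_, n),
             width = rep(NA_real_, n), height = rep(NA_real_, n),
             stringsAsFactors = FALSE)
}

truth_df <- function(image_id = character(), class = character(),
                     count = integer()) {
  data.frame(image_id = as.character(image_id),
             class = as.character(class), count = as.integer(count),
             stringsAsFactors = FALSE)
}

manifest_df <- function(image_id, station_id = "S1",
                        deployment_id = "S1-D1", reviewed = TRUE) {
  data.frame(image_id = as.character(image_id),
             station_id = station_id, deployment_id = deployment_id,
             timestamp = NA_character_, reviewed = reviewed,
             stringsAsFactors = FALSE)
}

# A small two-species study used by the binary-filter hand examples:
# 4 animal images with max scores {0.9, 0.5, 0.3, none} and 6 empty
# images with max scores {0.4, 0.8, none x4}.
binary_hand_study <- function() {
  imgs <- sprintf("i%02d", 1:10)
  truth <- truth_df(imgs[1:4], "baboon", 1L)
  preds <- pred_df(c("i01", "i02", "i03", "i05", "i06"),
                   "baboon", c(0.9, 0.5, 0.3, 0.4, 0.8))
  list(predictions = preds, truth = truth,
       manifest = manifest_df(imgs),
       vocabulary = class_vocabulary(c("baboon", "bushbuck")))
}
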