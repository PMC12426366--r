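vocab2 <- class_vocabulary(c("baboon", "bushbuck", "human", "vehicle"),
                           c("animal", "animal", "human", "vehicle"))

test_that("binary collapse takes the max animal score and excludes human/vehicle-only images", {
  preds <- pred_df(c("i1", "i1", "i2", "i3"),
                   c("baboon", "bushbuck", "human", "baboon"),
                   c(0.4, 0.9, 0.99, 0.2))
  truth <- truth_df(c("i1", "i2"), c("baboon", "human"), c(1L, 1L))
  man <- manifest_df(c("i1", "i2", "i3", "i4"))
  b <- collapse_to_binary(preds, truth, man, vocab2)
  expect_setequal(b$image_id, c("i1", "i3", "i4"))   # i2 is human-only
  expect_equal(b$max_animal_score[b$image_id == "i1"], 0.9)
  expect_equal(b$true_state[b$image_id == "i1"], "animal")
  expect_equal(b$true_state[b$image_id == "i4"], "empty")
  expect_true(is.na(b$max_animal_score[b$image_id == "i4"]))

  # multi-class truth images are excluded too, but can be retained
  truth2 <- rbind(truth, truth_df("i4", "baboon", 1L),
                  truth_df("i4", "bushbuck", 2L))
  b2 <- collapse_to_binary(preds, truth2, man, vocab2)
  expect_false("i4" %in% b2$image_id)
  b3 <- collapse_to_binary(preds, truth2, man, vocab2,
                           keep_excluded = TRUE)
  expect_setequal(b3$image_id, c("i1", "i2", "i3", "i4"))
})

test_that("confusion sweep reproduces the hand-enumerated example", {
  st <- binary_hand_study()
  # extend to the full spec example: 4 animal {0.9,0.5,0.3,none},
  # 6 empty {0.4,0.8,none x4}
  b <- collapse_to_binary(st$predictions, st$truth, st$manifest,
                          st$vocabulary)
  expect_equal(nrow(b), 10L)
  sw <- binary_confusion_sweep(b, thresholds = c(0.25, 0.6))
  expect_equal(unlist(sw[sw$threshold == 0.25, c("TP", "FN", "FP", "TN")]),
               c(TP = 3L, FN = 1L, FP = 2L, TN = 4L))
  expect_equal(sw$sensitivity[1], 0.75)
  expect_equal(sw$specificity[1], 2 / 3, tolerance = 1e-12)
  expect_equal(unlist(sw[sw$threshold == 0.6, c("TP", "FN", "FP", "TN")]),
               c(TP = 1L, FN = 3L, FP = 1L, TN = 5L))
  expect_equal(sw$sensitivity[2], 0.25)
  expect_equal(sw$specificity[2], 5 / 6, tolerance = 1e-12)
})

test_that("degenerate detectors hit the sensitivity/specificity boundaries", {
  imgs <- sprintf("i%02d", 1:8)
  truth <- truth_df(imgs[1:4], "baboon", 1L)
  man <- manifest_df(imgs)
  perfect <- pred_df(imgs[1:4], "baboon", 1.0)
  b <- collapse_to_binary(perfect, truth, man, vocab2)
  sw <- binary_confusion_sweep(b)
  expect_true(all(sw$sensitivity == 1))
  expect_true(all(sw$specificity == 1))

  none <- collapse_to_binary(pred_df(), truth, man, vocab2)
  sw0 <- binary_confusion_sweep(none)
  expect_true(all(sw0$sensitivity == 0))
  expect_true(all(sw0$specificity == 1))

  expect_error(binary_confusion_sweep(none[0, ]), "no images")
})

test_that("sweep is monotone and conserves row sums on random records", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(5:60, 1)
    b <- data.frame(
      image_id = sprintf("i%03d", seq_len(n)),
      true_state = sample(c("animal", "empty"), n, replace = TRUE),
      max_animal_score = ifelse(runif(n) < 0.3, NA_real_,
                                round(runif(n), 2)),
      stringsAsFactors = FALSE)
    sw <- binary_confusion_sweep(b, thresholds = threshold_grid(0.05, 1, 0.05))
    expect_true(all(diff(sw$TP) <= 0))
    expect_true(all(diff(sw$TN) >= 0))
    expect_true(all(diff(sw$sensitivity) <= 0 | is.na(diff(sw$sensitivity))))
    expect_true(all(diff(sw$specificity) >= 0 | is.na(diff(sw$specificity))))
    expect_equal(unique(sw$TP + sw$FN), sum(b$true_state == "animal"))
    expect_equal(unique(sw$FP + sw$TN), sum(b$true_state == "empty"))
  }
})

test_that("detector agreement tables cross-tabulate correctly", {
  st <- binary_hand_study()
  b <- collapse_to_binary(st$predictions, st$truth, st$manifest,
                          st$vocabulary)
  same <- compare_detectors(b, b, 0.5)
  expect_equal(sum(same$n), nrow(b))
  expect_equal(sum(same$n[same$a_animal != same$b_animal]), 0L)

  # 3 images: A scores {0.9, 0.2, 0.9}, B scores {0.9, 0.9, none}, t = 0.5
  mk <- function(scores) data.frame(
    image_id = c("x1", "x2", "x3"), true_state = "animal",
    max_animal_score = scores, stringsAsFactors = FALSE)
  tab <- compare_detectors(mk(c(0.9, 0.2, 0.9)), mk(c(0.9, 0.9, NA)), 0.5)
  cell <- function(a, bb) sum(tab$n[tab$a_animal == a & tab$b_animal == bb])
  expect_equal(cell(TRUE, TRUE), 1L)
  expect_equal(cell(TRUE, FALSE), 1L)
  expect_equal(cell(FALSE, TRUE), 1L)
  expect_equal(cell(FALSE, FALSE), 0L)

  # A predicts everywhere, B nowhere
  tab2 <- compare_detectors(mk(rep(1, 3)), mk(rep(NA_real_, 3)), 0.5)
  expect_equal(cell <- sum(tab2$n[tab2$a_animal & !tab2$b_animal]), 3L)

  expect_error(compare_detectors(b, b[-1, ], 0.5), "symmetric")
})

test_that("review planning follows the empty-sample and bin-sample rules", {
  # dep1: 500 predicted-empty images -> exactly 100 sampled
  # dep2: 60 predicted-empty images  -> all 60
  ids1 <- sprintf("e1-%03d", 1:500)
  ids2 <- sprintf("e2-%03d", 1:60)
  man <- rbind(manifest_df(ids1, "S1", "S1-D1"),
               manifest_df(ids2, "S1", "S1-D2"))
  plan <- plan_review(pred_df(), man, vocab2, seed = 3L)
  expect_equal(sum(plan$deployment_id == "S1-D1"), 100L)
  expect_equal(sum(plan$deployment_id == "S1-D2"), 60L)
  expect_true(all(plan$reason == "empty-sample"))
  expect_false(anyDuplicated(plan$image_id) > 0)

  # identical seed -> identical plan
  expect_identical(plan, plan_review(pred_df(), man, vocab2, seed = 3L))
})

test_that("overflowing strata switch to per-bin sampling with exact counts", {
  n <- 3000L
  ids <- sprintf("a%04d", seq_len(n))
  man3 <- rbind(manifest_df(ids, "S2", "S2-D1"),
                manifest_df(sprintf("s%02d", 1:30), "S2", "S2-D2"))
  # scores cover all four review bins (bin 1 only via scores == 0.25)
  scores <- rep(c(0.25, 0.4, 0.6, 0.9), length.out = n)
  preds <- rbind(pred_df(ids, "baboon", scores),
                 pred_df(sprintf("s%02d", 1:30), "bushbuck", 0.8))
  plan <- plan_review(preds, man3, vocab2, overflow_trigger = 2000L,
                      bin_sample_target = 50L, seed = 9L)
  bins <- plan[plan$reason == "bin-sample", ]
  expect_equal(nrow(bins), 200L)            # 50 per bin x 4 bins
  expect_true(all(bins$deployment_id == "S2-D1"))
  # the small stratum is reviewed exhaustively
  expect_equal(sum(plan$reason == "animal-prediction"), 30L)
  # sampled images come from all four score bins, >= 50 each
  sc <- scores[match(bins$image_id, ids)]
  expect_equal(as.integer(table(cut(sc, c(0, 0.25, 0.5, 0.75, 1),
                                    include.lowest = TRUE))),
               rep(50L, 4))
})
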