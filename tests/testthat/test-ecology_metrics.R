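test_that("site richness counts distinct qualifying species", {
  man <- rbind(manifest_df(c("i1", "i2", "i3"), "S1", "S1-D1"),
               manifest_df("i4", "S2", "S2-D1"))
  truth <- truth_df(c("i1", "i2", "i3"),
                    c("baboon", "elephant", "baboon"), 1L)
  r <- site_richness(truth, man)
  expect_equal(r[["S1"]], 2L)
  expect_equal(r[["S2"]], 0L)

  preds <- pred_df(c("i1", "i2"), c("baboon", "leopard"), c(0.9, 0.3))
  expect_equal(site_richness(preds, man, threshold = 0.5)[["S1"]], 1L)
  expect_error(site_richness(preds, man), "threshold")

  hum <- pred_df("i4", "human", 0.99)
  expect_equal(site_richness(hum, man, threshold = 0.25)[["S2"]], 0L)
})

test_that("richness concordance reproduces closed-form regressions", {
  obs <- c(A = 2, B = 4, C = 6)
  ident <- richness_concordance(obs, obs)
  expect_equal(ident$slope, 1, tolerance = 1e-12)
  expect_equal(ident$intercept, 0, tolerance = 1e-12)
  expect_equal(ident$r_squared, 1, tolerance = 1e-12)
  expect_equal(ident$mean_abs_bias, 0)
  expect_equal(ident$sd_abs_bias, 0)

  shifted <- richness_concordance(obs, obs + 1)
  expect_equal(shifted$slope, 1, tolerance = 1e-10)
  expect_equal(shifted$intercept, 1, tolerance = 1e-10)
  expect_equal(shifted$r_squared, 1, tolerance = 1e-10)
  expect_equal(shifted$mean_abs_bias, 1)
  expect_equal(shifted$sd_abs_bias, 0)

  flat <- richness_concordance(obs, c(A = 3, B = 3, C = 3))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_equal(flat$r_squared, 0)

  expect_error(richness_concordance(c(A = 2, B = 2, C = 2), obs),
               "zero variance")
  expect_error(richness_concordance(obs, obs[1:2]), "same stations")
})

test_that("count records keep only single-species true-positive images", {
  truth <- rbind(truth_df("i1", "baboon", 3L),
                 truth_df("i2", "baboon", 2L),
                 truth_df("i3", "baboon", 1L),
                 truth_df("i3", "elephant", 1L))
  preds <- rbind(pred_df(c("i1", "i1"), "baboon", c(0.8, 0.6)),
                 pred_df("i2", "bushbuck", 0.9),
                 pred_df(c("i3", "i3"), c("baboon", "elephant"), 0.9))
  rec <- extract_count_records(preds, truth, 0.25)
  expect_equal(nrow(rec), 1L)   # i2 not TP, i3 multi-species
  expect_equal(rec$count_true, 3L)
  expect_equal(rec$count_pred, 2L)

  # below-threshold boxes neither qualify the image nor count
  rec2 <- extract_count_records(preds, truth, 0.7)
  expect_equal(rec2$count_pred, 1L)
})

test_that("difference and ratio cell means equal hand-computed values", {
  rec <- data.frame(image_id = c("a", "b", "c"), class = "A",
                    count_true = c(2L, 4L, 3L), count_pred = c(1L, 3L, 3L))
  d <- fit_count_difference(rec)
  expect_equal(d$estimate, 2 / 3, tolerance = 1e-12)
  r <- fit_count_ratio(rec)
  expect_equal(r$estimate, (0.5 + 0.75 + 1) / 3, tolerance = 1e-12)

  perfect <- rec
  perfect$count_pred <- perfect$count_true
  expect_equal(fit_count_difference(perfect)$estimate, 0)
  expect_equal(fit_count_ratio(perfect)$estimate, 1)
})

test_that("cell means are invariant to record order, relabeling, and joint fitting", {
  set.seed(8)
  rec <- data.frame(image_id = sprintf("i%02d", 1:20),
                    class = sample(c("A", "B"), 20, replace = TRUE),
                    count_true = sample(1:6, 20, replace = TRUE))
  rec$count_pred <- pmax(1L, rec$count_true - sample(0:2, 20, replace = TRUE))
  joint <- fit_count_difference(rec)
  shuffled <- fit_count_difference(rec[sample(nrow(rec)), ])
  expect_equal(joint$estimate, shuffled$estimate, tolerance = 1e-12)
  # joint fit equals per-class separate fits
  for (cl in c("A", "B")) {
    sep <- fit_count_difference(rec[rec$class == cl, ])
    expect_equal(joint$estimate[joint$class == cl], sep$estimate,
                 tolerance = 1e-12)
  }
  # relabeling permutes rows without changing estimates
  rl <- rec
  rl$class <- chartr("AB", "ZY", rl$class)
  fit_rl <- fit_count_difference(rl)
  expect_equal(sort(fit_rl$estimate), sort(joint$estimate),
               tolerance = 1e-12)
})

test_that("Poisson GLM recovers exact multiplicative relationships", {
  rec <- data.frame(image_id = c("a", "b", "c"), class = "A",
                    count_true = c(2L, 4L, 8L), count_pred = c(1L, 2L, 4L))
  fit <- fit_count_glm(rec)
  expect_equal(fit$coefficients$intercept, log(2), tolerance = 1e-6)
  expect_equal(fit$coefficients$slope, 1, tolerance = 1e-6)
  expect_lt(fit$deviance, 1e-8)

  ident <- data.frame(image_id = letters[1:4], class = "A",
                      count_true = c(1L, 2L, 3L, 5L),
                      count_pred = c(1L, 2L, 3L, 5L))
  fi <- fit_count_glm(ident)
  expect_equal(fi$coefficients$intercept, 0, tolerance = 1e-6)
  expect_equal(fi$coefficients$slope, 1, tolerance = 1e-6)

  flat <- data.frame(image_id = c("a", "b"), class = "A",
                     count_true = c(2L, 3L), count_pred = 1L)
  expect_error(fit_count_glm(flat), "inestimable")
})

test_that("richness sweep ties stations, thresholds, and fits together", {
  set.seed(21)
  cfg <- default_synth_config(seed = 17L)
  study <- simulate_study(cfg)
  rs <- richness_sweep(study$predictions, study$truth, study$manifest)
  expect_equal(nrow(rs$fits), 8L)   # 0.25..0.95 by 0.10
  expect_equal(nrow(rs$records), 8L * cfg$n_stations)
  # observed richness is threshold-free: identical across thresholds
  ob <- tapply(rs$records$observed_richness, rs$records$station_id,
               function(x) length(unique(x)))
  expect_true(all(ob == 1))
  # predicted richness never increases with the threshold
  for (st in unique(rs$records$station_id)) {
    pr <- rs$records$predicted_richness[rs$records$station_id == st]
    expect_true(all(diff(pr) <= 0))
  }
})

test_that("the truncated binomial mean matches direct enumeration", {
  # size 2, p 1/2: E[X | X >= 1] = (1 * 1/2 + 2 * 1/4) / (3/4) = 4/3
  expect_equal(truncated_binomial_mean(2, 0.5), 4 / 3, tolerance = 1e-12)
  expect_equal(truncated_binomial_mean(3, 1), 3)
})
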