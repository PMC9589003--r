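# Odd-even split-half reliability and indicator weight analysis.

test_that("splitting 75 frames yields valid 38/37-frame halves", {
  seg <- make_toy_segment(75, seed = 30)
  halves <- split_half(seg)
  expect_equal(nrow(halves$odd$channels), 38L)
  expect_equal(nrow(halves$even$channels), 37L)
  expect_equal(halves$odd$fps, seg$fps / 2)
  # interleaving the halves reproduces the original segment
  rebuilt <- matrix(NA_real_, 75, 48)
  rebuilt[seq(1, 75, 2), ] <- halves$odd$channels
  rebuilt[seq(2, 75, 2), ] <- halves$even$channels
  expect_equal(rebuilt, unname(seg$channels))
  # determinism
  h2 <- split_half(seg)
  expect_identical(halves$odd$channels, h2$odd$channels)
  expect_error(split_half(make_toy_segment(60)), "64")
})

test_that("half-segment features use the same code path as direct extraction", {
  seg <- make_toy_segment(75, seed = 31)
  halves <- split_half(seg)
  direct <- gait_segment(seg$channels[seq(2, 75, 2), ], fps = seg$fps / 2,
                         participant_id = seg$participant_id)
  expect_identical(segment_features(halves$even), segment_features(direct))
})

test_that("noiseless periodic walkers give near-perfect split-half reliability", {
  # model trained under realistic keypoint jitter (selection then favours
  # jitter-robust features, as with real recordings) ...
  cfgN <- cohort_config(n_walkers = 30, bout_seconds = 20, noise_sd = 1,
                        trait_noise_sd = 0, stride_freq_range = c(1.35, 1.8),
                        seed = 141)
  coN <- quiet(simulate_cohort(cfgN))
  XN <- quiet(extract_cohort_features(coN$sequences))
  m <- quiet(trait_model(XN, coN$traits$score, algorithm = "lr", max_k = 10,
                         tol = 1e-3, seed = 7))
  # ... scored on noiseless deterministic kinematics: both halves sample the
  # same process, so predictions must agree almost perfectly
  cfg0 <- cohort_config(n_walkers = 15, bout_seconds = 20, noise_sd = 0,
                        trait_noise_sd = 0, stride_freq_range = c(1.35, 1.8),
                        seed = 41)
  co0 <- quiet(simulate_cohort(cfg0))
  segs <- lapply(co0$sequences, function(s) quiet(preprocess_sequence(s)))
  rel <- split_half_reliability(m, segs)
  expect_gte(rel$r_split, 0.99)
  expect_equal(rel$n, 15L)
  expect_equal(sum(rel$half_sizes), 75L)
})

test_that("reliability is deterministic and drops failing participants", {
  cfg <- cohort_config(n_walkers = 6, bout_seconds = 20, noise_sd = 0.5,
                       stride_freq_range = c(1.35, 1.8), seed = 42)
  co <- quiet(simulate_cohort(cfg))
  segs <- lapply(co$sequences, function(s) quiet(preprocess_sequence(s)))
  X <- t(sapply(segs, segment_features))
  m <- quiet(trait_model(X, co$traits$score, algorithm = "lr", max_k = 2, seed = 1))
  r1 <- split_half_reliability(m, segs)
  r2 <- split_half_reliability(m, segs)
  expect_identical(r1$r_split, r2$r_split)
  # a segment too short to split is dropped with a warning
  short <- gait_segment(segs[[1]]$channels[1:40, ], fps = 25,
                        participant_id = "short")
  expect_warning(r3 <- split_half_reliability(m, c(segs, list(short))),
                 "dropping participant 'short'")
  expect_equal(r3$n, 6L)
  expect_error(split_half_reliability(m, list(short, short, short)),
               "fewer than 3")
})

test_that("weight aggregation maps coefficients to indicators conservatively", {
  set.seed(43)
  nm <- c("td_angle_A9_mean", "td_dist_D5_x_max", "td_dist_D5_y_rms",
          "td_raw_j02_x_mean")
  X <- matrix(rnorm(120), 30, 4, dimnames = list(NULL, nm))
  y <- -1.5 * scale(X[, 1])[, 1] + 0.5 * scale(X[, 2])[, 1] +
    0.25 * scale(X[, 3])[, 1]
  m <- trait_model(X, y, algorithm = "lr", features_use = nm)
  wt <- aggregate_weights(m)
  expect_s3_class(wt, "weight_table")
  cf <- coef(m)[-1]
  expect_equal(wt$weight[wt$indicator == "A9"], abs(cf[["td_angle_A9_mean"]]),
               tolerance = 1e-10)
  expect_equal(wt$weight[wt$indicator == "D5"],
               abs(cf[["td_dist_D5_x_max"]]) + abs(cf[["td_dist_D5_y_rms"]]),
               tolerance = 1e-10)
  # unselected indicators are present with weight zero
  expect_equal(wt$weight[wt$indicator == "A0"], 0)
  expect_equal(sum(wt$group == "angle"), 10L)
  expect_equal(sum(wt$group == "distance"), 13L)
  # conservation: total aggregated weight equals the coefficient mass
  expect_equal(sum(wt$weight), sum(abs(cf)), tolerance = 1e-10)
  # weights are defined only for the linear model
  msvr <- trait_model(X, y, algorithm = "svr_rbf", features_use = nm)
  expect_error(aggregate_weights(msvr), "linear")
})

test_that("the distances-versus-angles comparison is a pooled t with df 21", {
  dict_groups <- function(dw, aw) {
    wt <- data.frame(
      indicator = c(paste0("D", 1:13), paste0("A", 0:9)),
      group = c(rep("distance", 13), rep("angle", 10)),
      weight = c(dw, aw))
    class(wt) <- c("weight_table", "data.frame")
    wt
  }
  set.seed(44)
  cmp <- compare_indicator_groups(dict_groups(rnorm(13, 2, 0.7),
                                              rnorm(10, 0.9, 1.3)))
  expect_equal(cmp$df, 21)
  # closed-form pooled t on a constructed table
  dw <- c(rep(1, 12), 2); aw <- c(rep(1, 9), 2)
  got <- compare_indicator_groups(dict_groups(dw, aw))
  tt <- t.test(dw, aw, var.equal = TRUE)
  expect_equal(got$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(got$p, tt$p.value, tolerance = 1e-12)
  expect_equal(got$sd_dist, sd(dw))
  # identical group means (with internal variance) give t = 0, p = 1
  same <- dict_groups(c(rep(1, 6), rep(3, 6), 2),
                      c(rep(1, 4), rep(3, 4), 2, 2))
  expect_equal(mean(same$weight[same$group == "distance"]),
               mean(same$weight[same$group == "angle"]))
  got0 <- compare_indicator_groups(same)
  expect_equal(got0$t, 0, tolerance = 1e-12)
  expect_equal(got0$p, 1, tolerance = 1e-12)
  # t grows and p falls as the distance-angle gap widens
  ps <- sapply(c(0.5, 1, 2), function(delta)
    compare_indicator_groups(dict_groups(c(rep(1, 6), rep(2, 7)) + delta,
                                         c(rep(1, 5), rep(2, 5))))$p)
  expect_true(all(diff(ps) < 0))
  # all-identical weights have zero pooled variance
  expect_error(compare_indicator_groups(dict_groups(rep(1, 13), rep(1, 10))),
               "pooled variance")
})
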