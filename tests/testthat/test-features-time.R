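# Time-domain features: differences, angles, distances, summary statistics,
# the 1,320-dimensional block.

test_that("frame differences are first differences with length n - 1", {
  seg <- make_toy_segment(40)
  d <- frame_difference(seg)
  expect_equal(nrow(d), 39L)
  expect_equal(d[, 3], diff(seg$channels[, 3]), ignore_attr = TRUE)
  const <- gait_segment(matrix(2, 75, 48))
  expect_true(all(frame_difference(const) == 0))
  expect_equal(nrow(frame_difference(make_toy_segment(75))), 74L)
})

test_that("angle series reproduces hand geometry", {
  nr <- 35L
  px <- matrix(0, nr, 25); py <- matrix(0, nr, 25)
  px[, 9] <- 50; py[, 9] <- 50             # MidHip away from the test joints
  # vertex Neck (j1) at origin after centering is awkward; use explicit joints:
  # a = Nose (j0), b = Neck (j1), c = RShoulder (j2)
  px[, 1] <- 0; py[, 1] <- 1               # a = (0, 1)
  px[, 2] <- 0; py[, 2] <- 0               # b = (0, 0)
  px[, 3] <- 1; py[, 3] <- 0               # c = (1, 0)
  seg <- segment_from_joints(px, py)
  expect_equal(angle_series(seg, "A0"), rep(pi / 2, nr))
  # collinear opposite -> pi; collinear same side -> 0
  px[, 1] <- -1; py[, 1] <- 0
  expect_equal(angle_series(segment_from_joints(px, py), "A0"), rep(pi, nr))
  px[, 1] <- 1; px[, 3] <- 2
  expect_equal(angle_series(segment_from_joints(px, py), "A0"), rep(0, nr))
  # zero-length limb vector is a degeneracy error naming the frame
  px[, 1] <- 0; py[, 1] <- 0
  expect_error(angle_series(segment_from_joints(px, py), "A0"),
               "degenerate.*frame 1")
})

test_that("distance series are per-axis absolute differences", {
  nr <- 35L
  px <- matrix(0, nr, 25); py <- matrix(0, nr, 25)
  px[, 9] <- -10; py[, 9] <- -10
  px[, 2] <- 3; py[, 2] <- 4               # Neck; D1 = (Neck, Nose)
  seg <- segment_from_joints(px, py)
  d <- distance_series(seg, "D1")
  expect_equal(unname(d[1, ]), c(3, 4))
  # symmetry: swapping the pair leaves the output unchanged
  expect_equal(distance_series(seg, c(1L, 0L)), distance_series(seg, c(0L, 1L)))
  # coincident joints -> zero
  expect_true(all(distance_series(seg, "D8") == 0))
})

test_that("summary statistics match hand computation and conventions", {
  s <- summary_stats(c(1, 2, 3))
  expect_equal(unname(s["abs_energy"]), 14)
  expect_equal(unname(s["mean"]), 2)
  expect_equal(unname(s["variance"]), 2 / 3)
  expect_equal(unname(s["rms"]), sqrt(14 / 3))
  expect_equal(unname(s["skewness"]), 0)
  const <- summary_stats(rep(5, 4))
  expect_equal(unname(const[c("variance", "skewness", "kurtosis",
                              "variation_coefficient")]), rep(0, 4))
  expect_equal(unname(const["abs_energy"]), 100)
  expect_error(summary_stats(1), "length")
})

test_that("summary statistics agree with a naive reference on random series", {
  set.seed(10)
  for (i in 1:25) {
    x <- rnorm(sample(5:80, 1), mean = runif(1, -3, 3), sd = runif(1, 0.1, 4))
    expect_equal(summary_stats(x), naive_stats(x), tolerance = 1e-12)
  }
})

test_that("negating a series flips the odd statistics and preserves the even", {
  set.seed(11)
  for (i in 1:10) {
    x <- rnorm(30)
    a <- summary_stats(x); b <- summary_stats(-x)
    expect_equal(unname(b["max"]), -unname(a["min"]))
    expect_equal(unname(b["mean"]), -unname(a["mean"]))
    expect_equal(unname(b["skewness"]), -unname(a["skewness"]))
    expect_equal(b[c("variance", "rms", "abs_energy", "kurtosis")],
                 a[c("variance", "rms", "abs_energy", "kurtosis")])
  }
})

test_that("the time-domain block has 1,320 uniquely named features", {
  seg <- make_toy_segment(75)
  fv <- time_domain_features(seg)
  expect_length(fv, 1320L)
  expect_equal(anyDuplicated(names(fv)), 0L)
  # names are stable across runs and segments
  expect_identical(names(fv), names(time_domain_features(make_toy_segment(40, seed = 9))))
  # angle means live in [0, pi]; distance location stats are nonnegative
  ang_means <- fv[grepl("^td_angle_.*_mean$", names(fv))]
  expect_true(all(ang_means >= 0 & ang_means <= pi))
  dist_loc <- fv[grepl("^td_dist_.*_(max|min|mean|rms)$", names(fv))]
  expect_true(all(dist_loc >= 0))
})

test_that("feature values equal a naive per-series reference on a toy segment", {
  seg <- make_toy_segment(40, seed = 3)
  fv <- time_domain_features(seg)
  # raw channel 5, diff channel 5, D3 x-channel, A4 - each against naive_stats
  expect_equal(unname(fv[paste0("td_raw_j02_x_", names(naive_stats(1:5)))]),
               unname(naive_stats(seg$channels[, "j02_x"])))
  expect_equal(unname(fv[paste0("td_diff_j14_y_", names(naive_stats(1:5)))]),
               unname(naive_stats(diff(seg$channels[, "j14_y"]))))
  d3 <- abs(seg$channels[, "j04_x"] - seg$channels[, "j02_x"])
  expect_equal(unname(fv[paste0("td_dist_D3_x_", names(naive_stats(1:5)))]),
               unname(naive_stats(d3)))
  a4 <- angle_series(seg, "A4")
  expect_equal(unname(fv[paste0("td_angle_A4_", names(naive_stats(1:5)))]),
               unname(naive_stats(a4)))
})

test_that("left-right mirroring permutes the paired indicators exactly", {
  seg <- make_toy_segment(75, seed = 8)
  swap <- c("2" = 5, "5" = 2, "3" = 6, "6" = 3, "4" = 7, "7" = 4,
            "9" = 12, "12" = 9, "10" = 13, "13" = 10, "11" = 14, "14" = 11)
  ch <- seg$channels
  m <- ch
  for (j in c(0:7, 9:24)) {
    src <- if (as.character(j) %in% names(swap)) swap[[as.character(j)]] else j
    m[, sprintf("j%02d_x", j)] <- -ch[, sprintf("j%02d_x", src)]
    m[, sprintf("j%02d_y", j)] <- ch[, sprintf("j%02d_y", src)]
  }
  mir <- gait_segment(m)
  fv <- time_domain_features(seg); fm <- time_domain_features(mir)
  pairs <- list(c("A0", "A1"), c("A2", "A3"), c("A4", "A5"), c("A6", "A7"),
                c("A8", "A9"), c("D2", "D4"), c("D3", "D5"), c("D8", "D10"),
                c("D9", "D11"))
  for (p in pairs) {
    pre <- if (startsWith(p[1], "A")) "td_angle_" else "td_dist_"
    n1 <- names(fv)[startsWith(names(fv), paste0(pre, p[1], "_"))]
    n2 <- sub(paste0(pre, p[1], "_"), paste0(pre, p[2], "_"), n1)
    expect_equal(unname(fm[n1]), unname(fv[n2]), tolerance = 1e-12)
  }
})
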