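# Standardization, sequential forward selection, the seven regressors,
# cross-validated evaluation, prediction and persistence.

make_xy <- function(n = 60, p = 12, seed = 20, signal = 7, noise = 0) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- 3 * X[, signal] + rnorm(n, sd = noise)
  list(X = X, y = y)
}

test_that("standardization z-scores, drops constants, and inverts", {
  set.seed(19)
  X <- cbind(a = rnorm(30, 5, 2), b = rnorm(30, -1, 0.1), c = rep(4, 30))
  expect_warning(std <- standardize_features(X), "zero-variance")
  expect_equal(colnames(std$features), c("a", "b"))
  expect_lt(max(abs(colMeans(std$features))), 1e-10)
  expect_equal(unname(apply(std$features, 2, sd)), c(1, 1), tolerance = 1e-10)
  # params fitted on A applied to B, then inverted, recover B exactly
  B <- cbind(a = rnorm(10), b = rnorm(10))
  ZB <- standardize_features(B, std$params)$features
  back <- sweep(sweep(ZB, 2, std$params$sd, "*"), 2, std$params$mean, "+")
  expect_equal(back, B, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(standardize_features(B[, "a", drop = FALSE], std$params), "lacks")
})

test_that("forward selection finds the true driver first, for lr and others", {
  d <- make_xy(n = 50, p = 11, signal = 7)
  for (alg in c("lr", "rfr")) {
    sel <- sequential_forward_selection(d$X, d$y, algorithm = alg,
                                        k_folds = 5, max_k = 2, seed = 2)
    expect_equal(sel$features[1], "f7")
  }
  # tol = Inf stops after exactly one accepted feature
  sel1 <- sequential_forward_selection(d$X, d$y, tol = Inf, seed = 2)
  expect_length(sel1$features, 1L)
  # accepted scores are nondecreasing
  d2 <- make_xy(n = 80, p = 10, signal = 3, noise = 2, seed = 33)
  sel2 <- sequential_forward_selection(d2$X, d2$y, max_k = 5, tol = 0,
                                       seed = 3)
  expect_true(all(diff(sel2$trace$score) >= -1e-12))
  expect_error(sequential_forward_selection(d$X, rep(1, 50)), "zero variance")
})

test_that("the closed-form lr scorer equals brute-force CV refits", {
  d <- make_xy(n = 40, p = 8, signal = 2, noise = 3, seed = 40)
  folds <- gaitrait:::make_folds(40, 5, seed = 4)
  S <- c(3L, 5L)
  fast <- gaitrait:::sfs_score_lr(d$X, d$y, S, folds)
  for (j in setdiff(1:8, S)) {
    pred <- numeric(40)
    for (f in 1:5) {
      te <- folds == f
      df_tr <- data.frame(y = d$y[!te], d$X[!te, c(S, j)])
      fit <- lm(y ~ ., data = df_tr)
      pred[te] <- predict(fit, data.frame(d$X[te, c(S, j), drop = FALSE]))
    }
    expect_equal(fast[j], cor(pred, d$y), tolerance = 1e-10)
  }
  expect_true(all(is.na(fast[S])))
})

test_that("the seven algorithms fit, predict deterministically, and lr is exact OLS", {
  set.seed(23)
  n <- 40
  X <- cbind(x1 = rnorm(n))
  y <- 2 * X[, 1] + 1
  m <- trait_model(X, y, algorithm = "lr", select = FALSE)
  cf <- coef(m)
  # standardized-scale OLS maps back to slope 2, intercept 1 exactly
  slope <- cf[["x1"]] / m$standardization$sd[["x1"]]
  expect_equal(slope, 2, tolerance = 1e-8)
  expect_equal(cf[["(Intercept)"]] - slope * m$standardization$mean[["x1"]], 1,
               tolerance = 1e-8)
  expect_equal(unname(predict(m, X)), unname(y), tolerance = 1e-8)
  expect_equal(unname(residuals(m)), rep(0, n), tolerance = 1e-8)
  # every algorithm runs and repeated prediction is identical
  Xp <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  yp <- Xp[, 1] - 0.5 * Xp[, 2] + rnorm(n, sd = 0.2)
  for (alg in c("gp", "lr", "rfr", "svr_linear", "svr_poly", "svr_rbf",
                "svr_sigmoid")) {
    mm <- trait_model(Xp, yp, algorithm = alg, select = FALSE, seed = 11)
    p1 <- predict(mm, Xp); p2 <- predict(mm, Xp)
    expect_identical(p1, p2)
    expect_length(p1, n)
  }
  # random forest refit with the same seed gives identical predictions
  r1 <- trait_model(Xp, yp, algorithm = "rfr", select = FALSE, seed = 5)
  r2 <- trait_model(Xp, yp, algorithm = "rfr", select = FALSE, seed = 5)
  expect_identical(predict(r1, Xp), predict(r2, Xp))
})

test_that("the GP interpolates a smooth noiseless 1-feature function", {
  x <- seq(-2, 2, length.out = 80)
  X <- cbind(x1 = x)
  y <- sin(x)
  m <- trait_model(X, y, algorithm = "gp", select = FALSE)
  expect_lt(max(abs(predict(m, X) - y)), 1e-2)
})

test_that("cross-validation scores pooled out-of-fold predictions", {
  d <- make_xy(n = 50, p = 6, signal = 2)
  ev <- cross_validate(d$X, d$y, algorithm = "lr", k = 10, seed = 6,
                       select = FALSE)
  expect_equal(ev$r_all, 1, tolerance = 1e-6)
  expect_lt(ev$mse, 1e-10)
  # folds partition the participants
  expect_equal(sort(unique(ev$predictions$fold)), 1:10)
  expect_equal(tabulate(ev$predictions$fold), rep(5L, 10))
  # constant predictor baseline: MSE equals the population variance of y
  base <- mean((d$y - mean(d$y))^2)
  set.seed(1); ynull <- sample(d$y)
  evn <- cross_validate(d$X, ynull, algorithm = "lr", k = 10, seed = 6,
                        select = TRUE, max_k = 1)
  expect_lt(abs(evn$r_all), 0.6)  # null data cannot be predicted well
  expect_gt(evn$mse, 0.3 * base)
})

test_that("pooled r is invariant to fold seed and positive affine y-rescaling", {
  d <- make_xy(n = 60, p = 5, signal = 1, noise = 2, seed = 50)
  r1 <- cross_validate(d$X, d$y, select = FALSE, seed = 1)$r_all
  r2 <- cross_validate(d$X, 10 + 2.5 * d$y, select = FALSE, seed = 1)$r_all
  expect_equal(r1, r2, tolerance = 1e-10)
  r3 <- cross_validate(d$X, d$y, select = FALSE, seed = 99)$r_all
  expect_equal(r1, r3, tolerance = 0.15)  # same data, different partition
})

test_that("subgroup correlations are reported and small groups warn to NA", {
  d <- make_xy(n = 40, p = 4, signal = 1, noise = 1, seed = 60)
  grp <- rep(c("male", "female"), 20)
  ev <- cross_validate(d$X, d$y, select = FALSE, seed = 2, subgroups = grp)
  expect_named(ev$r_subgroups, c("female", "male"))
  expect_true(all(abs(ev$r_subgroups) <= 1))
  grp2 <- c(rep("big", 38), "tiny", "tiny")
  expect_warning(ev2 <- cross_validate(d$X, d$y, select = FALSE, seed = 2,
                                       subgroups = grp2), "fewer than 3")
  expect_true(is.na(ev2$r_subgroups[["tiny"]]))
})

test_that("models survive serialization with identical predictions", {
  d <- make_xy(n = 30, p = 5, signal = 4, noise = 0.5, seed = 70)
  m <- trait_model(d$X, d$y, algorithm = "svr_rbf", select = FALSE, seed = 3)
  f <- withr::local_tempfile(fileext = ".rds")
  write_trait_model(m, f)
  m2 <- read_trait_model(f)
  expect_identical(predict(m, d$X), predict(m2, d$X))
  expect_error(predict(m, d$X[, 1:3]), "lacks")
})
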