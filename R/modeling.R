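# Modeling: feature standardization, sequential forward selection (SFS),
# the seven regression algorithms, and 10-fold cross-validated evaluation
# with pooled-prediction Pearson r, MSE and subgroup correlations.

ALGORITHMS <- c("gp", "lr", "rfr", "svr_linear", "svr_poly", "svr_rbf",
                "svr_sigmoid")

#' Standardize a feature table
#'
#' Z-scores every column. In fitting mode (no `params`) the means and SDs
#' come from the data and zero-variance columns are dropped with a warning;
#' in transform mode the supplied parameters are applied unchanged.
#'
#' @param features Numeric matrix or data.frame, features in columns.
#' @param params Optional list with `mean` and `sd` named vectors, as
#'   returned in the `params` component; supplying it switches to
#'   transform-only mode.
#' @return A list with `features` (standardized matrix) and `params`.
#' @export
standardize_features <- function(features, params = NULL) {
  X <- as.matrix(features)
  if (is.null(params)) {
    mu <- colMeans(X)
    sdev <- apply(X, 2, stats::sd)
    # near-zero spread (numerical dust on structurally constant series)
    # would be amplified into pure noise by the z-scoring
    drop <- sdev <= 1e-8 | !is.finite(sdev)
    if (any(drop)) {
      warning("dropping ", sum(drop), " zero-variance feature(s): ",
              paste(utils::head(colnames(X)[drop], 5), collapse = ", "),
              if (sum(drop) > 5) ", ..." else "")
      X <- X[, !drop, drop = FALSE]
      mu <- mu[!drop]; sdev <- sdev[!drop]
    }
    params <- list(mean = mu, sd = sdev)
  } else {
    missing_f <- setdiff(names(params$mean), colnames(X))
    if (length(missing_f) > 0L)
      stop("feature table lacks column(s): ",
           paste(utils::head(missing_f, 5), collapse = ", "))
    X <- X[, names(params$mean), drop = FALSE]
  }
  Z <- sweep(sweep(X, 2, params$mean), 2, params$sd, "/")
  list(features = Z, params = params)
}

# seeded shuffled k-fold assignment
make_folds <- function(n, k, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample(rep_len(seq_len(k), n))
}

pearson_r <- function(a, b) {
  if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) return(NA_real_)
  stats::cor(a, b)
}

# two-sided p-value for a Pearson correlation via the t transform (n-2 df)
cor_pvalue <- function(r, n) {
  if (is.na(r) || n < 3) return(NA_real_)
  tt <- r * sqrt((n - 2) / max(1e-300, 1 - r^2))
  2 * stats::pt(-abs(tt), df = n - 2)
}

# ---- fast exact OLS scorer for SFS -----------------------------------------
# For a current feature set S and every candidate feature j at once, computes
# the pooled k-fold CV predictions of the OLS model on S + {j} using block
# matrix identities (Schur complement of the bordered Gram matrix), so each
# SFS step costs a handful of matrix products rather than p * k model fits.
sfs_score_lr <- function(X, y, S, folds) {
  n <- nrow(X); p <- ncol(X)
  preds <- matrix(NA_real_, n, p)
  for (f in sort(unique(folds))) {
    te <- folds == f; tr <- !te
    Z <- cbind(1, X[tr, S, drop = FALSE])            # n_tr x m
    A <- crossprod(Z)
    Ainv <- tryCatch(solve(A), error = function(e) NULL)
    if (is.null(Ainv)) return(NULL)                  # caller falls back
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    B <- crossprod(Z, Xtr)                           # m x p
    cj <- colSums(Xtr^2)
    qj <- as.vector(crossprod(Xtr, y[tr]))
    r0 <- as.vector(crossprod(Z, y[tr]))
    M <- Ainv %*% B                                  # m x p
    s <- cj - colSums(B * M)                         # Schur complements
    u <- as.vector(Ainv %*% r0)
    beta_last <- (qj - colSums(B * u)) / s
    bad <- !is.finite(beta_last) | s < 1e-8
    beta_last[bad] <- 0
    m <- nrow(M)
    BH <- matrix(u, m, p) - M * rep(beta_last, each = m)
    Zte <- cbind(1, X[te, S, drop = FALSE])
    P <- Zte %*% BH + Xte * rep(beta_last, each = nrow(Xte))
    P[, bad] <- NA_real_
    preds[te, ] <- P
  }
  # column-wise Pearson r of pooled out-of-fold predictions against y
  ok <- colSums(is.na(preds)) == 0L
  r <- rep(NA_real_, p)
  if (any(ok)) {
    Pc <- scale(preds[, ok, drop = FALSE], scale = FALSE)
    yc <- y - mean(y)
    num <- as.vector(crossprod(Pc, yc))
    den <- sqrt(colSums(Pc^2) * sum(yc^2))
    r[ok] <- ifelse(den < 1e-12, NA_real_, num / den)
  }
  r
}

# generic (any-algorithm) pooled CV r of a fixed feature set
cv_score_set <- function(X, y, S, folds, algorithm, seed) {
  n <- nrow(X)
  pred <- numeric(n)
  for (f in sort(unique(folds))) {
    te <- folds == f; tr <- !te
    std <- standardize_features(X[tr, S, drop = FALSE])
    fit <- fit_algorithm(std$features, y[tr], algorithm, seed = seed)
    Zte <- standardize_features(X[te, S, drop = FALSE], std$params)$features
    pred[te] <- predict_algorithm(fit, Zte)
  }
  pearson_r(pred, y)
}

#' Sequential forward feature selection
#'
#' Greedy forward selection maximizing the pooled k-fold cross-validated
#' Pearson correlation between out-of-fold predictions and the trait score.
#' Stops when the best improvement falls below `tol` or `max_k` features are
#' selected. Ties break toward the smaller canonical feature index; the
#' fold assignment (and hence the whole trace) is deterministic given
#' `seed`. For `algorithm = "lr"` candidate scoring uses an exact
#' closed-form OLS update, making the scan over all 2,472 candidates cheap;
#' other algorithms are scored by refitting.
#'
#' @param X Numeric feature matrix (participants x features).
#' @param y Trait scores.
#' @param algorithm One of `gp`, `lr`, `rfr`, `svr_linear`, `svr_poly`,
#'   `svr_rbf`, `svr_sigmoid`.
#' @param k_folds Number of CV folds used for scoring (default 10).
#' @param max_k Maximum number of features to select.
#' @param tol Minimum score improvement to accept a step.
#' @param seed RNG seed for the fold assignment.
#' @return A list with `features` (ordered selected names) and `trace`
#'   (data.frame `feature`, `score` per accepted step).
#' @export
sequential_forward_selection <- function(X, y, algorithm = "lr", k_folds = 10,
                                         max_k = 10, tol = 0.02, seed = 1L) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  X <- as.matrix(X)
  n <- nrow(X)
  if (stats::sd(y) < 1e-12) stop("trait scores have zero variance")
  if (n < 2 * k_folds) k_folds <- max(2L, floor(n / 2))
  if (max_k < 1) stop("max_k must be at least 1")
  folds <- make_folds(n, k_folds, seed)
  S <- integer(0)
  best_score <- -Inf
  trace <- list()
  nm <- colnames(X)
  repeat {
    if (algorithm == "lr") {
      r <- sfs_score_lr(X, y, S, folds)
      if (!is.null(r)) r[S] <- NA_real_
    } else r <- NULL
    if (is.null(r)) {
      r <- rep(NA_real_, ncol(X))
      for (j in setdiff(seq_len(ncol(X)), S))
        r[j] <- tryCatch(cv_score_set(X, y, c(S, j), folds, algorithm, seed),
                         error = function(e) NA_real_)
    }
    if (all(is.na(r))) break
    j_best <- which.max(r)   # which.max returns the first (smallest index) tie
    sc <- r[j_best]
    improvement <- sc - if (is.finite(best_score)) best_score else -Inf
    if (length(S) > 0L && (is.na(sc) || improvement < tol)) break
    S <- c(S, j_best)
    best_score <- sc
    trace[[length(trace) + 1L]] <- data.frame(feature = nm[j_best], score = sc,
                                              stringsAsFactors = FALSE)
    if (length(S) >= max_k) break
  }
  if (length(S) == 0L) stop("no feature could be scored")
  list(features = nm[S], trace = do.call(rbind, trace))
}

# ---- the seven regressors ---------------------------------------------------

fit_algorithm <- function(Z, y, algorithm, seed = 1L,
                          hyper = list(gp_sigma = NULL, gp_var = 0.01,
                                       rfr_trees = 100L, svr_eps = 0.1,
                                       svr_cost = 1.0, svr_degree = 3L)) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  Z <- as.matrix(Z)
  if (nrow(Z) < 2L) stop("need at least 2 observations to fit")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  d <- ncol(Z)
  obj <- switch(
    algorithm,
    lr = {
      f <- stats::lm.fit(cbind(`(Intercept)` = 1, Z), y)
      list(coef = f$coefficients, fitted = f$fitted.values)
    },
    gp = {
      # RBF kernel + white-noise term (variance floored at 1e-6), with
      # target-mean normalization
      sigma <- if (is.null(hyper$gp_sigma)) 1 / (2 * d) else hyper$gp_sigma
      var_n <- max(1e-6, hyper$gp_var)
      ym <- mean(y)
      g <- kernlab::gausspr(x = Z, y = y - ym, type = "regression",
                            kernel = "rbfdot", kpar = list(sigma = sigma),
                            var = var_n, scaled = FALSE, fit = FALSE)
      list(model = g, ymean = ym)
    },
    rfr = randomForest::randomForest(x = Z, y = y,
                                     ntree = hyper$rfr_trees),
    {
      kern <- c(svr_linear = "linear", svr_poly = "polynomial",
                svr_rbf = "radial", svr_sigmoid = "sigmoid")[[algorithm]]
      mean_var <- mean(apply(Z, 2, stats::var))
      gamma <- if (mean_var > 1e-12) 1 / (d * mean_var) else 1 / d
      e1071::svm(x = Z, y = y, type = "eps-regression", kernel = kern,
                 epsilon = hyper$svr_eps, cost = hyper$svr_cost,
                 gamma = gamma, degree = hyper$svr_degree, scale = FALSE)
    })
  list(algorithm = algorithm, obj = obj, d = d)
}

predict_algorithm <- function(fit, Z) {
  Z <- as.matrix(Z)
  switch(
    fit$algorithm,
    lr = as.vector(cbind(1, Z) %*% fit$obj$coef),
    gp = as.vector(kernlab::predict(fit$obj$model, Z)) + fit$obj$ymean,
    rfr = as.vector(stats::predict(fit$obj, Z)),
    {
      if (is.null(colnames(Z)))
        colnames(Z) <- paste0("V", seq_len(ncol(Z)))
      as.vector(stats::predict(fit$obj, Z))
    })
}

# ---- the user-facing model --------------------------------------------------

#' Fit a gait trait-prediction model
#'
#' The package's central fitting function: standardizes the feature table,
#' optionally runs sequential forward selection, and fits one of the seven
#' regression algorithms, returning a `trait_model` with `print`,
#' `summary`, `coef`, `predict` and `residuals` methods.
#'
#' @param features Numeric matrix/data.frame of gait features (participants
#'   in rows, canonical feature names as columns).
#' @param scores Numeric trait scores, one per row of `features`.
#' @param algorithm One of `"gp"`, `"lr"`, `"rfr"`, `"svr_linear"`,
#'   `"svr_poly"`, `"svr_rbf"`, `"svr_sigmoid"`.
#' @param select If `TRUE` (default) run [sequential_forward_selection()];
#'   if `FALSE` use all features (or `features_use` when given).
#' @param features_use Optional explicit feature-name list overriding
#'   selection.
#' @param max_k,tol,k_folds Selection controls, see
#'   [sequential_forward_selection()].
#' @param seed Integer seed controlling fold assignment and any stochastic
#'   fit (random forest).
#' @return An object of class `trait_model`.
#' @export
trait_model <- function(features, scores, algorithm = "lr", select = TRUE,
                        features_use = NULL, max_k = 10, tol = 0.02,
                        k_folds = 10, seed = 1L) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  X <- as.matrix(features)
  if (nrow(X) != length(scores))
    stop("features and scores disagree on the number of participants")
  std <- standardize_features(X)
  sel_trace <- NULL
  if (!is.null(features_use)) {
    missing_f <- setdiff(features_use, colnames(std$features))
    if (length(missing_f) > 0L)
      stop("unknown feature name(s): ", paste(missing_f, collapse = ", "))
    selected <- features_use
  } else if (select) {
    sel <- sequential_forward_selection(std$features, scores,
                                        algorithm = algorithm,
                                        k_folds = k_folds, max_k = max_k,
                                        tol = tol, seed = seed)
    selected <- sel$features
    sel_trace <- sel$trace
  } else selected <- colnames(std$features)
  keep <- match(selected, names(std$params$mean))
  params <- list(mean = std$params$mean[keep], sd = std$params$sd[keep])
  Z <- std$features[, selected, drop = FALSE]
  fit <- fit_algorithm(Z, scores, algorithm, seed = seed)
  fitted_vals <- predict_algorithm(fit, Z)
  structure(list(algorithm = algorithm, selected_features = selected,
                 standardization = params, fit = fit,
                 selection_trace = sel_trace, seed = as.integer(seed),
                 y = scores, fitted = fitted_vals,
                 n = nrow(X)),
            class = "trait_model")
}

#' @export
print.trait_model <- function(x, ...) {
  cat(sprintf("<trait_model> %s on %d feature(s), n = %d\n",
              x$algorithm, length(x$selected_features), x$n))
  cat("  features:", paste(utils::head(x$selected_features, 5), collapse = ", "),
      if (length(x$selected_features) > 5) "..." else "", "\n")
  cat(sprintf("  training r = %.3f\n", pearson_r(x$fitted, x$y)))
  invisible(x)
}

#' @export
summary.trait_model <- function(object, ...) {
  r <- pearson_r(object$fitted, object$y)
  out <- list(algorithm = object$algorithm,
              n = object$n,
              selected_features = object$selected_features,
              selection_trace = object$selection_trace,
              training_r = r,
              training_p = cor_pvalue(r, object$n),
              training_mse = mean((object$fitted - object$y)^2))
  class(out) <- "summary.trait_model"
  out
}

#' @export
print.summary.trait_model <- function(x, ...) {
  cat(sprintf("Trait model (%s), n = %d\n", x$algorithm, x$n))
  cat(sprintf("  training r = %.3f (p = %.3g), MSE = %.3f\n",
              x$training_r, x$training_p, x$training_mse))
  if (!is.null(x$selection_trace)) {
    cat("  selection trace:\n")
    print(x$selection_trace, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.trait_model <- function(object, ...) {
  if (object$algorithm != "lr")
    stop("coefficients are defined only for the linear-regression model")
  object$fit$obj$coef
}

#' @export
residuals.trait_model <- function(object, ...) object$y - object$fitted

#' Predict trait scores from gait features
#'
#' Standardizes the supplied features with the parameters stored at fit
#' time (never refitted) and evaluates the fitted model. Deterministic.
#'
#' @param object A [trait_model()].
#' @param features Feature table containing at least the selected features.
#' @param ... Unused.
#' @return Numeric vector of predicted scores.
#' @export
predict.trait_model <- function(object, features, ...) {
  X <- as.matrix(features)
  missing_f <- setdiff(object$selected_features, colnames(X))
  if (length(missing_f) > 0L)
    stop("feature table lacks selected feature(s): ",
         paste(missing_f, collapse = ", "))
  Z <- standardize_features(X[, object$selected_features, drop = FALSE],
                            object$standardization)$features
  predict_algorithm(object$fit, Z)
}

#' Plot observed versus fitted trait scores
#' @param x A [trait_model()].
#' @param ... Passed to [plot()].
#' @export
plot.trait_model <- function(x, ...) {
  plot(x$fitted, x$y, xlab = "fitted score", ylab = "observed score",
       main = sprintf("%s: training r = %.2f", x$algorithm,
                      pearson_r(x$fitted, x$y)), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Save / load a fitted trait model
#'
#' Single-file serialized bundle carrying the algorithm, selected features,
#' standardization parameters, fitted state and seed. Round-tripped models
#' produce identical predictions.
#'
#' @param model A [trait_model()].
#' @param path File path.
#' @return `path` (write) or the restored `trait_model` (read).
#' @export
write_trait_model <- function(model, path) {
  stopifnot(inherits(model, "trait_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_trait_model
#' @export
read_trait_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "trait_model")) stop(path, " is not a trait model bundle")
  model
}

# ---- cross-validated evaluation --------------------------------------------

#' Cross-validated evaluation of the pipeline
#'
#' Seeded shuffled k-fold partition; per fold, features are standardized on
#' the training part only, sequential forward selection is run (inside each
#' training fold by default; with `paper_mode = TRUE` selection runs once on
#' all data before CV, replicating the common — leak-prone — protocol), the
#' model is fitted and the held-out fold predicted. Pooled out-of-fold
#' predictions are scored once: Pearson r (overall and per subgroup) and
#' MSE.
#'
#' @param features Feature matrix (participants x features).
#' @param scores Trait scores.
#' @param algorithm One of the seven algorithms.
#' @param k Number of folds (default 10).
#' @param seed Seed for fold assignment and stochastic fits.
#' @param subgroups Optional character vector of subgroup labels (e.g. sex)
#'   for per-subgroup correlations; groups with fewer than 3 members are
#'   reported as `NA` with a warning.
#' @param paper_mode If `TRUE`, run selection once on all data before CV.
#' @param select If `FALSE`, skip selection and use all features.
#' @param max_k,tol,sfs_folds Selection controls.
#' @return An object of class `gait_eval`: pooled predictions, `r_all` (+
#'   p-value), per-subgroup r, `mse`, fold assignment and selection traces.
#' @export
cross_validate <- function(features, scores, algorithm = "lr", k = 10,
                           seed = 1L, subgroups = NULL, paper_mode = FALSE,
                           select = TRUE, max_k = 10, tol = 0.02,
                           sfs_folds = 10) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  X <- as.matrix(features)
  n <- nrow(X)
  if (n < k) stop("need at least as many participants as folds")
  if (length(scores) != n) stop("scores must match the feature rows")
  folds <- make_folds(n, k, seed)
  pre_selected <- NULL
  traces <- list()
  if (select && paper_mode) {
    std_all <- standardize_features(X)
    sel <- sequential_forward_selection(std_all$features, scores,
                                        algorithm = algorithm,
                                        k_folds = sfs_folds, max_k = max_k,
                                        tol = tol, seed = seed)
    pre_selected <- sel$features
    traces[["all_data"]] <- sel$trace
  }
  pred <- numeric(n)
  for (f in seq_len(k)) {
    te <- folds == f; tr <- !te
    std <- standardize_features(X[tr, , drop = FALSE])
    if (!select) {
      selected <- colnames(std$features)
    } else if (paper_mode) {
      selected <- intersect(pre_selected, colnames(std$features))
    } else {
      sel <- sequential_forward_selection(std$features, scores[tr],
                                          algorithm = algorithm,
                                          k_folds = sfs_folds, max_k = max_k,
                                          tol = tol, seed = seed + f)
      selected <- sel$features
      traces[[paste0("fold_", f)]] <- sel$trace
    }
    fit <- fit_algorithm(std$features[, selected, drop = FALSE], scores[tr],
                         algorithm, seed = seed + f)
    Zte <- standardize_features(X[te, , drop = FALSE],
                                std$params)$features[, selected, drop = FALSE]
    pred[te] <- predict_algorithm(fit, Zte)
  }
  r_all <- pearson_r(pred, scores)
  r_sub <- NULL
  if (!is.null(subgroups)) {
    r_sub <- sapply(sort(unique(subgroups)), function(g) {
      idx <- subgroups == g
      if (sum(idx) < 3L) {
        warning("subgroup '", g, "' has fewer than 3 members; r set to NA")
        return(NA_real_)
      }
      pearson_r(pred[idx], scores[idx])
    })
  }
  structure(list(predictions = data.frame(
    participant = if (!is.null(rownames(X))) rownames(X) else seq_len(n),
    score = scores, predicted = pred, fold = folds,
    subgroup = if (is.null(subgroups)) NA_character_ else subgroups,
    stringsAsFactors = FALSE),
    r_all = r_all, p_all = cor_pvalue(r_all, n),
    r_subgroups = r_sub,
    mse = mean((pred - scores)^2),
    algorithm = algorithm, k = k, seed = as.integer(seed),
    paper_mode = paper_mode, selection_traces = traces),
    class = "gait_eval")
}

#' @export
print.gait_eval <- function(x, ...) {
  cat(sprintf("<gait_eval> %s, %d-fold CV, n = %d%s\n", x$algorithm, x$k,
              nrow(x$predictions),
              if (x$paper_mode) " (selection on all data)" else ""))
  cat(sprintf("  pooled r = %.3f (p = %.3g), MSE = %.3f\n",
              x$r_all, x$p_all, x$mse))
  if (!is.null(x$r_subgroups))
    for (g in names(x$r_subgroups))
      cat(sprintf("  r[%s] = %.3f\n", g, x$r_subgroups[[g]]))
  invisible(x)
}

#' @export
plot.gait_eval <- function(x, ...) {
  plot(x$predictions$predicted, x$predictions$score,
       xlab = "out-of-fold predicted score", ylab = "observed score",
       main = sprintf("%s: pooled CV r = %.2f", x$algorithm, x$r_all), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
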