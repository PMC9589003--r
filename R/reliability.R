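# Odd-even split-half reliability of model predictions, and
# indicator-level weight analysis (including the distances-versus-angles
# comparison).

#' Split a segment into odd- and even-frame halves
#'
#' Frames at 1-based positions 1, 3, 5, ... form the odd half and positions
#' 2, 4, ... the even half (75 frames split 38/37). Each half is a valid
#' [gait_segment()] with the fps halved in metadata. At least 64 frames are
#' required so both halves support a 5-level wavelet decomposition.
#'
#' @param segment A [gait_segment()].
#' @return A list with components `odd` and `even`.
#' @export
split_half <- function(segment) {
  stopifnot(inherits(segment, "gait_segment"))
  n <- nrow(segment$channels)
  if (n < 64L)
    stop("split-half needs at least 64 frames (both halves must support a ",
         "5-level DWT); got ", n)
  odd_idx <- seq(1L, n, 2L)
  even_idx <- seq(2L, n, 2L)
  list(
    odd = gait_segment(segment$channels[odd_idx, , drop = FALSE],
                       fps = segment$fps / 2,
                       participant_id = segment$participant_id),
    even = gait_segment(segment$channels[even_idx, , drop = FALSE],
                        fps = segment$fps / 2,
                        participant_id = segment$participant_id)
  )
}

#' Odd-even split-half reliability of model predictions
#'
#' For every participant, the full feature vector is recomputed
#' independently on the odd-frame and even-frame halves of the segment;
#' both halves are predicted with the unmodified full-segment model, and
#' the reliability is the Pearson correlation between the two prediction
#' vectors across participants.
#'
#' @param model A fitted [trait_model()].
#' @param segments A list of per-participant [gait_segment()] objects.
#' @return An object of class `reliability_report`: `r_split`, its p-value,
#'   `n`, `half_sizes`, and the two prediction vectors `pred_odd`,
#'   `pred_even`.
#' @export
split_half_reliability <- function(model, segments) {
  stopifnot(inherits(model, "trait_model"))
  if (inherits(segments, "gait_segment")) segments <- list(segments)
  feats_o <- list(); feats_e <- list(); ids <- character(0)
  half_sizes <- NULL
  for (seg in segments) {
    res <- tryCatch({
      halves <- split_half(seg)
      list(o = segment_features(halves$odd), e = segment_features(halves$even),
           sizes = c(nrow(halves$odd$channels), nrow(halves$even$channels)))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("dropping participant '", seg$participant_id, "': ",
              conditionMessage(res))
      next
    }
    feats_o[[length(feats_o) + 1L]] <- res$o
    feats_e[[length(feats_e) + 1L]] <- res$e
    ids <- c(ids, seg$participant_id)
    half_sizes <- res$sizes
  }
  if (length(ids) < 3L)
    stop("fewer than 3 participants survived half-segment feature extraction")
  Fo <- do.call(rbind, feats_o); Fe <- do.call(rbind, feats_e)
  rownames(Fo) <- rownames(Fe) <- ids
  po <- predict(model, Fo)
  pe <- predict(model, Fe)
  r <- pearson_r(po, pe)
  structure(list(r_split = r, p = cor_pvalue(r, length(ids)),
                 n = length(ids), half_sizes = half_sizes,
                 pred_odd = po, pred_even = pe, participant_id = ids),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("<reliability_report> odd-even split-half r = %.3f (p = %.3g), n = %d\n",
              x$r_split, x$p, x$n))
  cat(sprintf("  half sizes: %d / %d frames\n", x$half_sizes[1], x$half_sizes[2]))
  invisible(x)
}

#' Aggregate linear-model weights to the indicator level
#'
#' Each selected feature's absolute standardized coefficient is added to
#' the aggregate of its source indicator (angle indicators A0-A9, distance
#' indicators D1-D13, and raw/diff/wavelet channel groups, via the feature
#' dictionary). Indicators with no selected feature appear with weight 0.
#' Defined only for the linear-regression model, whose coefficients are the
#' weights. With `agg = "mean"` the per-indicator mean replaces the sum.
#'
#' @param model A [trait_model()] with `algorithm = "lr"`.
#' @param agg `"sum"` (default) or `"mean"`.
#' @return A data.frame (`weight_table`) with columns `indicator`, `group`
#'   (`angle`, `distance`, `other`) and `weight`.
#' @export
aggregate_weights <- function(model, agg = c("sum", "mean")) {
  stopifnot(inherits(model, "trait_model"))
  agg <- match.arg(agg)
  if (model$algorithm != "lr")
    stop("indicator weights are defined only for the linear model")
  dict <- feature_dictionary()
  cf <- coef(model)
  cf <- cf[setdiff(names(cf), "(Intercept)")]
  cf[is.na(cf)] <- 0
  idx <- match(names(cf), dict$name)
  if (anyNA(idx)) stop("model features missing from the feature dictionary")
  sel <- data.frame(indicator = dict$indicator[idx], w = abs(cf))
  base <- unique(dict[, c("indicator", "group")])
  agg_fun <- if (agg == "sum") sum else mean
  got <- tapply(sel$w, sel$indicator, agg_fun)
  base$weight <- as.numeric(ifelse(base$indicator %in% names(got),
                                   got[base$indicator], 0))
  base <- base[order(match(base$group, c("angle", "distance", "other")),
                     base$indicator), ]
  rownames(base) <- NULL
  class(base) <- c("weight_table", "data.frame")
  base
}

#' Compare distance and angle indicator weights
#'
#' Pooled-variance two-sample t-test of the 13 distance indicator
#' aggregates against the 10 angle indicator aggregates (df = 13 + 10 - 2 =
#' 21 structurally), two-sided. Group SDs use the n-1 divisor (the pooled
#' t-test convention).
#'
#' @param wt A `weight_table` from [aggregate_weights()].
#' @return A list: `t`, `df`, `p`, `mean_dist`, `sd_dist`, `mean_angle`,
#'   `sd_angle`.
#' @export
compare_indicator_groups <- function(wt) {
  stopifnot(inherits(wt, "weight_table") || is.data.frame(wt))
  dist_w <- wt$weight[wt$group == "distance"]
  ang_w <- wt$weight[wt$group == "angle"]
  if (length(dist_w) != 13L || length(ang_w) != 10L)
    stop("weight table must contain the 13 distance and 10 angle indicators")
  if (stats::var(dist_w) + stats::var(ang_w) <= 0)
    stop("zero pooled variance: indicator weights are all identical")
  tt <- stats::t.test(dist_w, ang_w, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value,
       mean_dist = mean(dist_w), sd_dist = stats::sd(dist_w),
       mean_angle = mean(ang_w), sd_angle = stats::sd(ang_w))
}
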