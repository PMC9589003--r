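# Time-domain gait features: 10 summary statistics over four series
# families (48 raw channels, 48 first-difference channels, 26 inter-joint
# distance channels, 10 inter-joint angle series) = 1,320 features.

#' Inter-frame difference of a segment
#'
#' Per channel, `out[k] = in[k+1] - in[k]`: the first difference encoding
#' the motion between adjacent frames.
#'
#' @param segment A [gait_segment()] with at least 2 frames.
#' @return A numeric matrix with one row fewer than the segment and the same
#'   48 columns.
#' @export
frame_difference <- function(segment) {
  stopifnot(inherits(segment, "gait_segment"))
  ch <- segment$channels
  if (nrow(ch) < 2L) stop("need at least 2 frames to difference")
  diff(ch)
}

# column index of joint j's x (or y) channel within the 48-channel matrix
.chan_col <- function(j, axis) {
  pos <- match(j, RETAINED_JOINTS)
  if (is.na(pos)) stop("joint ", j, " is not in the retained joint set")
  2L * (pos - 1L) + if (axis == "x") 1L else 2L
}

#' Inter-joint angle series
#'
#' The angle at vertex `b` between rays `b -> a` and `b -> c`, per frame, in
#' radians within \[0, pi\]. The ten canonical indicators (A0-A9) cover head
#' tilt, shoulders, elbows, hips and knees.
#'
#' @param segment A [gait_segment()].
#' @param indicator Either an indicator id (`"A0"` ... `"A9"`) or an integer
#'   triple `c(a, b, c)` of BODY25 joint indices with vertex `b`.
#' @return Numeric vector of per-frame angles (radians).
#' @export
angle_series <- function(segment, indicator) {
  stopifnot(inherits(segment, "gait_segment"))
  if (is.character(indicator)) {
    triple <- ANGLE_TRIPLES[[indicator]]
    if (is.null(triple)) stop("unknown angle indicator: ", indicator)
  } else triple <- as.integer(indicator)
  if (length(triple) != 3L) stop("an angle indicator is a joint triple")
  ch <- segment$channels
  ax <- ch[, .chan_col(triple[1], "x")] - ch[, .chan_col(triple[2], "x")]
  ay <- ch[, .chan_col(triple[1], "y")] - ch[, .chan_col(triple[2], "y")]
  cx <- ch[, .chan_col(triple[3], "x")] - ch[, .chan_col(triple[2], "x")]
  cy <- ch[, .chan_col(triple[3], "y")] - ch[, .chan_col(triple[2], "y")]
  na <- sqrt(ax^2 + ay^2); nc <- sqrt(cx^2 + cy^2)
  degen <- which(na < 1e-12 | nc < 1e-12)
  if (length(degen) > 0L)
    stop("degenerate geometry (zero-length limb vector) at frame ",
         degen[1], " for indicator (",
         paste(triple, collapse = ","), ")")
  cosv <- pmin(1, pmax(-1, (ax * cx + ay * cy) / (na * nc)))
  acos(cosv)
}

#' Inter-joint distance series
#'
#' Per frame, the transverse `|x_a - x_b|` and longitudinal `|y_a - y_b|`
#' distances between a joint pair. The thirteen canonical indicators
#' (D1-D13) cover head, arm, leg and stride swing amplitudes, giving 26
#' channels in total.
#'
#' @param segment A [gait_segment()].
#' @param indicator Either an indicator id (`"D1"` ... `"D13"`) or an
#'   integer pair `c(a, b)` of BODY25 joint indices.
#' @return A two-column matrix (`x`, `y`) of per-frame nonnegative distances.
#' @export
distance_series <- function(segment, indicator) {
  stopifnot(inherits(segment, "gait_segment"))
  if (is.character(indicator)) {
    pair <- DISTANCE_PAIRS[[indicator]]
    if (is.null(pair)) stop("unknown distance indicator: ", indicator)
  } else pair <- as.integer(indicator)
  if (length(pair) != 2L) stop("a distance indicator is a joint pair")
  ch <- segment$channels
  cbind(x = abs(ch[, .chan_col(pair[1], "x")] - ch[, .chan_col(pair[2], "x")]),
        y = abs(ch[, .chan_col(pair[1], "y")] - ch[, .chan_col(pair[2], "y")]))
}

#' The ten time-domain summary statistics of a series
#'
#' Maximum, minimum, mean, median, variance, root mean square, skewness,
#' kurtosis, absolute energy and coefficient of variation. Conventions,
#' frozen here and in the tests: variance is the population variance
#' (divisor n); skewness is `m3 / m2^1.5` and kurtosis the moment-based
#' excess `m4 / m2^2 - 3`, both 0 for a constant series; `abs_energy` is the
#' sum of squares; the variation coefficient is `sd / mean`, 0 when
#' `|mean| < 1e-12`.
#'
#' @param x Numeric vector of length at least 2.
#' @return Named numeric vector of the 10 statistics.
#' @export
#' @examples
#' summary_stats(c(1, 2, 3))["abs_energy"]  # 14
summary_stats <- function(x) {
  n <- length(x)
  if (n < 2L) stop("summary statistics need a series of length >= 2")
  m <- mean(x)
  xc <- x - m
  m2 <- mean(xc^2)
  sumsq <- sum(x^2)
  if (m2 < 1e-24) {
    skew <- 0; kurt <- 0
  } else {
    skew <- mean(xc^3) / m2^1.5
    kurt <- mean(xc^4) / m2^2 - 3
  }
  cv <- if (abs(m) < 1e-12) 0 else sqrt(m2) / m
  c(max = max(x), min = min(x), mean = m, median = stats::median(x),
    variance = m2, rms = sqrt(sumsq / n), skewness = skew, kurtosis = kurt,
    abs_energy = sumsq, variation_coefficient = cv)
}

#' All 1,320 time-domain features of a segment
#'
#' Concatenates, in canonical order, [summary_stats()] over the 48 raw
#' channels, the 48 inter-frame difference channels, the 26 distance
#' channels and the 10 angle series. Names follow
#' `td_{raw|diff}_j{idx}_{x|y}_{stat}`, `td_dist_D{k}_{x|y}_{stat}` and
#' `td_angle_A{k}_{stat}`.
#'
#' @param segment A [gait_segment()].
#' @return Named numeric vector of length 1320.
#' @export
time_domain_features <- function(segment) {
  stopifnot(inherits(segment, "gait_segment"))
  ch <- segment$channels
  dch <- frame_difference(segment)
  blocks <- list()
  raw <- as.vector(apply(ch, 2, summary_stats))
  names(raw) <- as.vector(outer(TIME_STATS, colnames(ch),
                                function(s, c) paste0("td_raw_", c, "_", s)))
  dif <- as.vector(apply(dch, 2, summary_stats))
  names(dif) <- as.vector(outer(TIME_STATS, colnames(ch),
                                function(s, c) paste0("td_diff_", c, "_", s)))
  dist_list <- lapply(names(DISTANCE_PAIRS), function(id) {
    d <- distance_series(segment, id)
    v <- c(summary_stats(d[, "x"]), summary_stats(d[, "y"]))
    names(v) <- c(paste0("td_dist_", id, "_x_", TIME_STATS),
                  paste0("td_dist_", id, "_y_", TIME_STATS))
    v
  })
  ang_list <- lapply(names(ANGLE_TRIPLES), function(id) {
    v <- summary_stats(angle_series(segment, id))
    names(v) <- paste0("td_angle_", id, "_", TIME_STATS)
    v
  })
  out <- c(raw, dif, unlist(dist_list), unlist(ang_list))
  stopifnot(length(out) == 1320L)
  out
}
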