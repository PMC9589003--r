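# Preprocessing: dropout interpolation, face-toward segment selection,
# MidHip re-referencing, binomial Gaussian smoothing, 75-frame
# standardization. Pipeline order is fixed:
# interpolate -> facing-select -> center -> smooth -> standardize.

#' Default preprocessing / pipeline configuration
#'
#' Flat key-value configuration shared by the pipeline functions and the
#' command-line interface. Unknown keys are rejected wherever a config is
#' consumed.
#'
#' @return A named list of defaults.
#' @export
default_config <- function() {
  list(
    fps = 25,
    n_frames = 75L,
    filter.window = 5L,
    filter.weights = c(1, 4, 6, 4, 1) / 16,
    filter.alignment = "forward",   # "forward" (as printed) or "centered"
    min_conf = 0.1,
    facing.window_s = 1.0,
    facing.slope_min = 0.0,
    wavelet.base = "haar",
    wavelet.levels = 5L,
    wavelet.padding = "symmetric-half"
  )
}

merge_config <- function(overrides = list(), base = default_config()) {
  if (length(overrides) == 0L) return(base)
  unknown <- setdiff(names(overrides), names(base))
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  base[names(overrides)] <- overrides
  base
}

#' Interpolate low-confidence keypoint dropouts
#'
#' Joints whose detection confidence falls below `min_conf` are linearly
#' interpolated over time, per coordinate channel; leading/trailing gaps are
#' filled with the nearest valid value. Filled points get confidence
#' `min_conf`.
#'
#' @param seq A [gait_sequence()].
#' @param min_conf Confidence threshold in \[0, 1).
#' @return A `gait_sequence` with no confidence below `min_conf`.
#' @export
interpolate_missing <- function(seq, min_conf = default_config()$min_conf) {
  stopifnot(inherits(seq, "gait_sequence"))
  if (min_conf < 0 || min_conf >= 1) stop("min_conf must lie in [0, 1)")
  bad <- seq$conf < min_conf
  if (!any(bad)) return(seq)
  n <- n_frames(seq)
  frac <- colMeans(bad)
  if (any(frac > 0.5)) {
    jn <- body25_joints()$name[which(frac > 0.5)]
    stop("joint(s) ", paste(jn, collapse = ", "),
         " missing in more than 50% of frames; data quality insufficient")
  }
  x <- seq$x; y <- seq$y; conf <- seq$conf
  t_all <- seq_len(n)
  for (j in which(colSums(bad) > 0L)) {
    ok <- !bad[, j]
    x[!ok, j] <- stats::approx(t_all[ok], x[ok, j], xout = t_all[!ok],
                               rule = 2)$y
    y[!ok, j] <- stats::approx(t_all[ok], y[ok, j], xout = t_all[!ok],
                               rule = 2)$y
    conf[!ok, j] <- min_conf
  }
  gait_sequence(x, y, conf, fps = seq$fps,
                participant_id = seq$participant_id, facing = seq$facing)
}

#' Detect face-toward (approaching-camera) intervals
#'
#' Pose estimation is more accurate when the walker faces the camera, so
#' only approaching segments feed feature extraction. The heuristic: the
#' apparent torso length (Neck to MidHip Euclidean distance), smoothed with
#' a 1-second moving average, grows while the walker approaches. Maximal
#' runs of positive slope longer than `min_len` frames are returned. When
#' the sequence carries `facing` metadata the labels override the heuristic.
#'
#' @param seq A [gait_sequence()].
#' @param min_len Minimum interval length in frames (default: the 75-frame
#'   analysis window).
#' @param window_s Moving-average window in seconds.
#' @param slope_min Minimum per-frame slope of the smoothed torso length for
#'   a frame to count as approaching.
#' @return A list of `c(start, end)` 1-based inclusive frame intervals.
#' @export
detect_facing_segments <- function(seq, min_len = default_config()$n_frames,
                                   window_s = default_config()$facing.window_s,
                                   slope_min = default_config()$facing.slope_min) {
  stopifnot(inherits(seq, "gait_sequence"))
  n <- n_frames(seq)
  if (n < 2 * seq$fps) stop("sequence must be at least 2 s long")
  runs_from_flags <- function(flag) {
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_len
    lapply(which(keep), function(i) c(starts[i], ends[i]))
  }
  if (!is.null(seq$facing))
    return(runs_from_flags(seq$facing == "toward"))
  torso <- sqrt((seq$x[, 2] - seq$x[, 9])^2 + (seq$y[, 2] - seq$y[, 9])^2)
  w <- max(1L, round(window_s * seq$fps))
  sm <- stats::filter(torso, rep(1 / w, w), sides = 2)
  sm <- as.numeric(sm)
  # moving average is NA near edges; carry the nearest value outward
  first_ok <- which(!is.na(sm))[1]
  last_ok <- max(which(!is.na(sm)))
  sm[seq_len(first_ok - 1L)] <- sm[first_ok]
  if (last_ok < n) sm[(last_ok + 1L):n] <- sm[last_ok]
  # slope from a local linear regression over a +-window_s span
  # (Savitzky-Golay first derivative), so frame-level jitter cannot
  # fragment the approach interval
  h <- min(max(2L, 2L * w), (n - 1L) %/% 2L)
  k <- seq(-h, h)
  slope <- as.numeric(stats::filter(sm, rev(k) / sum(k^2), sides = 2))
  first_ok <- which(!is.na(slope))[1]
  last_ok <- max(which(!is.na(slope)))
  slope[seq_len(first_ok - 1L)] <- slope[first_ok]
  if (last_ok < n) slope[(last_ok + 1L):n] <- slope[last_ok]
  flag <- slope > slope_min
  # bridge sub-window negative blips between approach runs (closing)
  r <- rle(flag)
  if (length(r$lengths) > 2L) {
    inner <- 2:(length(r$lengths) - 1L)
    r$values[inner][!r$values[inner] & r$lengths[inner] < w] <- TRUE
    flag <- inverse.rle(r)
  }
  out <- runs_from_flags(flag)
  if (length(out) == 0L)
    stop("no face-toward interval of at least ", min_len, " frames found; ",
         "supply facing labels if the heuristic is unsuitable")
  out
}

#' Re-reference a sequence to the MidHip
#'
#' Subtracts the MidHip (joint 8) coordinates from every joint in every
#' frame, removing camera-relative position and making the skeleton
#' translation-invariant; the now identically-zero MidHip is dropped,
#' leaving the 24 analysis joints.
#'
#' @param seq A [gait_sequence()] (after interpolation; the MidHip must not
#'   be missing).
#' @return A `centered_sequence`: list with `x`, `y` (frames x 24 matrices,
#'   columns named `j00` ... `j24` without `j08`), `fps`, `participant_id`.
#' @export
center_on_midhip <- function(seq) {
  stopifnot(inherits(seq, "gait_sequence"))
  if (any(seq$conf[, MIDHIP + 1L] == 0))
    stop("MidHip is missing in some frames; run interpolate_missing() first")
  keep <- RETAINED_JOINTS + 1L
  x <- seq$x[, keep, drop = FALSE] - seq$x[, MIDHIP + 1L]
  y <- seq$y[, keep, drop = FALSE] - seq$y[, MIDHIP + 1L]
  colnames(x) <- colnames(y) <- sprintf("j%02d", RETAINED_JOINTS)
  structure(list(x = x, y = y, fps = seq$fps,
                 participant_id = seq$participant_id),
            class = "centered_sequence")
}

#' Binomial Gaussian smoothing of a series
#'
#' The 5-point binomial low-pass filter: with the default kernel
#' c = \[1, 4, 6, 4, 1\]/16,
#' `Out[i] = (In[i] + 4 In[i+1] + 6 In[i+2] + 4 In[i+3] + In[i+4]) / 16`.
#' The window is forward-looking with no padding, so the output is
#' `window - 1` samples shorter than the input. `alignment = "centered"`
#' shifts the same output to the window centres (a 2-frame phase change
#' only; values are identical).
#'
#' @param series Numeric vector of length at least `length(weights)`.
#' @param weights Kernel weights; must sum to 1.
#' @param alignment `"forward"` or `"centered"`.
#' @return Numeric vector of length `length(series) - length(weights) + 1`.
#' @export
#' @examples
#' gaussian_smooth(c(0, 0, 0, 0, 16, 0, 0, 0, 0))  # impulse -> kernel
gaussian_smooth <- function(series, weights = default_config()$filter.weights,
                            alignment = c("forward", "centered")) {
  alignment <- match.arg(alignment)
  w <- length(weights)
  n <- length(series)
  if (abs(sum(weights) - 1) > 1e-12) stop("kernel weights must sum to 1")
  if (n < w) stop("series shorter than the smoothing window (", w, ")")
  out <- numeric(n - w + 1L)
  for (j in seq_len(w)) out <- out + weights[j] * series[j:(n - w + j)]
  # centered alignment returns the same values; only the implied time stamps
  # differ, which callers track via frame bookkeeping
  out
}

smooth_centered_sequence <- function(cs, weights = default_config()$filter.weights) {
  x <- apply(cs$x, 2, gaussian_smooth, weights = weights)
  y <- apply(cs$y, 2, gaussian_smooth, weights = weights)
  structure(list(x = x, y = y, fps = cs$fps,
                 participant_id = cs$participant_id),
            class = "centered_sequence")
}

#' Construct a gait segment
#'
#' The unit of feature extraction: 48 finite channels (24 retained BODY25
#' joints times x/y), fixed length (default 75 frames = 3 s at 25 Hz).
#'
#' @param channels Numeric matrix, frames in rows, 48 columns named as
#'   `j{idx}_{x|y}` in ascending joint order.
#' @param fps Sampling rate in Hz.
#' @param participant_id Identifier.
#' @return An object of class `gait_segment`.
#' @export
gait_segment <- function(channels, fps = 25, participant_id = "anon") {
  channels <- as.matrix(channels)
  if (ncol(channels) != 48L) stop("a gait_segment has exactly 48 channels")
  if (nrow(channels) < 32L)
    stop("a gait_segment needs at least 32 frames (5-level DWT feasibility)")
  if (!all(is.finite(channels))) stop("gait_segment channels must be finite")
  expected <- channel_names()
  if (is.null(colnames(channels))) colnames(channels) <- expected
  else if (!identical(colnames(channels), expected))
    channels <- channels[, expected, drop = FALSE]
  structure(list(channels = channels, fps = fps,
                 participant_id = participant_id,
                 joint_order = RETAINED_JOINTS),
            class = "gait_segment")
}

#' @export
print.gait_segment <- function(x, ...) {
  cat(sprintf("<gait_segment> participant '%s': %d frames x 48 channels @ %g Hz\n",
              x$participant_id, nrow(x$channels), x$fps))
  invisible(x)
}

# frames x 48 channel matrix from a centered_sequence, joint-major x/y order
interleave_channels <- function(cs) {
  nj <- ncol(cs$x)
  m <- matrix(0, nrow(cs$x), 2L * nj)
  m[, seq(1, 2 * nj, 2)] <- cs$x
  m[, seq(2, 2 * nj, 2)] <- cs$y
  colnames(m) <- as.vector(t(outer(colnames(cs$x), c("x", "y"), paste, sep = "_")))
  m
}

#' Standardize a centered, smoothed sequence to a fixed-length segment
#'
#' Takes the central contiguous window of exactly `n_frames` frames
#' (a centre-crop; no resampling, native timing is preserved). Warns when
#' the estimated gait cycle length implies fewer than 4 full cycles inside
#' the window.
#'
#' @param cs A `centered_sequence` (post smoothing).
#' @param n_frames Target length in frames (default 75).
#' @return A [gait_segment()].
#' @export
standardize_length <- function(cs, n_frames = default_config()$n_frames) {
  stopifnot(inherits(cs, "centered_sequence"))
  n <- nrow(cs$x)
  if (n < n_frames)
    stop("sequence of ", n, " frames is shorter than the ", n_frames,
         "-frame analysis window")
  start <- floor((n - n_frames) / 2) + 1L
  idx <- start:(start + n_frames - 1L)
  seg <- gait_segment(interleave_channels(
    structure(list(x = cs$x[idx, , drop = FALSE], y = cs$y[idx, , drop = FALSE],
                   fps = cs$fps, participant_id = cs$participant_id),
              class = "centered_sequence")),
    fps = cs$fps, participant_id = cs$participant_id)
  cyc <- estimate_cycle_length(seg)
  if (!is.na(cyc) && n_frames / cyc < 4)
    warning(sprintf("window of %d frames holds %.1f gait cycles (< 4)",
                    n_frames, n_frames / cyc), call. = FALSE)
  seg
}

#' Estimate the gait cycle length of a segment
#'
#' The horizontal ankle separation |x_RAnkle - x_LAnkle| peaks twice per
#' stride, so the cycle length is twice the lag of the first prominent
#' positive autocorrelation peak (> 0.3) of the mean-removed separation
#' series.
#'
#' @param segment A [gait_segment()].
#' @return Frames per gait cycle, or `NA` when no peak qualifies.
#' @export
estimate_cycle_length <- function(segment) {
  stopifnot(inherits(segment, "gait_segment"))
  d <- abs(segment$channels[, "j11_x"] - segment$channels[, "j14_x"])
  d <- d - mean(d)
  if (stats::sd(d) < 1e-12) return(NA_real_)
  n <- length(d)
  ac <- stats::acf(d, lag.max = n - 2L, plot = FALSE,
                   demean = FALSE)$acf[, 1, 1]
  # local maxima of the autocorrelation at lags >= 1
  if (length(ac) < 4L) return(NA_real_)
  lag <- NA_integer_
  for (k in 2:(length(ac) - 1L)) {
    if (ac[k] > ac[k - 1L] && ac[k] >= ac[k + 1L] && ac[k] > 0.3) {
      lag <- k - 1L  # acf index 1 is lag 0
      break
    }
  }
  if (is.na(lag)) return(NA_real_)
  2 * lag
}

#' Full preprocessing pipeline: raw sequence to analysis segment
#'
#' Runs, in order: dropout interpolation, face-toward interval selection
#' (longest qualifying interval), MidHip re-referencing, binomial smoothing
#' of all 48 channels, and centre-crop standardization to `n_frames`.
#'
#' @param seq A [gait_sequence()].
#' @param config Optional list of overrides for [default_config()] keys.
#' @return A [gait_segment()].
#' @export
preprocess_sequence <- function(seq, config = list()) {
  cfg <- merge_config(config)
  seq <- interpolate_missing(seq, min_conf = cfg$min_conf)
  ivs <- detect_facing_segments(seq, min_len = cfg$n_frames,
                                window_s = cfg$facing.window_s,
                                slope_min = cfg$facing.slope_min)
  lens <- vapply(ivs, function(iv) iv[2] - iv[1] + 1L, integer(1))
  iv <- ivs[[which.max(lens)]]
  sub <- gait_sequence(seq$x[iv[1]:iv[2], , drop = FALSE],
                       seq$y[iv[1]:iv[2], , drop = FALSE],
                       seq$conf[iv[1]:iv[2], , drop = FALSE],
                       fps = seq$fps, participant_id = seq$participant_id)
  cs <- center_on_midhip(sub)
  cs <- smooth_centered_sequence(cs, weights = cfg$filter.weights)
  standardize_length(cs, n_frames = cfg$n_frames)
}
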