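# Reading and writing BODY25 keypoint data: the per-frame OpenPose JSON
# dialect and a consolidated one-row-per-frame CSV table.

#' Construct a gait keypoint sequence
#'
#' A `gait_sequence` stores a 25-joint 2D keypoint time series: per-frame x
#' and y pixel coordinates and detection confidences, the sampling rate, and
#' optional per-frame facing labels. Coordinates follow the image convention
#' (x rightward, y downward); frame indexing is 0-based.
#'
#' @param x,y,conf Numeric matrices, frames in rows and the 25 BODY25 joints
#'   in columns. Confidences must lie in \[0, 1\]; a confidence of 0 marks a
#'   missing detection.
#' @param fps Sampling rate in Hz (default 25).
#' @param participant_id Identifier attached to downstream artifacts.
#' @param facing Optional character vector, one of `"toward"`, `"away"`,
#'   `"unknown"` per frame; overrides heuristic facing detection when present.
#' @return An object of class `gait_sequence`.
#' @export
gait_sequence <- function(x, y, conf, fps = 25, participant_id = "anon",
                          facing = NULL) {
  x <- as.matrix(x); y <- as.matrix(y); conf <- as.matrix(conf)
  if (ncol(x) != 25L || ncol(y) != 25L || ncol(conf) != 25L)
    stop("a gait_sequence needs exactly 25 joint columns per component")
  if (!all(dim(x) == dim(y)) || !all(dim(x) == dim(conf)))
    stop("x, y and conf must have identical dimensions")
  if (any(conf < 0 | conf > 1, na.rm = TRUE))
    stop("confidences must lie in [0, 1]")
  if (fps <= 0) stop("fps must be positive")
  if (!is.null(facing)) {
    if (length(facing) != nrow(x))
      stop("facing labels must match the number of frames")
    if (!all(facing %in% c("toward", "away", "unknown")))
      stop("facing labels must be 'toward', 'away' or 'unknown'")
  }
  bad <- !is.finite(x) | !is.finite(y)
  if (any(bad)) {
    # non-finite coordinates are encoded as missing detections
    x[bad] <- 0; y[bad] <- 0; conf[bad] <- 0
  }
  structure(
    list(x = x, y = y, conf = conf, fps = fps,
         participant_id = participant_id, facing = facing),
    class = "gait_sequence"
  )
}

#' @export
print.gait_sequence <- function(x, ...) {
  cat(sprintf("<gait_sequence> participant '%s': %d frames x 25 joints @ %g Hz (%.1f s)\n",
              x$participant_id, nrow(x$x), x$fps, nrow(x$x) / x$fps))
  if (!is.null(x$facing))
    cat("  facing labels:", paste(names(table(x$facing)), table(x$facing),
                                  sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Number of frames in a gait sequence
#' @param seq A `gait_sequence`.
#' @return Integer frame count.
#' @export
n_frames <- function(seq) nrow(seq$x)

#' Read an OpenPose BODY25 per-frame JSON directory
#'
#' Consumes the standard OpenPose output dialect: one JSON file per frame,
#' each with a `people` array whose entries carry a flat 75-number
#' `pose_keypoints_2d` list (x0, y0, c0, ..., x24, y24, c24). Files are taken
#' in lexicographic order; the frame index equals the file rank. Frames with
#' an empty `people` array become all-missing frames (confidence 0). When a
#' frame contains several people only the first is used, with a warning.
#'
#' @param path Directory containing the per-frame `*.json` files.
#' @param participant_id Identifier for the resulting sequence.
#' @param fps Sampling rate in Hz (default 25).
#' @return A [gait_sequence()].
#' @export
read_openpose_dir <- function(path, participant_id = basename(path), fps = 25) {
  if (!dir.exists(path)) stop("no such directory: ", path)
  files <- sort(list.files(path, pattern = "\\.json$", full.names = TRUE))
  if (length(files) == 0L) stop("no JSON frame files found in ", path)
  n <- length(files)
  x <- matrix(0, n, 25); y <- matrix(0, n, 25); conf <- matrix(0, n, 25)
  multi <- 0L
  for (i in seq_len(n)) {
    doc <- tryCatch(jsonlite::fromJSON(files[i], simplifyVector = TRUE),
                    error = function(e)
                      stop("malformed JSON in ", files[i], ": ",
                           conditionMessage(e), call. = FALSE))
    people <- doc$people
    kp <- NULL
    if (!is.null(people)) {
      if (is.data.frame(people) && nrow(people) > 0L) {
        if (nrow(people) > 1L) multi <- multi + 1L
        kp <- unlist(people$pose_keypoints_2d[1])
      } else if (is.list(people) && length(people) > 0L) {
        if (length(people) > 1L) multi <- multi + 1L
        kp <- unlist(people[[1]]$pose_keypoints_2d)
      }
    }
    if (!is.null(kp)) {
      if (length(kp) != 75L)
        stop("pose_keypoints_2d in ", files[i], " has length ", length(kp),
             ", expected 75", call. = FALSE)
      x[i, ] <- kp[seq(1, 75, 3)]
      y[i, ] <- kp[seq(2, 75, 3)]
      conf[i, ] <- kp[seq(3, 75, 3)]
    }
  }
  if (multi > 0L)
    warning(multi, " frame(s) contained multiple people; using people[0] only")
  gait_sequence(x, y, conf, fps = fps, participant_id = participant_id)
}

table_columns <- function() {
  c("frame", as.vector(t(outer(sprintf("j%02d", 0:24), c("x", "y", "c"),
                               paste, sep = "_"))))
}

#' Write a gait sequence to a consolidated keypoint CSV
#'
#' One row per frame with columns `frame, j00_x, j00_y, j00_c, ..., j24_c`.
#' Coordinates are written with enough digits to round-trip (at least 6
#' significant digits).
#'
#' @param seq A [gait_sequence()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_keypoint_table <- function(seq, path) {
  stopifnot(inherits(seq, "gait_sequence"))
  n <- n_frames(seq)
  out <- matrix(0, n, 75)
  out[, seq(1, 75, 3)] <- seq$x
  out[, seq(2, 75, 3)] <- seq$y
  out[, seq(3, 75, 3)] <- seq$conf
  df <- data.frame(frame = 0:(n - 1L), out)
  names(df) <- table_columns()
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write keypoint table to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read a consolidated keypoint CSV
#'
#' Inverse of [write_keypoint_table()]: expects a header `frame` followed by
#' `j{00..24}_{x,y,c}` columns.
#'
#' @param path CSV file path.
#' @param participant_id Identifier for the resulting sequence.
#' @param fps Sampling rate in Hz (default 25).
#' @return A [gait_sequence()].
#' @export
read_keypoint_table <- function(path, participant_id = sub("\\.csv$", "", basename(path)),
                                fps = 25) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  want <- table_columns()
  missing_cols <- setdiff(want, names(df))
  if (length(missing_cols) > 0L)
    stop("keypoint table ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- df[order(df$frame), , drop = FALSE]
  xc <- sprintf("j%02d_x", 0:24); yc <- sprintf("j%02d_y", 0:24)
  cc <- sprintf("j%02d_c", 0:24)
  gait_sequence(as.matrix(df[xc]), as.matrix(df[yc]), as.matrix(df[cc]),
                fps = fps, participant_id = participant_id)
}

#' Write a gait sequence as an OpenPose per-frame JSON directory
#'
#' Emits the standard BODY25 dialect, one file per frame
#' (`frame_000000.json`, ...), so simulated bouts are interchangeable with
#' real OpenPose output.
#'
#' @param seq A [gait_sequence()].
#' @param path Output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_openpose_dir <- function(seq, path) {
  stopifnot(inherits(seq, "gait_sequence"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create directory ", path)
  n <- n_frames(seq)
  for (i in seq_len(n)) {
    kp <- as.vector(rbind(seq$x[i, ], seq$y[i, ], seq$conf[i, ]))
    doc <- list(version = 1.3,
                people = list(list(pose_keypoints_2d = kp)))
    jsonlite::write_json(doc, file.path(path, sprintf("frame_%06d.json", i - 1L)),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
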