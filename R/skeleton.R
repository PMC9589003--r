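# BODY25 skeleton constants: the joint indexing every other module relies on.

#' BODY25 joint table
#'
#' The 25-keypoint skeleton emitted by OpenPose's BODY25 model. Indices are
#' 0-based (the OpenPose convention); the MidHip (index 8) serves as the
#' per-frame coordinate origin during preprocessing and is dropped from the
#' analysis joint set afterwards.
#'
#' @return A data.frame with columns `index` (integer, 0-24) and `name`
#'   (character, the BODY25 label).
#' @export
#' @examples
#' body25_joints()[9, ]  # MidHip
body25_joints <- function() {
  data.frame(
    index = 0:24,
    name = c(
      "Nose", "Neck", "RShoulder", "RElbow", "RWrist",
      "LShoulder", "LElbow", "LWrist", "MidHip", "RHip",
      "RKnee", "RAnkle", "LHip", "LKnee", "LAnkle",
      "REye", "LEye", "REar", "LEar", "LBigToe",
      "LSmallToe", "LHeel", "RBigToe", "RSmallToe", "RHeel"
    ),
    stringsAsFactors = FALSE
  )
}

# 0-based index of the MidHip reference joint
MIDHIP <- 8L

# the 24 joints retained after MidHip re-referencing, ascending BODY25 order
RETAINED_JOINTS <- c(0:7, 9:24)

# channel labels for the 48 retained coordinate channels, joint-major then axis
channel_names <- function() {
  as.vector(t(outer(sprintf("j%02d", RETAINED_JOINTS), c("x", "y"), paste, sep = "_")))
}

# Ten angle indicators: (a, vertex, c) BODY25 joint triples.
# A6/A7 use the contralateral hip as vertex arm because the MidHip is removed.
ANGLE_TRIPLES <- list(
  A0 = c(0L, 1L, 2L), A1 = c(0L, 1L, 5L),
  A2 = c(1L, 2L, 3L), A3 = c(1L, 5L, 6L),
  A4 = c(2L, 3L, 4L), A5 = c(5L, 6L, 7L),
  A6 = c(12L, 9L, 10L), A7 = c(9L, 12L, 13L),
  A8 = c(9L, 10L, 11L), A9 = c(12L, 13L, 14L)
)

# Thirteen distance indicators: (a, b) BODY25 joint pairs, each contributing
# a transverse (|x|) and a longitudinal (|y|) channel.
DISTANCE_PAIRS <- list(
  D1 = c(1L, 0L), D2 = c(3L, 2L), D3 = c(4L, 2L),
  D4 = c(6L, 5L), D5 = c(7L, 5L), D6 = c(6L, 3L),
  D7 = c(7L, 4L), D8 = c(10L, 9L), D9 = c(11L, 9L),
  D10 = c(13L, 12L), D11 = c(14L, 12L), D12 = c(13L, 10L),
  D13 = c(14L, 11L)
)

TIME_STATS <- c("max", "min", "mean", "median", "variance", "rms",
                "skewness", "kurtosis", "abs_energy", "variation_coefficient")

BAND_NAMES <- c("D1", "D2", "D3", "D4", "D5", "A5")
BAND_STATS <- c("absmax", "mean", "var", "energy")
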