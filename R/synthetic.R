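# Synthetic articulated-walker simulator: BODY25-format walking bouts from
# a minimal 2D sinusoidal limb model, with a planted linear trait. The
# generator emulates the acquisition protocol the pipeline targets: 25 Hz,
# 2-minute bouts, a face-toward (approaching-camera) half and a face-away
# half, periodic limb kinematics, keypoint jitter, and a trait score
# linearly coupled to the gait amplitudes.

#' Walker kinematic parameters
#'
#' @param stride_freq Stride (gait-cycle) frequency in Hz.
#' @param arm_swing_amp Shoulder swing amplitude in radians.
#' @param stride_amp Thigh swing amplitude in radians.
#' @param head_bob_amp Vertical head bob amplitude in pixels.
#' @param base_scale Hip-to-neck length in pixels.
#' @param approach_rate Relative apparent-scale growth per second while the
#'   walker approaches the camera.
#' @param noise_sd Isotropic Gaussian keypoint jitter, in pixels.
#' @param seed Integer RNG seed for the jitter and confidences.
#' @return A list of class `walker_params`.
#' @export
walker_params <- function(stride_freq = 1.0, arm_swing_amp = 0.35,
                          stride_amp = 0.40, head_bob_amp = 2,
                          base_scale = 120, approach_rate = 0.01,
                          noise_sd = 1.0, seed = 1L) {
  if (stride_freq <= 0) stop("stride_freq must be positive")
  if (arm_swing_amp < 0 || stride_amp < 0 || head_bob_amp < 0)
    stop("amplitudes must be nonnegative")
  if (base_scale <= 0) stop("base_scale must be positive")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  structure(list(stride_freq = stride_freq, arm_swing_amp = arm_swing_amp,
                 stride_amp = stride_amp, head_bob_amp = head_bob_amp,
                 base_scale = base_scale, approach_rate = approach_rate,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "walker_params")
}

# fixed skeleton offsets in hip-to-neck units (x rightward, y downward,
# pelvis at the origin)
.skel <- list(
  hip_dx = 0.03, shoulder_dx = 0.18, neck_y = -1.0, shoulder_y = -0.95,
  nose_y = -1.30, upper_arm = 0.35, forearm = 0.30, thigh = 0.50,
  shank = 0.45, eye = c(0.05, -0.05), ear = c(0.09, -0.02),
  bigtoe = c(0.10, 0.04), smalltoe = c(0.13, 0.03), heel = c(-0.05, 0.03)
)

#' Simulate one walking bout
#'
#' Generates a BODY25 keypoint sequence from a fixed-topology 2D skeleton:
#' pelvis at the image centre; thigh and shank angles sinusoidal at
#' `stride_freq` with the two legs in antiphase; arm swing antiphase to the
#' ipsilateral leg; vertical head bob at twice the stride frequency; global
#' apparent scale growing at `approach_rate` during the face-toward first
#' half of the bout and shrinking during the face-away second half (the
#' walker turns at half-bout); independent Gaussian jitter per joint per
#' frame; confidences drawn uniformly in (0.3, 1\].
#'
#' @param params A [walker_params()].
#' @param seconds Bout duration in seconds (default 120).
#' @param fps Sampling rate in Hz (default 25).
#' @param label_facing If `TRUE`, attach ground-truth facing labels to the
#'   sequence (they then override heuristic facing detection downstream).
#' @param participant_id Identifier.
#' @return A [gait_sequence()] of `round(seconds * fps)` frames.
#' @export
simulate_walker <- function(params, seconds = 120, fps = 25,
                            label_facing = FALSE, participant_id = "sim") {
  stopifnot(inherits(params, "walker_params"))
  n <- round(seconds * fps)
  if (n < 2) stop("bout must contain at least 2 frames")
  if (params$stride_freq < 4 / 3)
    warning(sprintf(paste0("stride_freq %.2f Hz gives fewer than 4 gait ",
                           "cycles per 3-s window"), params$stride_freq),
            call. = FALSE)
  t <- (seq_len(n) - 1L) / fps
  half <- seconds / 2
  s <- ifelse(t < half,
              params$base_scale * (1 + params$approach_rate * t),
              params$base_scale * (1 + params$approach_rate * (seconds - t)))
  ph <- 2 * pi * params$stride_freq * t
  sk <- .skel
  th_R <- params$stride_amp * sin(ph)           # right thigh, from vertical
  th_L <- params$stride_amp * sin(ph + pi)      # left thigh, antiphase
  # knee flexion: shank lags the thigh and never hyperextends
  kn_R <- 0.4 * params$stride_amp * (1 + sin(ph - pi / 2))
  kn_L <- 0.4 * params$stride_amp * (1 + sin(ph + pi / 2))
  arm_R <- params$arm_swing_amp * sin(ph + pi)  # antiphase to right leg
  arm_L <- params$arm_swing_amp * sin(ph)
  elb_R <- arm_R * 1.3 + 0.25                   # slight constant elbow bend
  elb_L <- arm_L * 1.3 + 0.25
  ux <- matrix(0, n, 25); uy <- matrix(0, n, 25)  # offsets in skeleton units
  set_j <- function(j, px, py) { ux[, j + 1L] <<- px; uy[, j + 1L] <<- py }
  set_j(8, 0, 0)                                    # MidHip
  set_j(1, 0, sk$neck_y)                            # Neck
  bob <- sin(2 * ph)                                # head bobs twice/cycle
  nose_y <- sk$nose_y + (params$head_bob_amp / params$base_scale) * bob
  set_j(0, 0, nose_y)                               # Nose
  set_j(15, -sk$eye[1], nose_y + sk$eye[2]); set_j(16, sk$eye[1], nose_y + sk$eye[2])
  set_j(17, -sk$ear[1], nose_y + sk$ear[2]); set_j(18, sk$ear[1], nose_y + sk$ear[2])
  set_j(2, -sk$shoulder_dx, sk$shoulder_y)          # RShoulder
  set_j(5, sk$shoulder_dx, sk$shoulder_y)           # LShoulder
  relbx <- -sk$shoulder_dx + sk$upper_arm * sin(arm_R)
  relby <- sk$shoulder_y + sk$upper_arm * cos(arm_R)
  set_j(3, relbx, relby)                            # RElbow
  set_j(4, relbx + sk$forearm * sin(elb_R), relby + sk$forearm * cos(elb_R))
  lelbx <- sk$shoulder_dx + sk$upper_arm * sin(arm_L)
  lelby <- sk$shoulder_y + sk$upper_arm * cos(arm_L)
  set_j(6, lelbx, lelby)                            # LElbow
  set_j(7, lelbx + sk$forearm * sin(elb_L), lelby + sk$forearm * cos(elb_L))
  set_j(9, -sk$hip_dx, 0.02); set_j(12, sk$hip_dx, 0.02)
  rknx <- -sk$hip_dx + sk$thigh * sin(th_R)
  rkny <- 0.02 + sk$thigh * cos(th_R)
  set_j(10, rknx, rkny)                             # RKnee
  rankx <- rknx + sk$shank * sin(th_R - kn_R)
  ranky <- rkny + sk$shank * cos(th_R - kn_R)
  set_j(11, rankx, ranky)                           # RAnkle
  lknx <- sk$hip_dx + sk$thigh * sin(th_L)
  lkny <- 0.02 + sk$thigh * cos(th_L)
  set_j(13, lknx, lkny)                             # LKnee
  lankx <- lknx + sk$shank * sin(th_L - kn_L)
  lanky <- lkny + sk$shank * cos(th_L - kn_L)
  set_j(14, lankx, lanky)                           # LAnkle
  set_j(22, rankx + sk$bigtoe[1], ranky + sk$bigtoe[2])   # RBigToe
  set_j(23, rankx + sk$smalltoe[1], ranky + sk$smalltoe[2])
  set_j(24, rankx + sk$heel[1], ranky + sk$heel[2])
  set_j(19, lankx - sk$bigtoe[1], lanky + sk$bigtoe[2])   # LBigToe
  set_j(20, lankx - sk$smalltoe[1], lanky + sk$smalltoe[2])
  set_j(21, lankx - sk$heel[1], lanky + sk$heel[2])
  centre <- c(320, 240)  # fixed image position of the pelvis
  x <- centre[1] + ux * s
  y <- centre[2] + uy * s
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(params$seed)
  if (params$noise_sd > 0) {
    x <- x + matrix(stats::rnorm(n * 25, 0, params$noise_sd), n, 25)
    y <- y + matrix(stats::rnorm(n * 25, 0, params$noise_sd), n, 25)
  }
  conf <- matrix(stats::runif(n * 25, 0.3 + 1e-9, 1), n, 25)
  facing <- NULL
  if (label_facing) facing <- ifelse(t < half, "toward", "away")
  gait_sequence(x, y, conf, fps = fps, participant_id = participant_id,
                facing = facing)
}

#' Cohort configuration for the simulator
#'
#' Trait scores are planted linearly in the kinematic amplitudes:
#' `y_i = beta0 + beta_arm * arm_swing_amp_i + beta_leg * stride_amp_i +
#' eps_i`, `eps ~ N(0, trait_noise_sd^2)`, then affinely rescaled so the
#' cohort sample mean and SD equal `trait_mean` / `trait_sd`. The default
#' marginal moments (31.40 / 4.55) match a typical Rosenberg Self-Esteem
#' Scale cohort.
#'
#' @param n_walkers Cohort size (>= 2).
#' @param trait_coefficients Named vector `c(beta0, beta_arm, beta_leg)`.
#' @param trait_noise_sd Trait noise SD, in pre-rescaling score units (the
#'   planted linear predictor has SD ~0.16 under the default amplitude
#'   ranges).
#' @param trait_mean,trait_sd Target marginal moments after rescaling.
#' @param bout_seconds Bout length in seconds (default 120).
#' @param fps Sampling rate (default 25).
#' @param noise_sd Keypoint jitter SD in pixels applied to every walker.
#' @param stride_freq_range,arm_amp_range,stride_amp_range Uniform sampling
#'   ranges for the per-walker kinematic parameters.
#' @param base_scale Hip-to-neck length in pixels (shared by the cohort).
#' @param seed Integer RNG seed; the whole cohort is reproducible from it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_walkers = 150L,
                          trait_coefficients = c(beta0 = 0, beta_arm = 1, beta_leg = 1),
                          trait_noise_sd = 0.08,
                          trait_mean = 31.40, trait_sd = 4.55,
                          bout_seconds = 120, fps = 25, noise_sd = 1.0,
                          stride_freq_range = c(0.8, 1.2),
                          arm_amp_range = c(0.15, 0.55),
                          stride_amp_range = c(0.25, 0.55),
                          base_scale = 120, seed = 1L) {
  if (n_walkers < 2) stop("a cohort needs at least 2 walkers")
  if (trait_sd <= 0) stop("trait_sd must be positive")
  if (fps <= 0) stop("fps must be positive")
  structure(list(n_walkers = as.integer(n_walkers),
                 trait_coefficients = trait_coefficients,
                 trait_noise_sd = trait_noise_sd, trait_mean = trait_mean,
                 trait_sd = trait_sd, bout_seconds = bout_seconds, fps = fps,
                 noise_sd = noise_sd, stride_freq_range = stride_freq_range,
                 arm_amp_range = arm_amp_range,
                 stride_amp_range = stride_amp_range,
                 base_scale = base_scale, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate a cohort in memory
#'
#' Draws per-walker kinematic parameters, simulates each bout, and plants
#' the linear trait. The trait depends only on the kinematic amplitudes
#' (never on `base_scale` or `approach_rate`), and after rescaling its
#' sample mean and SD equal the configured targets exactly.
#'
#' @param config A [cohort_config()].
#' @return A list with `sequences` (list of [gait_sequence()]), `traits`
#'   (data.frame `participant_id`, `score`, `sex` — sex assigned
#'   alternately for subgroup evaluation), and `manifest` (per-walker
#'   parameters, raw scores, seeds and the full configuration).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_walkers
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  stride_freq <- stats::runif(n, config$stride_freq_range[1], config$stride_freq_range[2])
  arm_amp <- stats::runif(n, config$arm_amp_range[1], config$arm_amp_range[2])
  stride_amp <- stats::runif(n, config$stride_amp_range[1], config$stride_amp_range[2])
  eps <- if (config$trait_noise_sd > 0)
    stats::rnorm(n, 0, config$trait_noise_sd) else numeric(n)
  walker_seeds <- sample.int(2^30, n)
  b <- config$trait_coefficients
  y_raw <- b[["beta0"]] + b[["beta_arm"]] * arm_amp +
    b[["beta_leg"]] * stride_amp + eps
  # affine rescale to the target marginal moments (exact in-sample)
  ssd <- stats::sd(y_raw)
  y <- if (ssd < 1e-12) rep(config$trait_mean, n) else
    config$trait_mean + config$trait_sd * (y_raw - mean(y_raw)) / ssd
  ids <- sprintf("P%03d", seq_len(n))
  sequences <- vector("list", n)
  for (i in seq_len(n)) {
    p <- walker_params(stride_freq = stride_freq[i], arm_swing_amp = arm_amp[i],
                       stride_amp = stride_amp[i], base_scale = config$base_scale,
                       noise_sd = config$noise_sd, seed = walker_seeds[i])
    sequences[[i]] <- suppressWarnings(
      simulate_walker(p, seconds = config$bout_seconds, fps = config$fps,
                      participant_id = ids[i]))
  }
  if (any(stride_freq < 4 / 3))
    warning(sum(stride_freq < 4 / 3), " walker(s) have stride_freq below ",
            "4/3 Hz: fewer than 4 gait cycles per 3-s window", call. = FALSE)
  traits <- data.frame(participant_id = ids, score = y,
                       sex = rep_len(c("male", "female"), n),
                       stringsAsFactors = FALSE)
  manifest <- list(
    config = unclass(config),
    walkers = data.frame(participant_id = ids, stride_freq = stride_freq,
                         arm_swing_amp = arm_amp, stride_amp = stride_amp,
                         seed = walker_seeds, score_raw = y_raw, score = y,
                         stringsAsFactors = FALSE))
  list(sequences = sequences, traits = traits, manifest = manifest)
}

#' Generate a cohort on disk
#'
#' Writes each simulated bout in both supported formats (OpenPose per-frame
#' JSON directory and consolidated keypoint CSV), plus `traits.csv`
#' (`participant_id`, `score`, `sex`) and `manifest.json` recording the
#' full parameterization. Byte-identical across runs with equal seeds.
#'
#' @param config A [cohort_config()].
#' @param out Output directory.
#' @param formats Subset of `c("json", "csv")`; both by default.
#' @return The in-memory cohort (see [simulate_cohort()]), invisibly.
#' @export
generate_cohort <- function(config, out, formats = c("json", "csv")) {
  formats <- match.arg(formats, several.ok = TRUE)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out)) stop("cannot create output directory ", out)
  cohort <- simulate_cohort(config)
  for (seq in cohort$sequences) {
    if ("json" %in% formats)
      write_openpose_dir(seq, file.path(out, seq$participant_id))
    if ("csv" %in% formats)
      write_keypoint_table(seq, file.path(out, paste0(seq$participant_id, ".csv")))
  }
  utils::write.csv(cohort$traits, file.path(out, "traits.csv"), row.names = FALSE)
  jsonlite::write_json(cohort$manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(cohort)
}
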