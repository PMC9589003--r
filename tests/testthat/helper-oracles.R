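# Shared fixtures and independent oracles, all built in code at test time.

# a generic 48-channel segment with smooth periodic structure plus noise
make_toy_segment <- function(n = 75, seed = 1, id = "toy") {
  set.seed(seed)
  t <- seq_len(n)
  ch <- sapply(seq_len(48), function(j)
    sin(2 * pi * t / (10 + j %% 7)) * (5 + j) + rnorm(n, sd = 0.5))
  gait_segment(ch, fps = 25, participant_id = id)
}

# a segment built from known joint positions (frames x 25 x/y matrices)
segment_from_joints <- function(px, py, fps = 25, id = "manual") {
  conf <- matrix(1, nrow(px), 25)
  seq <- gait_sequence(px, py, conf, fps = fps, participant_id = id)
  cs <- center_on_midhip(seq)
  gait_segment(gaitrait:::interleave_channels(cs), fps = fps, participant_id = id)
}

# naive single-pass reference for the ten time-domain statistics
naive_stats <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  v <- sum((x - m)^2) / n
  c(max = max(x), min = min(x), mean = m, median = median(x), variance = v,
    rms = sqrt(sum(x^2) / n),
    skewness = if (v <= 0) 0 else (sum((x - m)^3) / n) / v^1.5,
    kurtosis = if (v <= 0) 0 else (sum((x - m)^4) / n) / v^2 - 3,
    abs_energy = sum(x^2),
    variation_coefficient = if (abs(m) < 1e-12) 0 else sqrt(v) / m)
}

# explicit-matrix orthonormal Haar analysis for dyadic lengths: returns the
# bands of a `levels`-deep decomposition computed by dense matrix products
matrix_haar_bands <- function(x, levels = 5) {
  n <- length(x)
  stopifnot(n %% 2^levels == 0)
  step_matrix <- function(m) {
    H <- matrix(0, m, m)
    for (i in seq_len(m / 2)) {
      H[i, 2 * i - 1] <- 1 / sqrt(2); H[i, 2 * i] <- 1 / sqrt(2)
      H[m / 2 + i, 2 * i - 1] <- 1 / sqrt(2); H[m / 2 + i, 2 * i] <- -1 / sqrt(2)
    }
    H
  }
  details <- list()
  cur <- x
  for (lv in seq_len(levels)) {
    H <- step_matrix(length(cur))
    out <- as.vector(H %*% cur)
    half <- length(cur) / 2
    details[[paste0("D", lv)]] <- out[(half + 1):length(cur)]
    cur <- out[seq_len(half)]
  }
  c(details, list(approx = cur))
}

# small simulated cohort with features, shared across expensive tests
quiet <- function(expr) suppressWarnings(suppressMessages(expr))
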