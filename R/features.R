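# Assembling the full 2,472-dimensional feature vector and its dictionary.

#' Full gait feature vector of a segment
#'
#' Concatenates the 1,320 time-domain and 1,152 frequency-domain features
#' into the canonical 2,472-dimensional named vector.
#'
#' @param segment A [gait_segment()].
#' @return Named numeric vector of length 2472.
#' @export
segment_features <- function(segment) {
  out <- c(time_domain_features(segment), freq_domain_features(segment))
  stopifnot(length(out) == 2472L)
  out
}

#' Canonical feature names
#' @return Character vector of the 2,472 feature names in canonical order.
#' @export
feature_names <- function() {
  ch <- channel_names()
  td_raw <- as.vector(outer(TIME_STATS, ch, function(s, c) paste0("td_raw_", c, "_", s)))
  td_diff <- as.vector(outer(TIME_STATS, ch, function(s, c) paste0("td_diff_", c, "_", s)))
  td_dist <- unlist(lapply(names(DISTANCE_PAIRS), function(id)
    c(paste0("td_dist_", id, "_x_", TIME_STATS),
      paste0("td_dist_", id, "_y_", TIME_STATS))))
  td_ang <- unlist(lapply(names(ANGLE_TRIPLES), function(id)
    paste0("td_angle_", id, "_", TIME_STATS)))
  fd <- unlist(lapply(ch, function(cn)
    as.vector(outer(BAND_STATS, BAND_NAMES, function(s, b)
      paste0("fd_", cn, "_", b, "_", s)))))
  c(td_raw, td_diff, td_dist, td_ang, fd)
}

#' Feature dictionary
#'
#' Maps every canonical feature name to its source series family, source
#' indicator/channel, and statistic — the lookup used by indicator-level
#' weight aggregation.
#'
#' @return A data.frame with columns `name`, `family` (`raw`, `diff`,
#'   `dist`, `angle`, `wavelet`), `indicator` (A0-A9 and D1-D13 for angle
#'   and distance features; `raw_j{..}_{x|y}` style channel ids otherwise),
#'   `group` (`angle`, `distance`, `other`), and `statistic`.
#' @export
feature_dictionary <- function() {
  nm <- feature_names()
  family <- character(length(nm))
  indicator <- character(length(nm))
  statistic <- character(length(nm))
  parts <- strsplit(nm, "_")
  for (i in seq_along(nm)) {
    p <- parts[[i]]
    if (p[1] == "td" && p[2] %in% c("raw", "diff")) {
      family[i] <- p[2]
      indicator[i] <- paste(p[2], p[3], p[4], sep = "_")
      statistic[i] <- paste(p[-(1:4)], collapse = "_")
    } else if (p[1] == "td" && p[2] == "dist") {
      family[i] <- "dist"
      indicator[i] <- p[3]
      statistic[i] <- paste(p[4], paste(p[-(1:4)], collapse = "_"), sep = "_")
    } else if (p[1] == "td" && p[2] == "angle") {
      family[i] <- "angle"
      indicator[i] <- p[3]
      statistic[i] <- paste(p[-(1:3)], collapse = "_")
    } else {
      family[i] <- "wavelet"
      indicator[i] <- paste("wav", p[2], p[3], sep = "_")
      statistic[i] <- paste(p[4], p[5], sep = "_")
    }
  }
  group <- ifelse(family == "angle", "angle",
                  ifelse(family == "dist", "distance", "other"))
  data.frame(name = nm, family = family, indicator = indicator,
             group = group, statistic = statistic, stringsAsFactors = FALSE)
}

#' Extract features for a whole cohort
#'
#' Runs the full preprocessing pipeline and both feature families for each
#' sequence. Per-participant failures are logged and skipped; the run
#' continues. Per-participant sub-4-cycle warnings are aggregated into one
#' summary warning.
#'
#' @param sequences A list of [gait_sequence()] objects (or a single one).
#' @param config Optional [default_config()] overrides.
#' @return A numeric matrix, one row per surviving participant (rownames =
#'   participant ids), 2,472 feature columns.
#' @export
extract_cohort_features <- function(sequences, config = list()) {
  if (inherits(sequences, "gait_sequence")) sequences <- list(sequences)
  rows <- list(); ids <- character(0)
  n_cycle_warn <- 0L; failed <- character(0)
  for (seq in sequences) {
    fv <- withCallingHandlers(
      tryCatch(segment_features(preprocess_sequence(seq, config)),
               error = function(e) e),
      warning = function(w) {
        if (grepl("gait cycles", conditionMessage(w)))
          n_cycle_warn <<- n_cycle_warn + 1L
        invokeRestart("muffleWarning")
      })
    if (inherits(fv, "error")) {
      failed <- c(failed, seq$participant_id)
      message("skipping participant '", seq$participant_id, "': ",
              conditionMessage(fv))
    } else {
      rows[[length(rows) + 1L]] <- fv
      ids <- c(ids, seq$participant_id)
    }
  }
  if (n_cycle_warn > 0L)
    warning(n_cycle_warn, " participant(s) had fewer than 4 gait cycles in ",
            "the analysis window", call. = FALSE)
  if (length(rows) == 0L)
    stop("feature extraction failed for every participant")
  out <- do.call(rbind, rows)
  rownames(out) <- ids
  out
}
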