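# Frequency-domain gait features: 5-level orthonormal Haar wavelet
# decomposition of each of the 48 channels, 4 statistics per band
# (D1..D5, A5) = 1,152 features.
#
# The analysis/synthesis pair is written out explicitly (orthonormal Haar
# filters 1/sqrt(2); symmetric half-point extension by one sample at odd
# lengths), so perfect reconstruction and Parseval's identity are exact and
# testable.

haar_step <- function(x) {
  n <- length(x)
  padded <- n %% 2L == 1L
  if (padded) x <- c(x, x[n])  # symmetric half-point extension
  odd <- x[seq(1, length(x), 2)]
  even <- x[seq(2, length(x), 2)]
  list(a = (odd + even) / sqrt(2), d = (odd - even) / sqrt(2), n = n)
}

haar_unstep <- function(a, d, n) {
  out <- numeric(2L * length(a))
  out[seq(1, length(out), 2)] <- (a + d) / sqrt(2)
  out[seq(2, length(out), 2)] <- (a - d) / sqrt(2)
  out[seq_len(n)]
}

#' Multi-level Haar wavelet decomposition
#'
#' Orthonormal Haar analysis applied recursively to the approximation
#' branch. Non-dyadic lengths are handled by symmetric half-point padding
#' (the last sample is repeated once at odd lengths), which preserves exact
#' reconstruction. With 5 levels the source series X decomposes into detail
#' bands D1..D5 and the final approximation A5, with X = D1 + D2 + D3 + D4 +
#' D5 + A5 after per-band reconstruction.
#'
#' @param x Numeric series of length at least `2^levels`.
#' @param levels Decomposition depth (default 5).
#' @return An object of class `wavelet_bands`: list with `details` (list
#'   D1..D5 of coefficient arrays), `approx` (A5 coefficients), `lengths`
#'   (pre-padding input length per level, for reconstruction), `n`, `level`,
#'   `base = "haar"`, `padding = "symmetric-half"`.
#' @export
haar_dwt <- function(x, levels = 5L) {
  n <- length(x)
  if (n < 2^levels)
    stop("series of length ", n, " cannot support a ", levels,
         "-level decomposition (need >= ", 2^levels, ")")
  details <- vector("list", levels)
  lengths <- integer(levels)
  cur <- x
  for (lv in seq_len(levels)) {
    st <- haar_step(cur)
    details[[lv]] <- st$d
    lengths[lv] <- st$n
    cur <- st$a
  }
  names(details) <- paste0("D", seq_len(levels))
  structure(list(details = details, approx = cur, lengths = lengths,
                 n = n, level = levels, base = "haar",
                 padding = "symmetric-half"),
            class = "wavelet_bands")
}

#' @export
print.wavelet_bands <- function(x, ...) {
  cat(sprintf("<wavelet_bands> %d-level %s DWT of a length-%d series\n",
              x$level, x$base, x$n))
  cat("  band lengths:",
      paste(c(names(x$details), paste0("A", x$level)),
            c(vapply(x$details, length, integer(1)), length(x$approx)),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# inverse transform of a full coefficient set (list of details + approx)
haar_idwt <- function(details, approx, lengths) {
  cur <- approx
  for (lv in rev(seq_along(details)))
    cur <- haar_unstep(cur, details[[lv]], lengths[lv])
  cur
}

#' Per-band time-domain reconstructions
#'
#' Inverts the decomposition once per band with all other bands zeroed,
#' yielding 6 series of the original length whose sum reproduces the input
#' exactly (the synthesis is linear and the full coefficient set is
#' lossless).
#'
#' @param bands A [haar_dwt()] result.
#' @param n Original series length; must match `bands$n`.
#' @return A matrix `n x 6` with columns D1..D5, A5.
#' @export
reconstruct_bands <- function(bands, n = bands$n) {
  stopifnot(inherits(bands, "wavelet_bands"))
  if (n != bands$n)
    stop("inconsistent length: bands came from a series of length ", bands$n)
  lv <- bands$level
  zero_d <- lapply(bands$details, function(d) numeric(length(d)))
  out <- matrix(0, n, lv + 1L,
                dimnames = list(NULL, c(names(bands$details), paste0("A", lv))))
  for (k in seq_len(lv)) {
    d <- zero_d
    d[[k]] <- bands$details[[k]]
    out[, k] <- haar_idwt(d, numeric(length(bands$approx)), bands$lengths)
  }
  out[, lv + 1L] <- haar_idwt(zero_d, bands$approx, bands$lengths)
  out
}

#' Four statistics per wavelet band
#'
#' Per band, in order D1..D5, A5: absolute maximum, mean, population
#' variance, and absolute energy (sum of squared coefficients).
#'
#' @param bands A [haar_dwt()] result.
#' @return Named numeric vector of `(level + 1) * 4` values.
#' @export
band_stats <- function(bands) {
  stopifnot(inherits(bands, "wavelet_bands"))
  arrs <- c(bands$details, list(bands$approx))
  names(arrs) <- c(names(bands$details), paste0("A", bands$level))
  out <- vapply(arrs, function(b) {
    m <- mean(b)
    c(absmax = max(abs(b)), mean = m, var = mean((b - m)^2),
      energy = sum(b^2))
  }, numeric(4))
  v <- as.vector(out)
  names(v) <- as.vector(outer(BAND_STATS, names(arrs), function(s, b)
    paste0(b, "_", s)))
  v
}

#' All 1,152 frequency-domain features of a segment
#'
#' [band_stats()] of the 5-level Haar decomposition of each of the 48
#' channels. Names follow `fd_j{idx}_{x|y}_{D1..D5|A5}_{absmax|mean|var|energy}`.
#'
#' @param segment A [gait_segment()] with at least 32 frames.
#' @return Named numeric vector of length 1152.
#' @export
freq_domain_features <- function(segment) {
  stopifnot(inherits(segment, "gait_segment"))
  ch <- segment$channels
  out <- lapply(colnames(ch), function(cn) {
    v <- band_stats(haar_dwt(ch[, cn], levels = 5L))
    names(v) <- paste0("fd_", cn, "_", names(v))
    v
  })
  out <- unlist(out)
  stopifnot(length(out) == 1152L)
  out
}
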