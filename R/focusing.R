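#' Receive-focusing delays for a focal point
#'
#' For a focal point (x, z) mm the delay of element m is the differential
#' path time `Psi_m = (r_m - min_m r_m) / c`, where `r_m` is the Euclidean
#' distance from element m to the focal point. Delays are normalized so the
#' nearest element has delay exactly 0; all delays are >= 0.
#'
#' When a snapshot is extracted ([extract_snapshot()]) each channel is read
#' at its own delayed instant, so echoes from the focal point line up across
#' elements ("point-by-point" dynamic receive focusing).
#'
#' @param geometry an `array_geometry`.
#' @param focal_point c(x, z) in mm; z must be > 0 (below the array plane).
#' @return an object of class `focus_delays` with fields `delays` (seconds,
#'   length M) and `focal_point`.
#' @export
compute_focus_delays <- function(geometry, focal_point) {
  stopifnot(inherits(geometry, "array_geometry"), length(focal_point) == 2)
  if (focal_point[2] <= 0) {
    stop_field("focal_point", "focal depth z must be > 0 (below the array plane)")
  }
  ex <- element_positions(geometry)
  r <- sqrt((ex - focal_point[1])^2 + focal_point[2]^2)   # mm
  d <- (r - min(r)) * 1e-3 / geometry$sound_speed
  structure(list(delays = d, focal_point = focal_point),
            class = "focus_delays")
}

#' Analytic (complex) signal of real RF channel data
#'
#' Computes the analytic signal per element over the full time axis via the
#' FFT construction (zeroing negative frequencies, doubling positive ones),
#' so that the real part equals the input exactly and the magnitude is the
#' envelope. Complex input is passed through unchanged with a notice.
#'
#' @param channel_data a `channel_data` (or a plain M x T matrix).
#' @return complex `channel_data` (or matrix) of identical shape.
#' @export
analytic_signal <- function(channel_data) {
  if (inherits(channel_data, "channel_data")) {
    if (is.complex(channel_data$samples)) {
      message("analytic_signal: input is already complex; passing through unchanged")
      return(channel_data)
    }
    out <- channel_data
    out$samples <- analytic_matrix(channel_data$samples)
    return(out)
  }
  x <- channel_data
  if (is.complex(x)) {
    message("analytic_signal: input is already complex; passing through unchanged")
    return(x)
  }
  analytic_matrix(x)
}

analytic_matrix <- function(x) {
  x <- as.matrix(x)
  n <- ncol(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    if (n > 1) h[2:((n + 1) / 2)] <- 2
  }
  t(apply(x, 1, function(row) fft(fft(row) * h, inverse = TRUE) / n))
}

#' Extract an aligned snapshot at a focal point
#'
#' Returns the length-M vector of per-element samples read at the focusing
#' delays: element m is read at time index `time_index + delays_m * fs`
#' (its echo from the focal point arrives `Psi_m` later than at the nearest
#' element), with linear interpolation at fractional positions. With
#' all-zero delays this is the raw column `time_index`.
#'
#' @param channel_data a `channel_data` (real or complex).
#' @param focus_delays a `focus_delays`.
#' @param time_index 1-based sample index of the reference (nearest-element)
#'   arrival; may be fractional.
#' @return an object of class `snapshot` with fields `values` (length M),
#'   `focal_point`, `time_index`.
#' @export
extract_snapshot <- function(channel_data, focus_delays, time_index) {
  sm <- extract_snapshot_matrix(channel_data, focus_delays, time_index,
                                temporal_halfwidth = 0)
  structure(list(values = drop(sm),
                 focal_point = focus_delays$focal_point,
                 time_index = time_index),
            class = "snapshot")
}

#' Extract a temporal window of aligned snapshots
#'
#' Like [extract_snapshot()] but returns the M x (2h+1) matrix of snapshots
#' at sample offsets -h..h around `time_index`, the temporal window used for
#' covariance estimation.
#'
#' @inheritParams extract_snapshot
#' @param temporal_halfwidth integer h >= 0.
#' @return complex (or numeric) M x (2h+1) matrix.
#' @export
extract_snapshot_matrix <- function(channel_data, focus_delays, time_index,
                                    temporal_halfwidth = 0) {
  stopifnot(inherits(channel_data, "channel_data"),
            inherits(focus_delays, "focus_delays"))
  S <- channel_data$samples
  M <- nrow(S); nt <- ncol(S)
  fs <- channel_data$sampling_frequency
  h <- as.integer(temporal_halfwidth)
  fidx <- time_index + focus_delays$delays * fs        # fractional, length M
  offs <- seq(-h, h)
  pos <- outer(fidx, offs, "+")                        # M x K fractional index
  lo <- pmin(floor(pos), nt - 1)                       # pos == nt reads exactly
  if (any(lo < 1) || any(pos > nt)) {
    bad <- which(lo < 1 | pos > nt, arr.ind = TRUE)[1, ]
    stop(sprintf("delayed sample position out of range for element %d at time offset %d (index %.2f of %d)",
                 bad[1], offs[bad[2]], pos[bad[1], bad[2]], nt), call. = FALSE)
  }
  w <- pos - lo
  lin <- row(lo) + (lo - 1) * M                        # column-major linear idx
  S[lin] * (1 - w) + S[lin + M] * w
}

#' Weighted delay-and-sum output
#'
#' The beamformer output for one snapshot: `Q = sum_m conj(Z_m) * p_m`, the
#' inner product of the conjugated weight vector with the aligned snapshot.
#' Uniform weights `1/M` give classical DAS.
#'
#' @param snapshot a `snapshot` or a plain numeric/complex vector.
#' @param weights weight vector of matching length (or a
#'   `beamformer_weights` object).
#' @return a complex scalar.
#' @export
das_output <- function(snapshot, weights) {
  p <- if (inherits(snapshot, "snapshot")) snapshot$values else snapshot
  z <- if (inherits(weights, "beamformer_weights")) weights$weights else weights
  if (length(z) != length(p)) {
    stop(sprintf("weight length %d does not match snapshot length %d",
                 length(z), length(p)), call. = FALSE)
  }
  sum(Conj(z) * p)
}
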