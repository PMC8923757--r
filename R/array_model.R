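#' Linear transducer array geometry
#'
#' Describes a 1-D linear array of `num_elements` elements at pitch `pitch`
#' (mm), centered on the origin at depth z = 0. Element m (1-based) sits at
#' lateral position `x_m = (m - 1 - (M - 1)/2) * pitch`, so the array is
#' symmetric about x = 0 and spans an aperture of `(M - 1) * pitch` mm.
#'
#' @param num_elements number of elements M (integer >= 2).
#' @param pitch element spacing in mm (> 0).
#' @param center_frequency transmit center frequency in Hz.
#' @param sampling_frequency RF sampling rate in Hz; must be at least
#'   `4 * center_frequency` (Nyquist with margin).
#' @param sound_speed speed of sound in m/s (default 1540, soft tissue).
#' @return an object of class `array_geometry`.
#' @examples
#' geom <- make_linear_array(64, 0.154, 5e6, 40e6)
#' range(element_positions(geom))
#' @export
make_linear_array <- function(num_elements, pitch, center_frequency,
                              sampling_frequency, sound_speed = 1540) {
  if (!is.numeric(num_elements) || length(num_elements) != 1 ||
      num_elements < 2 || num_elements != round(num_elements)) {
    stop_field("num_elements", "must be an integer >= 2")
  }
  if (!is.numeric(pitch) || length(pitch) != 1 || pitch <= 0) {
    stop_field("pitch", "must be a positive length in mm")
  }
  if (!is.numeric(center_frequency) || center_frequency <= 0) {
    stop_field("center_frequency", "must be positive (Hz)")
  }
  if (!is.numeric(sampling_frequency) || sampling_frequency <= 0) {
    stop_field("sampling_frequency", "must be positive (Hz)")
  }
  if (sampling_frequency < 4 * center_frequency) {
    stop_field("sampling_frequency",
               sprintf("must be >= 4 x center_frequency (%g Hz); got %g Hz",
                       4 * center_frequency, sampling_frequency))
  }
  if (!is.numeric(sound_speed) || sound_speed <= 0) {
    stop_field("sound_speed", "must be positive (m/s)")
  }
  structure(list(num_elements = as.integer(num_elements),
                 pitch = pitch,
                 center_frequency = center_frequency,
                 sampling_frequency = sampling_frequency,
                 sound_speed = sound_speed),
            class = "array_geometry")
}

#' Element lateral positions of a linear array
#'
#' @param geometry an `array_geometry`.
#' @return numeric vector of length M: lateral positions in mm, centered at 0.
#' @export
element_positions <- function(geometry) {
  stopifnot(inherits(geometry, "array_geometry"))
  M <- geometry$num_elements
  (seq_len(M) - 1 - (M - 1) / 2) * geometry$pitch
}

#' @export
print.array_geometry <- function(x, ...) {
  cat(sprintf("linear array: %d elements, pitch %.4g mm, f0 %.3g MHz, fs %.3g MHz, c %.4g m/s\n",
              x$num_elements, x$pitch, x$center_frequency / 1e6,
              x$sampling_frequency / 1e6, x$sound_speed))
  invisible(x)
}

#' Gaussian-modulated excitation pulse
#'
#' A Gaussian-envelope sinusoid, the conventional broadband pulse model. The
#' envelope standard deviation is set from the -6 dB fractional bandwidth
#' `b`: `sigma_t = sqrt(2 log 2) / (pi * b * f0)`, and the waveform is
#' truncated to `duration_cycles / f0` seconds total so it has compact
#' support.
#'
#' @param center_frequency pulse center frequency in Hz.
#' @param fractional_bandwidth -6 dB fractional bandwidth, in (0, 2).
#' @param duration_cycles truncation width in carrier cycles (> 0).
#' @return an object of class `pulse`.
#' @export
make_pulse <- function(center_frequency, fractional_bandwidth = 0.6,
                       duration_cycles = 4) {
  if (!is.numeric(center_frequency) || center_frequency <= 0) {
    stop_field("center_frequency", "must be positive (Hz)")
  }
  if (!is.numeric(fractional_bandwidth) || fractional_bandwidth <= 0 ||
      fractional_bandwidth >= 2) {
    stop_field("fractional_bandwidth", "must lie in (0, 2)")
  }
  if (!is.numeric(duration_cycles) || duration_cycles <= 0) {
    stop_field("duration_cycles", "must be positive")
  }
  structure(list(center_frequency = center_frequency,
                 fractional_bandwidth = fractional_bandwidth,
                 duration_cycles = duration_cycles),
            class = "pulse")
}

#' Evaluate a pulse waveform at arbitrary times
#'
#' @param pulse a `pulse`.
#' @param t times in seconds (vector or array), centered on the pulse peak.
#' @return waveform values, same shape as `t`.
#' @export
pulse_waveform <- function(pulse, t) {
  f0 <- pulse$center_frequency
  sigma <- sqrt(2 * log(2)) / (pi * pulse$fractional_bandwidth * f0)
  half <- pulse$duration_cycles / (2 * f0)
  out <- exp(-t^2 / (2 * sigma^2)) * cos(2 * pi * f0 * t)
  out[abs(t) > half] <- 0
  out
}

# half-support of the pulse in seconds (truncation point)
pulse_half_support <- function(pulse) pulse$duration_cycles / (2 * pulse$center_frequency)

#' Scatterer phantom
#'
#' A phantom is a set of point scatterers at positions (x, z) mm with real
#' amplitudes, plus zero or more circular anechoic (cyst) regions in which
#' diffuse scatterers are suppressed. `make_phantom()` builds one from an
#' explicit scatterer table; [make_cyst_phantom()] adds uniformly distributed
#' diffuse speckle scatterers around an anechoic disc.
#'
#' @param scatterers data.frame with columns `x`, `z` (mm) and `amplitude`.
#' @param cyst_regions optional data.frame with columns `x`, `z`, `radius` (mm).
#' @param speckle_density diffuse scatterer density per mm^2 (bookkeeping).
#' @return an object of class `phantom`.
#' @export
make_phantom <- function(scatterers,
                         cyst_regions = NULL,
                         speckle_density = 0) {
  scatterers <- as.data.frame(scatterers)
  if (nrow(scatterers) > 0) {
    stopifnot(all(c("x", "z", "amplitude") %in% names(scatterers)))
    if (any(scatterers$z <= 0)) {
      stop_field("scatterers$z", "all targets must lie below the array face (z > 0)")
    }
  }
  if (!is.null(cyst_regions)) {
    cyst_regions <- as.data.frame(cyst_regions)
    stopifnot(all(c("x", "z", "radius") %in% names(cyst_regions)))
    if (any(cyst_regions$radius <= 0)) stop_field("cyst_regions$radius", "must be > 0")
  }
  structure(list(scatterers = scatterers,
                 cyst_regions = cyst_regions,
                 speckle_density = speckle_density),
            class = "phantom")
}

#' Single point-target phantom
#'
#' @param x,z target position in mm (z > 0).
#' @param amplitude scatterer amplitude.
#' @return a `phantom` with one scatterer and no diffuse speckle.
#' @export
make_point_phantom <- function(x, z, amplitude = 1) {
  make_phantom(data.frame(x = x, z = z, amplitude = amplitude))
}

#' Anechoic-cyst speckle phantom
#'
#' Fills a rectangular field with diffuse scatterers drawn from a Poisson
#' process of intensity `speckle_density` per mm^2, Rayleigh-distributed
#' amplitudes with unit mean (fully developed speckle), and removes every
#' scatterer inside the anechoic cyst disc.
#'
#' @param cyst_center c(x, z) center of the anechoic disc, mm.
#' @param cyst_radius disc radius, mm (> 0).
#' @param field_extent list with `x = c(min, max)` and `z = c(min, max)` in mm
#'   (z entirely > 0); the cyst must be contained in the extent.
#' @param speckle_density expected diffuse scatterers per mm^2 (>= 0).
#' @param seed integer seed for reproducible scatterer draws.
#' @param extra_scatterers optional data.frame of deterministic scatterers
#'   (columns `x`, `z`, `amplitude`) appended unchanged.
#' @return a `phantom`.
#' @examples
#' ph <- make_cyst_phantom(c(0, 17), 2, list(x = c(-5, 5), z = c(12, 22)), 4, seed = 1)
#' nrow(ph$scatterers)
#' @export
make_cyst_phantom <- function(cyst_center, cyst_radius, field_extent,
                              speckle_density, seed = NULL,
                              extra_scatterers = NULL) {
  stopifnot(length(cyst_center) == 2, cyst_radius > 0, speckle_density >= 0)
  xr <- sort(field_extent$x); zr <- sort(field_extent$z)
  if (zr[1] <= 0) stop_field("field_extent$z", "must be entirely > 0")
  if (cyst_center[1] - cyst_radius < xr[1] || cyst_center[1] + cyst_radius > xr[2] ||
      cyst_center[2] - cyst_radius < zr[1] || cyst_center[2] + cyst_radius > zr[2]) {
    stop("cyst is not contained in the field extent", call. = FALSE)
  }
  area <- diff(xr) * diff(zr)
  sc <- with_local_seed(seed, {
    n <- rpois(1, speckle_density * area)
    if (n > 0) {
      x <- runif(n, xr[1], xr[2])
      z <- runif(n, zr[1], zr[2])
      # Rayleigh amplitude rescaled to unit mean (mean of Rayleigh(1) is sqrt(pi/2))
      amp <- sqrt(rnorm(n)^2 + rnorm(n)^2) * sqrt(2 / pi)
      keep <- (x - cyst_center[1])^2 + (z - cyst_center[2])^2 > cyst_radius^2
      data.frame(x = x[keep], z = z[keep], amplitude = amp[keep])
    } else {
      data.frame(x = numeric(0), z = numeric(0), amplitude = numeric(0))
    }
  })
  if (!is.null(extra_scatterers)) sc <- rbind(sc, as.data.frame(extra_scatterers))
  make_phantom(sc,
               cyst_regions = data.frame(x = cyst_center[1], z = cyst_center[2],
                                         radius = cyst_radius),
               speckle_density = speckle_density)
}

#' Per-element RF channel data
#'
#' Container for the array received signal: one time series per element,
#' stored as an M x T matrix (row m = element m). Values may be real RF or
#' complex analytic samples (see [analytic_signal()]).
#'
#' @param samples M x T numeric or complex matrix, finite values only.
#' @param time_origin time of the first sample, seconds.
#' @param sampling_frequency Hz.
#' @param geometry the `array_geometry` the data was recorded with.
#' @return an object of class `channel_data`.
#' @export
make_channel_data <- function(samples, time_origin, sampling_frequency, geometry) {
  stopifnot(inherits(geometry, "array_geometry"), is.matrix(samples))
  if (nrow(samples) != geometry$num_elements) {
    stop_field("samples", sprintf("row count %d must equal num_elements %d",
                                  nrow(samples), geometry$num_elements))
  }
  if (!all(is.finite(Re(samples))) || !all(is.finite(Im(samples)))) {
    stop_field("samples", "finite values only")
  }
  structure(list(samples = samples,
                 time_origin = time_origin,
                 sampling_frequency = sampling_frequency,
                 geometry = geometry),
            class = "channel_data")
}

#' @export
print.channel_data <- function(x, ...) {
  cat(sprintf("channel data: %d elements x %d samples, fs %.3g MHz, t0 %.3g us, %s\n",
              nrow(x$samples), ncol(x$samples), x$sampling_frequency / 1e6,
              x$time_origin * 1e6,
              if (is.complex(x$samples)) "complex (analytic)" else "real RF"))
  invisible(x)
}

#' Simulate RF channel data for a phantom
#'
#' Monostatic pulse-echo forward model: a plane wave is launched from the
#' aperture plane (transmit delay `z/c` to a scatterer at depth z) and each
#' scatterer echoes back to every element m over the direct path `r_m`.
#' Element m therefore records, for each scatterer of amplitude a at (x, z),
#' a pulse replica delayed by `(z + r_m)/c` and scaled by `a / r_m`
#' (spherical spreading; r in mm cancels into an arbitrary common gain).
#' Additive white Gaussian noise is quoted in dB relative to the peak
#' absolute signal amplitude; `noise_db = -Inf` disables it.
#'
#' The model is linear in the phantom: simulating the union of two scatterer
#' sets equals the sum of the separate (noiseless) simulations.
#'
#' @param geometry an `array_geometry`.
#' @param phantom a `phantom`; must contain at least one scatterer unless
#'   noise is enabled (all-zero data is rejected, not returned).
#' @param pulse a `pulse`.
#' @param noise_db noise level in dB relative to peak signal amplitude
#'   (`-Inf` = noiseless).
#' @param seed integer seed for the noise draw.
#' @param t_max optional recording end time (s); default covers every
#'   scatterer's farthest echo plus the pulse support.
#' @return real-valued `channel_data`.
#' @export
simulate_channel_data <- function(geometry, phantom, pulse, noise_db = -Inf,
                                  seed = NULL, t_max = NULL) {
  stopifnot(inherits(geometry, "array_geometry"), inherits(phantom, "phantom"),
            inherits(pulse, "pulse"))
  sc <- phantom$scatterers
  noiseless <- identical(noise_db, -Inf)
  if ((nrow(sc) == 0 || all(sc$amplitude == 0)) && noiseless) {
    stop("phantom has no echoing scatterer and noise is disabled: refusing to return all-zero channel data",
         call. = FALSE)
  }
  fs <- geometry$sampling_frequency
  c0 <- geometry$sound_speed
  ex <- element_positions(geometry)            # mm
  M <- geometry$num_elements
  half <- pulse_half_support(pulse)

  if (is.null(t_max)) {
    if (nrow(sc) > 0) {
      rmax <- max(vapply(seq_len(nrow(sc)), function(i) {
        max(sqrt((ex - sc$x[i])^2 + sc$z[i]^2))
      }, numeric(1)))
      # pulse support plus slack for covariance temporal windows at the far edge
      t_max <- (max(sc$z) + rmax) * 1e-3 / c0 + 2 * half + 64 / fs
    } else {
      t_max <- 256 / fs
    }
  }
  nt <- ceiling(t_max * fs) + 1L
  samples <- matrix(0, M, nt)
  khalf <- ceiling(half * fs) + 1L
  koff <- seq(-khalf, khalf)                   # pulse support in samples

  for (i in seq_len(nrow(sc))) {
    a <- sc$amplitude[i]
    if (a == 0) next
    r <- sqrt((ex - sc$x[i])^2 + sc$z[i]^2)    # mm, element -> scatterer
    tau <- (sc$z[i] + r) * 1e-3 / c0           # two-way arrival, s
    base <- round(tau * fs)                    # nearest sample, 0-based
    idx <- outer(base, koff, "+")              # M x K, 0-based sample index
    tmat <- idx / fs - tau                     # time rel. pulse peak
    val <- (a / r) * pulse_waveform(pulse, tmat)
    ok <- idx >= 0 & idx < nt
    lin <- cbind(row(idx)[ok], idx[ok] + 1L)
    samples[lin] <- samples[lin] + val[ok]
  }

  if (!noiseless) {
    if (!is.finite(noise_db)) stop_field("noise_db", "must be finite or -Inf")
    ref <- max(abs(samples))
    if (ref == 0) ref <- 1                      # pure-noise data: unit scale
    sd <- ref * 10^(noise_db / 20)
    noise <- with_local_seed(seed, matrix(rnorm(M * nt, sd = sd), M, nt))
    samples <- samples + noise
  }
  make_channel_data(samples, time_origin = 0, sampling_frequency = fs,
                    geometry = geometry)
}
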