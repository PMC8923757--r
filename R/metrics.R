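#' Average power of a signal window
#'
#' The time average of the instantaneous power `p(t) = |s(t)|^2` over the
#' window, `P = (1/T) integral_0^T p(t) dt`, discretized with the
#' trapezoidal rule. For a unit-amplitude sinusoid over whole periods this
#' is 1/2; scaling the amplitude by `a` scales the result by `a^2`.
#'
#' @param signal_samples real or complex sample vector (>= 2 samples).
#' @param sampling_interval sample spacing in seconds (> 0).
#' @return average power (real scalar).
#' @export
average_power <- function(signal_samples, sampling_interval = 1) {
  n <- length(signal_samples)
  if (n < 2) stop("need at least two samples to average power over a window", call. = FALSE)
  if (sampling_interval <= 0) stop_field("sampling_interval", "must be > 0")
  p <- Mod(signal_samples)^2
  # trapezoid: (dt * (sum - (first+last)/2)) / T, T = (n-1) dt
  (sum(p) - (p[1] + p[n]) / 2) / (n - 1)
}

#' Scoring region of an image
#'
#' @param shape `"disc"` or `"rect"`.
#' @param center c(x, z) in mm.
#' @param radius disc radius in mm (shape "disc").
#' @param half_extents c(hx, hz) in mm (shape "rect").
#' @param label free-text label, conventionally `"center"` or
#'   `"background"`.
#' @return an object of class `region_spec`.
#' @export
make_region <- function(shape = c("disc", "rect"), center, radius = NULL,
                        half_extents = NULL, label = "") {
  shape <- match.arg(shape)
  stopifnot(length(center) == 2)
  if (shape == "disc" && (is.null(radius) || radius <= 0)) {
    stop_field("radius", "must be > 0 for a disc region")
  }
  if (shape == "rect" && (is.null(half_extents) || any(half_extents <= 0))) {
    stop_field("half_extents", "must be > 0 for a rect region")
  }
  structure(list(shape = shape, center = center, radius = radius,
                 half_extents = half_extents, label = label),
            class = "region_spec")
}

region_mask <- function(grid, region) {
  xs <- grid$x_positions; zs <- grid$z_positions
  X <- matrix(xs, length(zs), length(xs), byrow = TRUE)
  Z <- matrix(zs, length(zs), length(xs))
  if (region$shape == "disc") {
    (X - region$center[1])^2 + (Z - region$center[2])^2 <= region$radius^2
  } else {
    abs(X - region$center[1]) <= region$half_extents[1] &
      abs(Z - region$center[2]) <= region$half_extents[2]
  }
}

#' Mean region power in dB
#'
#' `10 log10` of the mean squared envelope over the region's pixels,
#' referenced to the image's global maximum squared envelope, so a region
#' holding only peak-level pixels scores 0 dB and everything else is
#' negative.
#'
#' @param image a `beamformed_image`.
#' @param region a `region_spec`; must intersect the grid in at least 9
#'   pixels.
#' @return power in dB (<= 0).
#' @export
region_power_db <- function(image, region) {
  stopifnot(inherits(image, "beamformed_image"), inherits(region, "region_spec"))
  mask <- region_mask(image$grid, region)
  if (sum(mask) < 9) {
    stop(sprintf("region '%s' covers only %d pixel(s); at least 9 required",
                 region$label, sum(mask)), call. = FALSE)
  }
  env2 <- Mod(image$complex_values)^2
  10 * log10(mean(env2[mask]) / max(env2))
}

#' Contrast between two image regions in dB
#'
#' Absolute difference of the background and center region powers,
#' `|P_bg - P_center|` in dB. With the anechoic-cyst convention (center =
#' cyst interior, background = surrounding speckle) larger contrast means
#' better interference and clutter rejection. Invariant to global image
#' rescaling.
#'
#' @param image a `beamformed_image`.
#' @param center_region,background_region disjoint `region_spec`s. Exactly
#'   identical regions are allowed and give 0 by definition; partially
#'   overlapping regions are an error.
#' @return contrast in dB (>= 0).
#' @export
contrast_db <- function(image, center_region, background_region) {
  mc <- region_mask(image$grid, center_region)
  mb <- region_mask(image$grid, background_region)
  if (identical(mc, mb)) return(0)     # degenerate but well-defined: |P - P| = 0
  if (any(mc & mb)) stop("center and background regions overlap", call. = FALSE)
  abs(region_power_db(image, background_region) -
        region_power_db(image, center_region))
}

#' Lateral -6 dB width of a point target (FWHM resolution)
#'
#' Takes the lateral envelope profile through the image row nearest the
#' point target, finds its peak near the target's lateral position, and
#' measures the width at half the peak amplitude (-6 dB) by linear
#' interpolation between straddling samples. Smaller is better.
#'
#' @param image a `beamformed_image` dominated by a point target near
#'   `point_target_location`.
#' @param point_target_location c(x, z) in mm.
#' @return width in mm.
#' @export
lateral_fwhm <- function(image, point_target_location) {
  stopifnot(inherits(image, "beamformed_image"))
  zs <- image$grid$z_positions
  iz <- which.min(abs(zs - point_target_location[2]))
  prof <- Mod(image$complex_values[iz, ])
  profile_fwhm(prof, image$grid$x_positions)
}

# -6 dB width of a sampled amplitude profile (linear amplitudes)
profile_fwhm <- function(prof, x) {
  ipk <- which.max(prof)
  half <- prof[ipk] / 2
  cross <- function(idx_seq) {
    for (j in idx_seq) {
      if (prof[j] < half) {
        # linear interpolation between j and previous point toward the peak
        jn <- j + if (idx_seq[1] > ipk) -1L else 1L
        return(x[j] + (x[jn] - x[j]) * (half - prof[j]) / (prof[jn] - prof[j]))
      }
    }
    NULL
  }
  xr <- if (ipk < length(prof)) cross(seq(ipk + 1L, length(prof))) else NULL
  xl <- if (ipk > 1) cross(seq(ipk - 1L, 1L)) else NULL
  if (is.null(xr) || is.null(xl)) {
    stop("profile never falls below -6 dB inside the grid: width unmeasurable", call. = FALSE)
  }
  xr - xl
}

#' Peak sidelobe level of a beam profile
#'
#' Identifies the main lobe around the global peak (descending to the first
#' local minimum on each side) and returns the highest local maximum outside
#' it, in dB below the peak. Returns `-Inf` when no secondary maximum
#' exists (single-lobe profile).
#'
#' @param profile vector of linear (amplitude) profile samples.
#' @return peak sidelobe level in dB (negative), or `-Inf`.
#' @export
peak_sidelobe_db <- function(profile) {
  prof <- Mod(profile)
  n <- length(prof)
  ipk <- which.max(prof)
  # walk down each side of the main lobe to its first local minimum
  right <- ipk
  while (right < n && prof[right + 1] <= prof[right]) right <- right + 1
  left <- ipk
  while (left > 1 && prof[left - 1] <= prof[left]) left <- left - 1
  outside <- prof[setdiff(seq_len(n), seq(left, right))]
  if (length(outside) == 0) return(-Inf)
  20 * log10(max(outside) / prof[ipk])
}

#' Image-quality benchmark across beamformers and seeds
#'
#' Runs the standardized synthetic evaluation: for each seed, an
#' anechoic-cyst speckle phantom (contrast, region powers) and a separate
#' point-target phantom (lateral FWHM resolution and peak sidelobe level)
#' are simulated, beamformed with every requested method, and scored. The
#' per-method medians across seeds summarize the comparison.
#'
#' @param methods character vector of beamformer names.
#' @param config benchmark configuration; see [standard_benchmark_config()]
#'   for the documented defaults.
#' @param n_seeds number of independent phantom/noise realizations.
#' @param seed base seed; realization j uses `seed + j - 1`.
#' @param csv optional path; when given, the per-run table is written as CSV
#'   with the fixed column order `method, seed, center_power_db,
#'   background_power_db, contrast_db, resolution_fwhm_mm,
#'   peak_sidelobe_db`.
#' @return list with `runs` (data.frame, one row per method x seed) and
#'   `medians` (per-method medians of every metric).
#' @export
benchmark_report <- function(methods = c("DAS", "SCB", "ISCB"),
                             config = standard_benchmark_config(),
                             n_seeds = 10, seed = 1, csv = NULL) {
  if (length(methods) < 1) stop("need at least one method", call. = FALSE)
  if (n_seeds < 1) stop("need at least one seed", call. = FALSE)
  rows <- vector("list", length(methods) * n_seeds)
  ri <- 1L
  for (j in seq_len(n_seeds)) {
    sj <- seed + j - 1L
    res <- benchmark_one_seed(methods, config, sj)
    for (m in methods) {
      rows[[ri]] <- data.frame(method = m, seed = sj,
                               center_power_db = res[[m]]$center_power_db,
                               background_power_db = res[[m]]$background_power_db,
                               contrast_db = res[[m]]$contrast_db,
                               resolution_fwhm_mm = res[[m]]$resolution_fwhm_mm,
                               peak_sidelobe_db = res[[m]]$peak_sidelobe_db)
      ri <- ri + 1L
    }
  }
  runs <- do.call(rbind, rows)
  med <- do.call(rbind, lapply(split(runs, runs$method), function(d) {
    data.frame(method = d$method[1],
               center_power_db = median(d$center_power_db),
               background_power_db = median(d$background_power_db),
               contrast_db = median(d$contrast_db),
               resolution_fwhm_mm = median(d$resolution_fwhm_mm),
               peak_sidelobe_db = median(d$peak_sidelobe_db))
  }))
  med <- med[match(methods, med$method), ]
  rownames(med) <- NULL
  if (!is.null(csv)) {
    write.csv(runs, csv, row.names = FALSE, quote = FALSE)
  }
  list(runs = runs, medians = med)
}

# one seed of the standardized benchmark: cyst image + point-target image
benchmark_one_seed <- function(methods, config, seed) {
  geom <- do.call(make_linear_array, config$geometry)
  pulse <- do.call(make_pulse, config$pulse)

  cyst <- config$cyst
  ph_c <- make_cyst_phantom(cyst$center, cyst$radius, cyst$field_extent,
                            cyst$speckle_density, seed = seed)
  cd_c <- simulate_channel_data(geom, ph_c, pulse, noise_db = config$noise_db,
                                seed = seed + 100003L)
  imgs_c <- beamform_methods(cd_c, do.call(make_image_grid, cyst$grid),
                             methods, config$beamform_params)

  pt <- config$point
  ph_p <- make_point_phantom(pt$location[1], pt$location[2])
  cd_p <- simulate_channel_data(geom, ph_p, pulse, noise_db = config$noise_db,
                                seed = seed + 200003L)
  imgs_p <- beamform_methods(cd_p, do.call(make_image_grid, pt$grid),
                             methods, config$beamform_params)

  ctr_reg <- make_region("disc", cyst$center, radius = 0.6 * cyst$radius,
                         label = "center")
  bg_reg <- do.call(make_region, c(config$background_region, list(label = "background")))

  out <- list()
  for (m in methods) {
    ic <- imgs_c[[m]]; ip <- imgs_p[[m]]
    izp <- which.min(abs(ip$grid$z_positions - pt$location[2]))
    out[[m]] <- list(
      center_power_db = region_power_db(ic, ctr_reg),
      background_power_db = region_power_db(ic, bg_reg),
      contrast_db = contrast_db(ic, ctr_reg, bg_reg),
      resolution_fwhm_mm = lateral_fwhm(ip, pt$location),
      peak_sidelobe_db = peak_sidelobe_db(Mod(ip$complex_values[izp, ]))
    )
  }
  out
}

#' Standardized benchmark configuration
#'
#' The documented defaults of the synthetic evaluation suite: a 64-element,
#' 5 MHz, half-wavelength-pitch linear array sampled at 40 MHz in 1540 m/s
#' tissue; a 4-cycle, 60% bandwidth Gaussian pulse; an anechoic cyst of
#' radius 2 mm at (0, 17) mm in a 10 x 10 mm speckle field of density
#' 4 scatterers/mm^2; channel noise at -30 dB of the peak signal; and a
#' separate unit point target at (0, 25) mm for resolution. Region
#' conventions: center = disc of 0.6 x cyst radius at the cyst center;
#' background = 1 x 2.5 mm rectangle at (3, 17) mm, inside the speckle but
#' clear of the cyst.
#'
#' @return a nested configuration list accepted by [benchmark_report()].
#' @export
standard_benchmark_config <- function() {
  list(
    geometry = list(num_elements = 64, pitch = 0.154, center_frequency = 5e6,
                    sampling_frequency = 40e6, sound_speed = 1540),
    pulse = list(center_frequency = 5e6, fractional_bandwidth = 0.6,
                 duration_cycles = 4),
    noise_db = -30,
    cyst = list(center = c(0, 17), radius = 2,
                field_extent = list(x = c(-5, 5), z = c(12, 22)),
                speckle_density = 4,
                grid = list(x_positions = seq(-4, 4, by = 0.2),
                            z_positions = seq(13.5, 20.5, by = 0.2))),
    background_region = list(shape = "rect", center = c(3, 17),
                             half_extents = c(0.5, 1.25)),
    point = list(location = c(0, 25),
                 grid = list(x_positions = seq(-1.5, 1.5, by = 0.025),
                             z_positions = seq(24.8, 25.2, by = 0.05))),
    beamform_params = list()
  )
}
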