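test_that("average power: constants, sinusoids, trapezoid oracle, symmetry", {
  expect_equal(average_power(rep(2, 50)), 4)

  # unit sinusoid over whole periods: exactly 1/2
  fs <- 80; f0 <- 5
  t <- seq(0, 8 / f0, by = 1 / fs)       # 8 whole periods
  x <- sin(2 * pi * f0 * t)
  expect_equal(average_power(x, 1 / fs), 0.5, tolerance = 1e-9)

  set.seed(20)
  v <- rnorm(16) + 1i * rnorm(16)
  dt <- 0.125
  p <- Mod(v)^2
  oracle <- sum((p[-1] + p[-16]) / 2 * dt) / (15 * dt)
  expect_equal(average_power(v, dt), oracle, tolerance = 1e-12)

  # time-reversal invariance and quadratic amplitude scaling
  expect_equal(average_power(rev(v), dt), average_power(v, dt), tolerance = 1e-14)
  expect_equal(average_power(3 * v, dt), 9 * average_power(v, dt), tolerance = 1e-12)

  expect_error(average_power(numeric(0)), "samples")
})

make_test_image <- function(values, xs, zs, dr = 60) {
  structure(list(complex_values = values,
                 bmode_db = envelope_log_compress(values, dr),
                 dynamic_range = dr, method = "TEST",
                 grid = make_image_grid(xs, zs)),
            class = "beamformed_image")
}

test_that("region power: reference, uniform image, two-level oracle", {
  xs <- seq(-2, 2, by = 0.25); zs <- seq(10, 14, by = 0.25)
  uni <- make_test_image(matrix(1 + 0i, length(zs), length(xs)), xs, zs)
  anywhere <- make_region("rect", c(0, 12), half_extents = c(1, 1))
  expect_equal(region_power_db(uni, anywhere), 0)

  # two-level image: left half amplitude 1, right half 0.1
  v <- matrix(1 + 0i, length(zs), length(xs))
  v[, xs > 0] <- 0.1
  img <- make_test_image(v, xs, zs)
  left <- make_region("rect", c(-1.5, 12), half_extents = c(0.4, 1))
  right <- make_region("rect", c(1.5, 12), half_extents = c(0.4, 1))
  expect_equal(region_power_db(img, left), 0)
  expect_equal(region_power_db(img, right), 10 * log10(0.01), tolerance = 1e-12)
  expect_equal(contrast_db(img, right, left), 20, tolerance = 1e-12)

  # identical regions give zero contrast; partial overlap errors
  expect_equal(contrast_db(img, left, left), 0)
  shifted <- make_region("rect", c(-1.2, 12), half_extents = c(0.4, 1))
  expect_error(contrast_db(img, left, shifted), "overlap")

  tiny <- make_region("disc", c(0, 12), radius = 0.01)
  expect_error(region_power_db(img, tiny), "at least 9")

  # contrast is invariant to global rescaling
  img10 <- make_test_image(10 * v, xs, zs)
  expect_equal(contrast_db(img10, right, left), contrast_db(img, right, left),
               tolerance = 1e-12)
})

test_that("lateral fwhm: Gaussian closed form, exact crossings, flat error", {
  xs <- seq(-3, 3, by = 0.02); zs <- c(9.9, 10, 10.1)
  sigma <- 0.4
  prof <- exp(-xs^2 / (2 * sigma^2))
  v <- rbind(0.01 * prof, prof, 0.01 * prof) + 0i
  img <- make_test_image(v, xs, zs)
  fw <- lateral_fwhm(img, c(0, 10))
  expect_lt(abs(fw - 2 * sigma * sqrt(2 * log(2))), 0.02)   # within one step

  # profile sampled exactly at the half-max points: exact width
  xs2 <- seq(-2, 2, by = 0.5)
  prof2 <- pmax(1 - abs(xs2), 0)       # triangle: half-max at +/- 0.5
  v2 <- rbind(prof2 * 0.01, prof2, prof2 * 0.01) + 0i
  img2 <- make_test_image(v2, xs2, zs)
  expect_equal(lateral_fwhm(img2, c(0, 10)), 1)

  flat <- make_test_image(matrix(1 + 0i, 3, length(xs)), xs, zs)
  expect_error(lateral_fwhm(flat, c(0, 10)), "unmeasurable")
})

test_that("peak sidelobe: sinc oracle, single lobe, two-lobe case", {
  # uniform-aperture far-field pattern ~ |sinc|: first sidelobe -13.26 dB
  u <- seq(-4, 4, by = 0.001)
  af <- abs(sin(pi * u) / (pi * u)); af[u == 0] <- 1
  expect_equal(peak_sidelobe_db(af), -13.26, tolerance = 0.01)

  single <- exp(-seq(-3, 3, by = 0.1)^2)
  expect_identical(peak_sidelobe_db(single), -Inf)

  two <- c(0.01, 0.5, 1, 0.5, 0.01, 0.05, 0.1, 0.05, 0.01)
  expect_equal(peak_sidelobe_db(two), -20, tolerance = 1e-9)
})

test_that("benchmark report: table shape and consistency with direct metrics", {
  cfg <- standard_benchmark_config()
  # scaled-down configuration: tiny grids, sparse speckle (documented: this
  # test checks bookkeeping, not image quality)
  cfg$geometry$num_elements <- 16
  cfg$cyst$speckle_density <- 0.5
  cfg$cyst$grid <- list(x_positions = seq(-4, 4, by = 0.5),
                        z_positions = seq(14, 20, by = 0.5))
  # wide lateral span: the 16-element DAS beam is ~3 mm at this depth
  cfg$point$grid <- list(x_positions = seq(-4.5, 4.5, by = 0.25),
                         z_positions = seq(24.9, 25.1, by = 0.1))
  res <- benchmark_report(c("DAS", "SCB"), cfg, n_seeds = 2, seed = 5)
  expect_equal(nrow(res$runs), 4)                       # methods x seeds
  expect_equal(nrow(res$medians), 2)
  expect_named(res$runs, c("method", "seed", "center_power_db",
                           "background_power_db", "contrast_db",
                           "resolution_fwhm_mm", "peak_sidelobe_db"))

  # one row equals the individually computed metrics
  one <- usbeam:::benchmark_one_seed("DAS", cfg, 5)
  row <- res$runs[res$runs$method == "DAS" & res$runs$seed == 5, ]
  expect_equal(row$contrast_db, one$DAS$contrast_db)
  expect_equal(row$resolution_fwhm_mm, one$DAS$resolution_fwhm_mm)

  csv <- tempfile(fileext = ".csv")
  benchmark_report("DAS", cfg, n_seeds = 1, seed = 5, csv = csv)
  expect_equal(nrow(read.csv(csv)), 1)
})
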