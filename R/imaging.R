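#' Rectangular image grid
#'
#' @param x_positions strictly increasing lateral pixel positions, mm.
#' @param z_positions strictly increasing depth pixel positions, mm (> 0).
#' @return an object of class `image_grid`.
#' @export
make_image_grid <- function(x_positions, z_positions) {
  if (any(diff(x_positions) <= 0)) stop_field("x_positions", "must be strictly increasing")
  if (any(diff(z_positions) <= 0)) stop_field("z_positions", "must be strictly increasing")
  if (any(z_positions <= 0)) stop_field("z_positions", "must be > 0 (below the array)")
  structure(list(x_positions = x_positions, z_positions = z_positions),
            class = "image_grid")
}

resolve_beamform_params <- function(geometry, params) {
  M <- geometry$num_elements
  defaults <- list(
    subarray_length = max(1L, floor(M / 2)),
    # ~ half the default 4-cycle pulse length in samples
    temporal_halfwidth = max(1L, round(2 * geometry$sampling_frequency /
                                         geometry$center_frequency)),
    loading_factor = NULL,          # filled below once L is known
    tau = NULL,                     # 0.1 * L
    threshold_factor = 0.5,
    dynamic_range = 60,
    rls_forgetting = 0.99,
    rls_init_delta = NULL,          # scaled to the data inside the loop
    ser_step = 0.05
  )
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown) > 0) {
    stop(sprintf("unknown beamforming parameter(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  p <- modifyList(defaults, params)
  p$subarray_length <- as.integer(p$subarray_length)
  if (p$subarray_length < 1 || p$subarray_length > M) {
    stop_field("subarray_length", sprintf("must be in 1..%d", M))
  }
  p$loading_factor <- p$loading_factor %||% (1 / (100 * p$subarray_length))
  p$tau <- p$tau %||% (0.1 * p$subarray_length)
  p
}

#' Beamform a full image
#'
#' Sweeps the chosen beamformer over every pixel of the grid with dynamic
#' receive focusing: per pixel, focusing delays are computed, a temporal
#' window of aligned snapshots is extracted, the subaperture-averaged
#' covariance is estimated (adaptive methods), weights are solved, and the
#' beamformed output is the weight response averaged over the sliding
#' subapertures of the central snapshot. DAS uses uniform `1/M` weights on
#' the full aperture. The result is deterministic given data and parameters.
#'
#' @param channel_data a `channel_data`; real RF input is converted with
#'   [analytic_signal()] first.
#' @param grid an `image_grid` inside the recorded time support.
#' @param method one of `"DAS"`, `"SCB"`, `"ISCB"`, `"RLS"`, `"SER"`.
#' @param params named list overriding the adaptive defaults:
#'   `subarray_length` (L, default `floor(M/2)`), `temporal_halfwidth`
#'   (samples, default ~half a pulse), `loading_factor` (default
#'   `1/(100 L)`), `tau` (default `0.1 L`), `threshold_factor` (0.5),
#'   `dynamic_range` (60 dB), `rls_forgetting`, `rls_init_delta`,
#'   `ser_step`.
#' @return an object of class `beamformed_image` with fields
#'   `complex_values` (nz x nx), `bmode_db`, `dynamic_range`, `method`,
#'   `grid`.
#' @export
beamform_image <- function(channel_data, grid,
                           method = c("DAS", "SCB", "ISCB", "RLS", "SER"),
                           params = list()) {
  method <- match.arg(method)
  beamform_methods(channel_data, grid, method, params)[[method]]
}

#' Beamform one dataset with several methods at once
#'
#' Shares the per-pixel focusing, snapshot extraction and covariance
#' estimation across methods, so comparing beamformers on the same data
#' costs little more than the most expensive single method.
#'
#' @inheritParams beamform_image
#' @param methods character vector of methods (see [beamform_image()]).
#' @return named list of `beamformed_image` objects.
#' @export
beamform_methods <- function(channel_data, grid, methods, params = list()) {
  valid <- c("DAS", "SCB", "ISCB", "RLS", "SER")
  bad <- setdiff(methods, valid)
  if (length(bad) > 0) {
    stop(sprintf("unknown method(s) %s; valid methods are %s",
                 paste(bad, collapse = ", "), paste(valid, collapse = ", ")),
         call. = FALSE)
  }
  stopifnot(inherits(channel_data, "channel_data"), inherits(grid, "image_grid"))
  cd <- if (is.complex(channel_data$samples)) channel_data else
    suppressMessages(analytic_signal(channel_data))

  geom <- cd$geometry
  M <- geom$num_elements
  fs <- cd$sampling_frequency
  c0 <- geom$sound_speed
  p <- resolve_beamform_params(geom, params)
  L <- p$subarray_length
  h <- as.integer(p$temporal_halfwidth)
  G <- M - L + 1L
  K <- 2L * h + 1L
  adaptive <- setdiff(methods, "DAS")

  # linear-index patterns into the M x K snapshot matrix
  sub1 <- as.vector(outer(seq_len(L), seq_len(G) - 1L, "+"))   # one column
  subfull <- rep(sub1, K) + rep((seq_len(K) - 1L) * M, each = L * G)
  subctr <- sub1 + h * M                                        # center column
  lam0 <- rep(1 + 0i, L)

  nx <- length(grid$x_positions); nz <- length(grid$z_positions)
  Q <- lapply(methods, function(m) matrix(0i, nz, nx))
  names(Q) <- methods
  ex <- element_positions(geom)

  for (ix in seq_len(nx)) {
    x <- grid$x_positions[ix]
    for (iz in seq_len(nz)) {
      z <- grid$z_positions[iz]
      fd <- compute_focus_delays(geom, c(x, z))
      r_min_t <- (z + min(sqrt((ex - x)^2 + z^2))) * 1e-3 / c0
      tidx <- (r_min_t - cd$time_origin) * fs + 1
      snap <- extract_snapshot_matrix(cd, fd, tidx, temporal_halfwidth = h)

      if (length(adaptive) > 0) {
        X <- matrix(snap[subfull], nrow = L)
        Fm <- hermitize(X %*% Conj(t(X)) / ncol(X))
        Fl <- Fm + p$loading_factor * (Re(sum(diag(Fm))) / L + 1e-300) * diag(L)
        Wc <- matrix(snap[subctr], nrow = L)
      }
      for (m in methods) {
        q <- switch(m,
          DAS = mean(snap[, h + 1L]),
          SCB = subap_output(scb_weights(Fl, lam0)$weights, Wc),
          ISCB = subap_output(
            iscb_weights(Fl, lam0, tau = p$tau,
                         threshold_factor = p$threshold_factor)$weights, Wc),
          RLS = subap_output(
            rls_weights(X, lam0, forgetting_factor = p$rls_forgetting,
                        init_delta = p$rls_init_delta %||%
                          max(1e-12, 0.01 * mean(Mod(X)^2) * L))$weights, Wc),
          SER = subap_output(ser_weights(X, lam0, step_size = p$ser_step)$weights, Wc)
        )
        Q[[m]][iz, ix] <- q
      }
    }
  }
  out <- Map(function(cv, m) new_beamformed_image(cv, p$dynamic_range, m, grid),
             Q, names(Q))
  out[methods]
}

subap_output <- function(w, Wc) mean(colSums(Conj(w) * Wc))

new_beamformed_image <- function(complex_values, dynamic_range, method, grid) {
  structure(list(complex_values = complex_values,
                 bmode_db = envelope_log_compress(complex_values, dynamic_range),
                 dynamic_range = dynamic_range,
                 method = method,
                 grid = grid),
            class = "beamformed_image")
}

#' @export
print.beamformed_image <- function(x, ...) {
  cat(sprintf("%s B-mode image: %d x %d pixels, %g dB dynamic range\n",
              x$method, nrow(x$bmode_db), ncol(x$bmode_db), x$dynamic_range))
  invisible(x)
}

#' Envelope detection and log compression
#'
#' `20 log10(|Q| / max |Q|)`, clipped below at `-dynamic_range`. The peak
#' pixel maps to exactly 0 dB.
#'
#' @param complex_values complex (or real) matrix of beamformed outputs.
#' @param dynamic_range display range in dB (> 0).
#' @return numeric matrix of the same shape, values in `[-dynamic_range, 0]`.
#' @export
envelope_log_compress <- function(complex_values, dynamic_range = 60) {
  if (dynamic_range <= 0) stop_field("dynamic_range", "must be > 0")
  env <- Mod(complex_values)
  mx <- max(env)
  if (mx == 0) stop("all-zero image cannot be log-compressed", call. = FALSE)
  pmax(20 * log10(env / mx + .Machine$double.xmin), -dynamic_range)
}

#' Write a B-mode image as an ASCII PGM file
#'
#' Grayscale rendering: 0 dB maps to white (255), `-dynamic_range` to black
#' (0), affine in between with `round()` (banker's rounding: a -20 dB pixel
#' at 40 dB range maps to 127.5 and is written as 128). The plain-text PGM
#' (P2) format is used so output bytes are deterministic for identical
#' input.
#'
#' @param bmode_db a `beamformed_image` (its `bmode_db` and `dynamic_range`
#'   are used) or a numeric dB matrix.
#' @param path output file path (conventionally `.pgm`).
#' @param dynamic_range display range in dB; ignored when a
#'   `beamformed_image` is given.
#' @return the path, invisibly.
#' @export
render_pgm <- function(bmode_db, path, dynamic_range = 60) {
  if (inherits(bmode_db, "beamformed_image")) {
    dynamic_range <- bmode_db$dynamic_range
    bmode_db <- bmode_db$bmode_db
  }
  gray <- round(255 * pmin(pmax(1 + bmode_db / dynamic_range, 0), 1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(gray), nrow(gray)), "255",
               apply(gray, 1, paste, collapse = " ")),
             con, sep = "\n")
  invisible(path)
}

#' Read back an ASCII PGM file written by [render_pgm()]
#'
#' @param path a P2 PGM file.
#' @return integer matrix of gray levels.
#' @export
read_pgm <- function(path) {
  txt <- readLines(path)
  txt <- txt[!grepl("^#", txt)]
  vals <- scan(text = paste(txt[-1], collapse = " "), quiet = TRUE)
  wh <- vals[1:2]
  matrix(vals[-(1:3)], nrow = wh[2], ncol = wh[1], byrow = TRUE)
}
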