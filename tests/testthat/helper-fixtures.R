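# shared fixture builders for the test suite (everything generated in code)

tiny_geom <- function(M = 16, f0 = 5e6, fs = 40e6) {
  make_linear_array(M, 0.154, f0, fs)
}

tiny_pulse <- function(f0 = 5e6) make_pulse(f0, 0.6, 4)

# random Hermitian matrix (not necessarily PSD)
rand_hermitian <- function(L) {
  A <- matrix(rnorm(L * L) + 1i * rnorm(L * L), L)
  (A + Conj(t(A))) / 2
}

# random Hermitian PSD via B B^H
rand_psd <- function(L, rank = L) {
  B <- matrix(rnorm(L * rank) + 1i * rnorm(L * rank), L, rank)
  B %*% Conj(t(B)) / rank
}

# random positive-definite Hermitian (PSD + ridge)
rand_pd <- function(L) rand_psd(L) + diag(L) * 0.1

rand_steering <- function(L) {
  v <- rnorm(L) + 1i * rnorm(L)
  v / sqrt(sum(Mod(v)^2)) * sqrt(L)
}

# brute-force constrained minimizer of w^H F w s.t. w^H lam = 1, via BFGS on
# the real parametrization of the affine constraint set (independent oracle)
oracle_mvdr_power <- function(F, lam) {
  L <- length(lam)
  w0 <- lam / sum(Mod(lam)^2)
  N <- svd(cbind(lam), nu = L)$u[, -1, drop = FALSE]   # orthonormal basis of lam^perp
  fn <- function(u) {
    uc <- u[seq_len(L - 1)] + 1i * u[L:(2 * (L - 1))]
    w <- w0 + N %*% uc
    Re(Conj(t(w)) %*% F %*% w)
  }
  opt <- optim(rep(0, 2 * (L - 1)), fn, method = "BFGS",
               control = list(reltol = 1e-15, maxit = 2000))
  opt$value
}

# cheap end-to-end channel data: a couple of point targets, small array
tiny_channel_data <- function(noise_db = -Inf, seed = 1, M = 16) {
  geom <- tiny_geom(M)
  ph <- make_phantom(data.frame(x = c(0, 1), z = c(10, 12), amplitude = c(1, 0.5)))
  simulate_channel_data(geom, ph, tiny_pulse(), noise_db = noise_db, seed = seed)
}

# minimal run-config for CLI tests: 2 deterministic scatterers, small grid
tiny_cli_config <- function(path, method = "DAS", extra = list()) {
  cfg <- list(
    seed = 3L,
    geometry = list(num_elements = 16, pitch = 0.154, center_frequency = 5e6,
                    sampling_frequency = 40e6, sound_speed = 1540),
    phantom = list(type = "points",
                   scatterers = data.frame(x = c(0, 0.5), z = c(10, 11),
                                           amplitude = c(1, 0.7)),
                   noise_db = -40),
    beamformer = list(method = method),
    grid = list(x = c(-1, 1), z = c(9.5, 11.5), step = 0.25),
    metrics = list(dynamic_range = 60,
                   center_region = list(shape = "rect", center = c(0, 10),
                                        half_extents = c(0.5, 0.4)),
                   background_region = list(shape = "rect", center = c(0, 11.2),
                                            half_extents = c(0.5, 0.3))),
    benchmark = list(methods = c("DAS", "SCB"), n_seeds = 2)
  )
  cfg <- modifyList(cfg, extra)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, null = "null")
  path
}
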