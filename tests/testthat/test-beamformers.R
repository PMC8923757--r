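test_that("scb weights: closed forms and distortionless constraint", {
  lam <- c(1, 1 + 1i, 2 - 1i)
  w <- scb_weights(diag(3), lam)
  expect_equal(w$weights, lam / sum(Mod(lam)^2), tolerance = 1e-12)

  w2 <- scb_weights(diag(c(1, 4)), c(1, 1))
  expect_equal(w2$weights, c(0.8, 0.2) + 0i, tolerance = 1e-12)
  expect_equal(w2$output_power, 1 / 1.25, tolerance = 1e-12)

  set.seed(2)
  for (rep in 1:5) {
    F <- rand_pd(4); lam <- rand_steering(4)
    z <- scb_weights(F, lam)$weights
    expect_lt(Mod(sum(Conj(z) * lam) - 1), 1e-10)
  }

  near_sing <- diag(c(1, 1e-14))
  expect_error(scb_weights(near_sing, c(1, 1)), "loading")
})

test_that("eigen split obeys the half-maximum threshold rule", {
  s1 <- eigendecompose_subspace(diag(c(4, 1, 0.5)), 0.5)
  expect_equal(length(s1$signal_values), 1)
  expect_equal(s1$signal_values, 4)

  s2 <- eigendecompose_subspace(diag(c(4, 3, 1)), 0.5)
  expect_equal(s2$signal_values, c(4, 3))

  set.seed(4)
  for (rep in 1:10) {
    F <- rand_psd(5)
    sub <- eigendecompose_subspace(F, 0.5)
    vals <- eigen(F, symmetric = TRUE, only.values = TRUE)$values
    k_loop <- 0
    for (v in vals) if (v >= 0.5 * max(vals)) k_loop <- k_loop + 1
    expect_equal(length(sub$signal_values), k_loop)
    # orthonormality and exact reconstruction
    V <- cbind(sub$signal_vectors, sub$noise_vectors)
    expect_lt(max(Mod(Conj(t(V)) %*% V - diag(5))), 1e-10)
    rec <- sub$signal_vectors %*% diag(sub$signal_values, length(sub$signal_values)) %*%
      Conj(t(sub$signal_vectors)) +
      sub$noise_vectors %*% diag(sub$noise_values, length(sub$noise_values)) %*%
      Conj(t(sub$noise_vectors))
    expect_lt(max(Mod(rec - F)) / max(Mod(F)), 1e-10)
  }

  # subspace dimension is non-increasing in the threshold factor
  F <- rand_psd(6)
  ks <- vapply(seq(0.1, 0.9, by = 0.1), function(tf) {
    length(eigendecompose_subspace(F, tf)$signal_values)
  }, numeric(1))
  expect_true(all(diff(ks) <= 0))

  expect_error(eigendecompose_subspace(matrix(c(1, 2, 3, 4), 2)), "Hermitian")
})

test_that("steering correction: degeneracies and the worked 2-d case", {
  sub0 <- eigendecompose_subspace(diag(c(1, 1e-12)))
  lam_bar <- c(1, 1) + 0i

  st0 <- correct_steering_vector(sub0, lam_bar, tau = 0)
  expect_identical(st0$corrected, lam_bar)

  subz <- eigendecompose_subspace(matrix(0, 2, 2))
  stz <- correct_steering_vector(subz, lam_bar, tau = 0.5)
  expect_identical(stz$corrected, lam_bar)

  st <- correct_steering_vector(sub0, lam_bar, tau = 0.25)
  expect_equal(st$corrected, c(0.5, 1) + 0i, tolerance = 1e-6)
  expect_equal(st$beta, 1, tolerance = 1e-6)
  expect_equal(sum(Mod(st$corrected - lam_bar)^2), 0.25, tolerance = 1e-9)
})

test_that("steering correction activates the constraint when violated", {
  set.seed(6)
  for (rep in 1:20) {
    L <- 4
    sub <- eigendecompose_subspace(rand_psd(L), 0.5)
    lam_bar <- rand_steering(L)
    tau <- runif(1, 0.01, 0.5)
    st <- correct_steering_vector(sub, lam_bar, tau)
    resid <- sum(Mod(st$corrected - lam_bar)^2)
    expect_lte(resid, tau * (1 + 1e-9))
    Ws <- sub$signal_vectors
    d_unc <- sum(Mod(Conj(t(Ws)) %*% lam_bar)^2)
    if (d_unc > tau) {
      expect_equal(resid, tau, tolerance = 1e-6)
    }
  }
})

test_that("iscb reduces to scb for tau = 0 on persymmetric covariance", {
  # real symmetric Toeplitz: FB correction returns 2F, and Capon weights are
  # scale invariant, so ISCB with tau = 0 equals SCB on F
  Ft <- toeplitz(c(3, 1, 0.3, 0.1)) + diag(4) * 0.5
  lam <- rep(1 + 0i, 4)
  wi <- iscb_weights(Ft, lam, tau = 0)
  ws <- scb_weights(Ft, lam)
  expect_equal(wi$weights, ws$weights, tolerance = 1e-10)
  # distortionless w.r.t. the steering vector actually used
  expect_lt(Mod(sum(Conj(wi$weights) * wi$steering_used) - 1), 1e-10)
})

test_that("iscb suppresses an off-axis interferer at least as well as scb", {
  set.seed(12)
  L <- 8; n <- 200
  d <- seq_len(L) - 1
  sv <- function(th) exp(1i * pi * sin(th) * d)
  lam <- sv(0); vi <- sv(20 * pi / 180)
  pn <- 10^(-20 / 10); pint <- 10^(10 / 10)
  Rin <- pint * vi %*% Conj(t(vi)) + pn * diag(L)
  out <- t(vapply(seq_len(100), function(r) {
    s <- (rnorm(n) + 1i * rnorm(n)) / sqrt(2)
    ii <- sqrt(pint) * (rnorm(n) + 1i * rnorm(n)) / sqrt(2)
    N <- sqrt(pn) * matrix(rnorm(L * n) + 1i * rnorm(L * n), L, n) / sqrt(2)
    X <- lam %*% t(s) + vi %*% t(ii) + N
    F <- X %*% Conj(t(X)) / n
    Fl <- F + (1 / (100 * L)) * Re(sum(diag(F))) / L * diag(L)
    w_s <- scb_weights(Fl, lam)$weights
    w_i <- iscb_weights(Fl, lam)$weights
    c(scb = Re(Conj(t(w_s)) %*% Rin %*% w_s),
      iscb = Re(Conj(t(w_i)) %*% Rin %*% w_i))
  }, numeric(2)))
  expect_lte(median(out[, "iscb"]), median(out[, "scb"]))
})

test_that("rls: forgetting-factor-1 equivalence, rank-1 step, constraint", {
  set.seed(8)
  L <- 4; n <- 60
  X <- matrix(rnorm(L * n) + 1i * rnorm(L * n), L, n)
  lam <- rand_steering(L)
  delta <- 0.5

  w_rls <- rls_weights(X, lam, forgetting_factor = 1, init_delta = delta)
  R_acc <- delta * diag(L) + X %*% Conj(t(X))       # unnormalized: scale-free
  w_scb <- scb_weights(R_acc, lam)
  expect_equal(w_rls$weights, w_scb$weights, tolerance = 1e-8)
  expect_lt(Mod(sum(Conj(w_rls$weights) * lam) - 1), 1e-10)

  # single snapshot: hand-coded Sherman-Morrison oracle
  x <- X[, 1]
  P0 <- diag(L) / delta
  P1 <- P0 - (P0 %*% x %*% Conj(t(x)) %*% P0) / drop(1 + Re(Conj(t(x)) %*% P0 %*% x))
  y <- drop(P1 %*% lam)
  w_hand <- y / Re(sum(Conj(lam) * y))
  w1 <- rls_weights(X[, 1, drop = FALSE], lam, forgetting_factor = 1,
                    init_delta = delta)
  expect_equal(w1$weights, w_hand, tolerance = 1e-10)

  expect_error(rls_weights(matrix(0i, 3, 0), lam), "empty")
})

test_that("ser: white-noise convergence, zero step, constraint held", {
  set.seed(10)
  L <- 4
  lam <- rep(1 + 0i, L)
  # exactly-white deterministic stream (cycled basis vectors: sample
  # covariance is exactly proportional to I): converges to the limit oracle
  Xd <- diag(L)[, rep(seq_len(L), length.out = 5000)] + 0i
  # linearly annealed steps: the O(mu) cyclic orbit collapses onto the limit
  wd <- ser_weights(Xd, lam, step_size = 0.05 * (1 - seq_len(5000) / 5000))
  expect_equal(wd$weights, lam / sum(Mod(lam)^2), tolerance = 1e-3)

  # random white stream: same limit up to the ~1/sqrt(n) sampling floor
  X <- matrix(rnorm(L * 5000) + 1i * rnorm(L * 5000), L) / sqrt(2)
  w <- ser_weights(X, lam, step_size = 1 / (20 + seq_len(5000)))
  expect_equal(w$weights, lam / sum(Mod(lam)^2), tolerance = 0.05)
  expect_lt(Mod(sum(Conj(w$weights) * lam) - 1), 1e-10)

  w0 <- ser_weights(X[, 1:10], lam, step_size = 0)
  expect_identical(w0$weights, lam / sum(Mod(lam)^2))
})

test_that("adaptive weights are scale invariant in the covariance", {
  set.seed(14)
  F <- rand_pd(5); lam <- rand_steering(5)
  wi <- iscb_weights(F, lam)$weights
  for (cc in c(0.5, 2, 10)) {
    expect_equal(iscb_weights(cc * F, lam)$weights, wi, tolerance = 1e-10)
  }
})
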