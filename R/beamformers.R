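#' Standard Capon (MVDR) beamformer weights
#'
#' Minimizes the output power `w^H F w` subject to the distortionless
#' constraint `w^H lambda = 1`, with the closed-form solution
#' `Z = F^{-1} lambda / (lambda^H F^{-1} lambda)`. The minimized output
#' power is `1 / (lambda^H F^{-1} lambda)`.
#'
#' Weights are invariant to positive rescaling of `F`, which is why the
#' unhalved forward-backward sum of [forward_backward_correct()] is
#' harmless.
#'
#' @param F a `covariance_estimate` or positive-definite Hermitian matrix
#'   (apply diagonal loading first if the estimate may be rank-deficient).
#' @param steering steering (guidance) vector of length L, or a
#'   `steering_vector` object (its corrected vector is used).
#' @param method label stored on the result (default "SCB").
#' @return an object of class `beamformer_weights` with fields `weights`,
#'   `method`, `steering`, `output_power`.
#' @examples
#' w <- scb_weights(diag(c(1, 4)), c(1, 1))
#' w$weights  # (0.8, 0.2)
#' @export
scb_weights <- function(F, steering, method = "SCB") {
  Fm <- as_cov_matrix(F)
  st <- as_steering(steering, nrow(Fm))
  lam <- st$corrected
  if (nrow(Fm) != ncol(Fm) || length(lam) != nrow(Fm)) {
    stop("covariance and steering dimensions do not match", call. = FALSE)
  }
  if (all(Mod(lam) == 0)) stop_field("steering", "must be nonzero")
  if (rcond(Fm) < 1e-12) {
    stop("covariance is singular or ill-conditioned (rcond < 1e-12); increase diagonal loading",
         call. = FALSE)
  }
  x <- solve(Fm, lam)
  denom <- Re(sum(Conj(lam) * x))          # lambda^H F^-1 lambda, real for Hermitian F
  if (denom <= 0) {
    stop("covariance is not positive definite along the steering direction", call. = FALSE)
  }
  new_beamformer_weights(x / denom, method, st, output_power = 1 / denom)
}

new_beamformer_weights <- function(w, method, steering, output_power = NA_real_) {
  if (!all(is.finite(Re(w))) || !all(is.finite(Im(w)))) {
    stop("non-finite beamformer weights", call. = FALSE)
  }
  structure(list(weights = as.complex(w),
                 method = method,
                 steering = steering,
                 output_power = output_power),
            class = "beamformer_weights")
}

#' @export
print.beamformer_weights <- function(x, ...) {
  cat(sprintf("%s weights, length %d, |Z^H lambda - 1| = %.2g\n",
              x$method, length(x$weights),
              Mod(sum(Conj(x$weights) * x$steering$corrected) - 1)))
  invisible(x)
}

#' Eigen split of a covariance into signal and noise subspaces
#'
#' Eigendecomposes a Hermitian covariance and partitions eigenpairs at
#' `threshold_factor` times the largest eigenvalue: eigenvalues at or above
#' the threshold span the signal(+interference) subspace `Ws`, the rest the
#' noise subspace `Wm`. The largest eigenvalue always qualifies, so the
#' signal subspace dimension k is >= 1; ties at the threshold go to the
#' signal side.
#'
#' @param F a `covariance_estimate` or Hermitian matrix.
#' @param threshold_factor fraction of the maximum eigenvalue in (0, 1]
#'   (default 0.5).
#' @return an object of class `subspace_decomposition` with fields
#'   `signal_vectors` (L x k), `signal_values` (descending),
#'   `noise_vectors`, `noise_values`, `threshold_factor`.
#' @export
eigendecompose_subspace <- function(F, threshold_factor = 0.5) {
  Fm <- as_cov_matrix(F)
  if (nrow(Fm) != ncol(Fm) || !is_hermitian(Fm)) {
    stop("input covariance must be square Hermitian", call. = FALSE)
  }
  if (!is.numeric(threshold_factor) || threshold_factor <= 0 || threshold_factor > 1) {
    stop_field("threshold_factor", "must lie in (0, 1]")
  }
  eg <- eigen(hermitize(Fm), symmetric = TRUE)   # values descending
  vals <- eg$values
  k <- sum(vals >= threshold_factor * vals[1])
  k <- max(k, 1L)
  L <- length(vals)
  V <- eg$vectors
  if (!is.complex(V)) V <- V + 0i
  structure(list(signal_vectors = V[, seq_len(k), drop = FALSE],
                 signal_values = vals[seq_len(k)],
                 noise_vectors = V[, setdiff(seq_len(L), seq_len(k)), drop = FALSE],
                 noise_values = vals[setdiff(seq_len(L), seq_len(k))],
                 threshold_factor = threshold_factor),
            class = "subspace_decomposition")
}

#' @export
print.subspace_decomposition <- function(x, ...) {
  cat(sprintf("subspace decomposition: k = %d signal / %d noise (threshold %.2f x max)\n",
              length(x$signal_values), length(x$noise_values), x$threshold_factor))
  invisible(x)
}

#' Quadratically constrained steering-vector correction
#'
#' Solves `min_lambda  lambda^H A lambda  s.t.  ||lambda - lambda_bar||^2 <= tau`
#' with `A = Ws Pi_s Ws^H` the signal-subspace energy operator, by the
#' Lagrange stationarity solution `lambda(beta) = (I + A/beta)^{-1} lambda_bar`.
#' In the signal eigenbasis the constraint residual
#' `d(beta) = sum_i |a_i|^2 (pi_i / (beta + pi_i))^2`, with
#' `a = Ws^H lambda_bar`, is strictly decreasing in `beta`, so the Lagrange
#' multiplier is found by bisection (monotone root bracketing on log beta)
#' when the unconstrained minimizer (projection onto the orthogonal
#' complement of `Ws`) violates the constraint. Degenerate cases return the
#' nominal vector unchanged: `tau = 0`, zero signal energy (`A = 0`), or
#' `A lambda_bar = 0`.
#'
#' @param subspace a `subspace_decomposition` (or a list with
#'   `signal_vectors`, `signal_values`).
#' @param nominal the preset (nominal) steering vector `lambda_bar`.
#' @param tau squared-norm error bound, >= 0.
#' @return an object of class `steering_vector` with fields `nominal`,
#'   `corrected`, `tau`, `beta` (Lagrange multiplier; `Inf` in the
#'   degenerate cases, 0 when the constraint is inactive).
#' @examples
#' sub <- eigendecompose_subspace(diag(c(1, 1e-12)))
#' correct_steering_vector(sub, c(1, 1), tau = 0.25)$corrected  # ~ (0.5, 1)
#' @export
correct_steering_vector <- function(subspace, nominal, tau) {
  if (!is.numeric(tau) || length(tau) != 1 || tau < 0) {
    stop_field("tau", "must be a single number >= 0")
  }
  lam_bar <- as.complex(nominal)
  Ws <- subspace$signal_vectors
  pis <- subspace$signal_values
  if (tau == 0 || length(pis) == 0 || all(pis <= 0)) {
    return(new_steering_vector(lam_bar, lam_bar, tau, beta = Inf))
  }
  keep <- pis > 0
  Ws <- Ws[, keep, drop = FALSE]
  pis <- pis[keep]
  a <- drop(Conj(t(Ws)) %*% lam_bar)
  aa <- Mod(a)^2
  if (sum(aa) == 0) {
    # lambda_bar already orthogonal to the signal subspace: objective is 0
    return(new_steering_vector(lam_bar, lam_bar, tau, beta = Inf))
  }
  d0 <- sum(aa)   # residual of the unconstrained minimizer (beta -> 0+)
  if (d0 <= tau) {
    lam <- lam_bar - drop(Ws %*% a)
    return(new_steering_vector(lam_bar, lam, tau, beta = 0))
  }
  # constraint is active: bisect d(beta) = tau on log(beta)
  dfun <- function(logb) {
    b <- exp(logb)
    sum(aa * (pis / (b + pis))^2) - tau
  }
  pmax_ <- max(pis)
  lo <- log(1e-12 * pmax_); hi <- log(1e12 * pmax_)
  flo <- dfun(lo); fhi <- dfun(hi)
  tries <- 0
  while (flo * fhi > 0 && tries < 8) {     # expand bracket if ever needed
    lo <- lo - 10; hi <- hi + 10
    flo <- dfun(lo); fhi <- dfun(hi)
    tries <- tries + 1
  }
  if (flo * fhi > 0) {
    stop(sprintf("failed to bracket the Lagrange multiplier: d(lo)=%.3g, d(hi)=%.3g, tau=%.3g",
                 flo + tau, fhi + tau, tau), call. = FALSE)
  }
  root <- uniroot(dfun, c(lo, hi), tol = 1e-13)
  beta <- exp(root$root)
  shrink <- pis / (beta + pis)
  lam <- lam_bar - drop(Ws %*% (a * shrink))
  new_steering_vector(lam_bar, lam, tau, beta = beta)
}

new_steering_vector <- function(nominal, corrected, tau, beta) {
  resid <- sum(Mod(corrected - nominal)^2)
  if (resid > tau + 1e-9 * max(1, tau)) {
    stop(sprintf("internal error: corrected steering violates the constraint (%.3g > %.3g)",
                 resid, tau), call. = FALSE)
  }
  structure(list(nominal = as.complex(nominal),
                 corrected = as.complex(corrected),
                 tau = tau, beta = beta),
            class = "steering_vector")
}

as_steering <- function(steering, L) {
  if (inherits(steering, "steering_vector")) return(steering)
  lam <- as.complex(steering)
  if (length(lam) != L) {
    stop(sprintf("steering length %d does not match dimension %d", length(lam), L),
         call. = FALSE)
  }
  new_steering_vector(lam, lam, tau = 0, beta = Inf)
}

#' Improved standard Capon beamformer (ISCB) weights
#'
#' The full robust pipeline: (1) forward-backward correction of the raw
#' covariance; (2) eigen split of the corrected covariance at
#' `threshold_factor` times the maximum eigenvalue; (3) quadratically
#' constrained correction of the nominal steering vector against the
#' signal-subspace energy; (4) renormalization of the corrected steering to
#' `||lambda|| = sqrt(L)` (removing the power ambiguity the correction
#' introduces); (5) Capon weights on the corrected covariance.
#'
#' @param F_raw a `covariance_estimate` or Hermitian positive-definite
#'   matrix (diagonal loading applied upstream).
#' @param nominal nominal steering vector `lambda_bar`, length L.
#' @param tau squared-norm uncertainty bound; default `0.1 * L`.
#' @param threshold_factor signal/noise eigenvalue split point (default 0.5).
#' @return a `beamformer_weights` with method "ISCB"; its `steering` field
#'   holds the pre-normalization corrected vector (so the constraint
#'   `||corrected - nominal||^2 <= tau` is meaningful) and `steering_used`
#'   the renormalized vector actually passed to the Capon solver.
#' @export
iscb_weights <- function(F_raw, nominal, tau = NULL, threshold_factor = 0.5) {
  Ffb <- forward_backward_correct(F_raw)
  Fm <- as_cov_matrix(Ffb)
  L <- nrow(Fm)
  lam_bar <- as.complex(nominal)
  if (length(lam_bar) != L) {
    stop(sprintf("steering length %d does not match covariance dimension %d",
                 length(lam_bar), L), call. = FALSE)
  }
  tau <- tau %||% (0.1 * L)
  sub <- eigendecompose_subspace(Fm, threshold_factor)
  st <- correct_steering_vector(sub, lam_bar, tau)
  lam <- st$corrected
  nrm <- sqrt(sum(Mod(lam)^2))
  if (nrm == 0) stop("corrected steering vector is zero; decrease tau", call. = FALSE)
  lam_used <- lam * sqrt(L) / nrm
  w <- scb_weights(Fm, lam_used, method = "ISCB")
  w$steering <- st
  w$steering_used <- lam_used
  w$subspace <- sub
  w
}

#' Recursive least squares (RLS) adaptive weights
#'
#' Standard textbook baseline: the inverse of the exponentially weighted
#' sample covariance is propagated by the matrix inversion lemma
#' (`P_0 = I / init_delta`, update with forgetting factor `mu`), and Capon
#' normalization is applied at the end. With `forgetting_factor = 1` the
#' result equals [scb_weights()] on `init_delta * I + sum_t x_t x_t^H`.
#'
#' @param snapshots L x n matrix of snapshots (columns in arrival order),
#'   or anything [estimate_covariance()] accepts.
#' @param steering steering vector, length L.
#' @param forgetting_factor in (0, 1].
#' @param init_delta initial diagonal loading of the covariance (> 0).
#' @return a `beamformer_weights` with method "RLS".
#' @export
rls_weights <- function(snapshots, steering, forgetting_factor = 0.99,
                        init_delta = 1e-2) {
  X <- as_snapshot_matrix(snapshots)
  if (ncol(X) == 0) stop("empty snapshot stream", call. = FALSE)
  if (forgetting_factor <= 0 || forgetting_factor > 1) {
    stop_field("forgetting_factor", "must lie in (0, 1]")
  }
  if (init_delta <= 0) stop_field("init_delta", "must be > 0")
  L <- nrow(X)
  st <- as_steering(steering, L)
  lam <- st$corrected
  ff <- forgetting_factor
  P <- diag(L) / init_delta + 0i
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    Px <- P %*% x
    denom <- ff + Re(sum(Conj(x) * Px))
    g <- Px / denom
    P <- (P - g %*% (Conj(t(x)) %*% P)) / ff
    P <- hermitize(P)
  }
  y <- drop(P %*% lam)
  denom <- Re(sum(Conj(lam) * y))
  new_beamformer_weights(y / denom, "RLS", st, output_power = 1 / denom)
}

#' Sequential regression (SER) adaptive weights
#'
#' Standard stochastic-gradient baseline for the constrained minimum-power
#' problem: starting from `w = lambda / ||lambda||^2`, each snapshot applies
#' a (normalized) gradient step `w <- w - mu_t x (x^H w)` followed by exact
#' re-projection onto the distortionless constraint `w^H lambda = 1`. On
#' stationary white noise the iteration converges to the `F = I` Capon
#' solution `lambda / ||lambda||^2`.
#'
#' @param snapshots L x n matrix of snapshots (columns in arrival order).
#' @param steering steering vector, length L.
#' @param step_size scalar step, or a vector of per-step sizes (recycled);
#'   steps are normalized by the snapshot power (`mu_t = step_size /
#'   (x^H x + eps)`). Zero leaves the initialization untouched.
#' @return a `beamformer_weights` with method "SER".
#' @export
ser_weights <- function(snapshots, steering, step_size = 0.05) {
  X <- as_snapshot_matrix(snapshots)
  if (ncol(X) == 0) stop("empty snapshot stream", call. = FALSE)
  L <- nrow(X)
  st <- as_steering(steering, L)
  lam <- st$corrected
  lam2 <- sum(Mod(lam)^2)
  mu <- rep_len(step_size, ncol(X))
  w <- lam / lam2
  eps <- .Machine$double.eps
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    if (mu[j] != 0) {
      w <- w - (mu[j] / (Re(sum(Conj(x) * x)) + eps)) * x * sum(Conj(x) * w)
      w <- w + lam * Conj(1 - sum(Conj(w) * lam)) / lam2
    }
  }
  new_beamformer_weights(w, "SER", st)
}
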