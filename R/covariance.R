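#' Interference-plus-noise covariance estimate
#'
#' Sample covariance of aligned snapshots with sliding-subaperture (spatial
#' smoothing) and temporal averaging, plus optional diagonal loading:
#'
#' `F = mean_{g,k} s_{g,k} s_{g,k}^H + loading_factor * (tr(F)/L) * I`
#'
#' where `s_{g,k}` is the length-L window starting at element g of the
#' snapshot at temporal offset k. Subaperture averaging restores rank
#' against coherent echoes; loading guarantees invertibility.
#'
#' @param snapshots an M x n matrix of aligned snapshots (columns = temporal
#'   offsets), a single `snapshot`, or a vector.
#' @param subarray_length window length L, 1 <= L <= M (default M: no
#'   smoothing).
#' @param temporal_halfwidth only columns within this many columns of the
#'   central column are averaged (default `Inf`: all columns).
#' @param loading_factor diagonal loading as a fraction of the mean
#'   eigenvalue `tr(F)/L` (>= 0).
#' @return an object of class `covariance_estimate` with fields `matrix`
#'   (Hermitian L x L), `subarray_length`, `temporal_halfwidth`,
#'   `loading_factor`, `corrected` (FALSE).
#' @export
estimate_covariance <- function(snapshots, subarray_length = NULL,
                                temporal_halfwidth = Inf, loading_factor = 0) {
  S <- as_snapshot_matrix(snapshots)
  M <- nrow(S); n <- ncol(S)
  if (n < 1) stop("need at least one snapshot", call. = FALSE)
  L <- as.integer(subarray_length %||% M)
  if (L < 1 || L > M) {
    stop_field("subarray_length", sprintf("must be in 1..%d, got %d", M, L))
  }
  if (loading_factor < 0) stop_field("loading_factor", "must be >= 0")
  if (all(Mod(S) == 0)) {
    stop("all snapshots are zero: covariance is degenerate, not estimated", call. = FALSE)
  }
  ctr <- (n + 1) / 2
  S <- S[, abs(seq_len(n) - ctr) <= temporal_halfwidth, drop = FALSE]
  if (ncol(S) == 0) {
    stop("temporal_halfwidth excludes every snapshot column", call. = FALSE)
  }
  X <- subarray_stack(S, L)
  Fm <- hermitize(X %*% Conj(t(X)) / ncol(X))
  if (loading_factor > 0) {
    Fm <- Fm + loading_factor * (Re(sum(diag(Fm))) / L) * diag(L)
  }
  new_covariance_estimate(Fm, L, temporal_halfwidth, loading_factor,
                          corrected = FALSE)
}

# stack all length-L sliding windows of every column of S into an L x (G*n)
# matrix, G = M - L + 1 subapertures
subarray_stack <- function(S, L) {
  M <- nrow(S); n <- ncol(S); G <- M - L + 1L
  idx <- as.vector(outer(seq_len(L), seq_len(G) - 1L, "+"))  # L*G row indices
  full <- rep(idx, n) + rep((seq_len(n) - 1L) * M, each = L * G)
  matrix(S[full], nrow = L)
}

as_snapshot_matrix <- function(snapshots) {
  if (inherits(snapshots, "snapshot")) return(cbind(snapshots$values))
  if (is.matrix(snapshots)) return(snapshots)
  if (is.numeric(snapshots) || is.complex(snapshots)) return(cbind(snapshots))
  if (is.list(snapshots)) {
    return(do.call(cbind, lapply(snapshots, function(s) {
      if (inherits(s, "snapshot")) s$values else s
    })))
  }
  stop("cannot interpret 'snapshots'", call. = FALSE)
}

new_covariance_estimate <- function(Fm, L, halfwidth, loading, corrected) {
  structure(list(matrix = Fm,
                 subarray_length = L,
                 temporal_halfwidth = halfwidth,
                 loading_factor = loading,
                 corrected = corrected),
            class = "covariance_estimate")
}

as_cov_matrix <- function(F) {
  if (inherits(F, "covariance_estimate")) F$matrix else as.matrix(F)
}

#' @export
print.covariance_estimate <- function(x, ...) {
  cat(sprintf("covariance estimate: %dx%d, loading %.3g, %s\n",
              nrow(x$matrix), ncol(x$matrix), x$loading_factor,
              if (x$corrected) "forward-backward corrected" else "uncorrected"))
  invisible(x)
}

#' Forward-backward (Toeplitz) covariance correction
#'
#' Returns `F + K conj(F) K`, where `K` is the exchange matrix (ones on the
#' anti-diagonal) and `conj` is elementwise complex conjugation. The backward
#' term is the covariance of the conjugated, element-reversed array, so the
#' sum decorrelates coherent sources and is persymmetric
#' (`K conj(F') K = F'`). Note the sum is deliberately not halved; Capon
#' weights are invariant to a positive scaling of the covariance, so the
#' missing 1/2 of conventional forward-backward averaging has no effect on
#' any beamformer output.
#'
#' @param F a `covariance_estimate` or square Hermitian matrix.
#' @return same type as the input, marked `corrected`; for a plain matrix, a
#'   matrix.
#' @export
forward_backward_correct <- function(F) {
  Fm <- as_cov_matrix(F)
  if (nrow(Fm) != ncol(Fm)) stop("covariance must be square", call. = FALSE)
  rev_idx <- rev(seq_len(nrow(Fm)))
  Ffb <- Fm + Conj(Fm)[rev_idx, rev_idx, drop = FALSE]
  if (inherits(F, "covariance_estimate")) {
    new_covariance_estimate(Ffb, F$subarray_length, F$temporal_halfwidth,
                            F$loading_factor, corrected = TRUE)
  } else {
    Ffb
  }
}
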