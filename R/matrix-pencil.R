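#' Build the Hankel matrix pencil of a signal
#'
#' Forms the `(N - p) x (p + 1)` Hankel matrix `Y[i, j] = x[i + j - 1]` and
#' its two column-shifted submatrices: `Y1` (drop the last column) and `Y2`
#' (drop the first). The family `Y2 - lambda * Y1` is the matrix pencil
#' whose generalized eigenvalues are the signal poles.
#'
#' @param x Signal vector.
#' @param p Pencil parameter, `1 <= p <= N - 1`.
#' @return A list of class `"pencil_system"` with fields `Y`, `Y1`, `Y2`,
#'   `n`, `p`.
#' @examples
#' build_pencil(1:5, 2)$Y  # 3 x 3 Hankel
#' @export
build_pencil <- function(x, p) {
  p <- check_order(p)
  n <- length(x)
  if (p > n - 1L) {
    abort(sprintf("pencil parameter must satisfy 1 <= p <= N - 1 (N = %d, p = %d).",
                  n, p),
          class = "pronyfit_error_usage")
  }
  idx <- outer(seq_len(n - p), seq_len(p + 1L), `+`) - 1L
  Y <- matrix(x[idx], nrow = n - p, ncol = p + 1L)
  structure(
    list(Y = Y, Y1 = Y[, seq_len(p), drop = FALSE],
         Y2 = Y[, 1L + seq_len(p), drop = FALSE], n = n, p = p),
    class = "pencil_system"
  )
}

#' Signal poles from a matrix pencil
#'
#' The poles are the eigenvalues of \eqn{Y_1^{+} Y_2}, with the
#' Moore-Penrose pseudoinverse computed by SVD truncated at the
#' signal-subspace threshold `sqrt(eps) * sigma_1` (~`1.5e-8`), the
#' conservative rank rule customary for matrix-pencil estimation of
#' closely spaced modes. (The generalized QZ route on `Y2 - lambda Y1` is
#' deliberately avoided: the pencil matrices are ill-conditioned and QZ
#' is not stable enough here.)
#'
#' For a noiseless signal that is a sum of `M` distinct exponentials with
#' `M <= p <= N - M`, exactly `M` eigenvalues match the true poles and the
#' remaining `p - M` vanish. Eigenvalues with modulus at or below
#' `1e-8 * max(|lambda|)` are snapped to exact zero ("zero poles", reported
#' with `damping = -Inf`); the count of the others is the effective rank.
#'
#' @param sys A `"pencil_system"` from [build_pencil()].
#' @return A list of class `"pencil_poles"`: `poles` (complex, length `p`),
#'   `rank` (effective rank `r`), `n_zero` (`p - r`).
#' @examples
#' pencil_poles(build_pencil(2^(0:4), 1))$poles  # 2
#' @export
pencil_poles <- function(sys) {
  if (!inherits(sys, "pencil_system")) {
    abort("`sys` must come from build_pencil().",
          class = "pronyfit_error_usage")
  }
  sv <- svd(sys$Y1)
  # signal-subspace truncation at sqrt(eps) ~ 1.5e-8 relative to sigma_1:
  # directions below it carry no resolvable pole information but, kept,
  # are amplified by 1/sigma and scramble the eigenvalues (closely spaced
  # undamped poles make the Hankel spectrum decay gradually, so a
  # machine-precision cut is far too permissive there)
  tol <- sqrt(.Machine$double.eps) * sv$d[1L]
  rank_y1 <- sum(sv$d > tol)
  p <- sys$p
  if (rank_y1 == 0L) {
    lambda <- rep(0 + 0i, p)
  } else {
    keep <- seq_len(rank_y1)
    pinv <- sv$v[, keep, drop = FALSE] %*%
      (Conj(t(sv$u[, keep, drop = FALSE])) / sv$d[keep])
    lambda <- eigen(pinv %*% sys$Y2, only.values = TRUE)$values
    mods <- Mod(lambda)
    # rank(Y1+ Y2) <= rank(Y1), so at most rank_y1 eigenvalues are genuine
    # poles: the p - rank_y1 smallest-modulus ones are null-space artefacts
    # and are snapped to zero along with anything below the modulus
    # threshold.
    ord <- order(mods, decreasing = TRUE)
    zero <- logical(p)
    if (rank_y1 < p) zero[ord[(rank_y1 + 1L):p]] <- TRUE
    zero <- zero | mods <= 1e-8 * max(mods)
    lambda[zero] <- 0 + 0i
  }
  zero_n <- sum(Mod(lambda) == 0)
  structure(
    list(poles = lambda, rank = p - zero_n, n_zero = zero_n),
    class = "pencil_poles"
  )
}
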