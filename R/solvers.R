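#' Solve a linear system exactly or in the least-squares sense
#'
#' Internal workhorse for the two linear steps of the polynomial Prony
#' method. With `strategy = "classic"` the matrix must be square and
#' non-singular and the system is solved exactly (LU). With
#' `strategy = "ls"` an overdetermined (or square) system is solved in the
#' minimum-residual sense by rank-revealing QR with matrix left-division
#' semantics: columns judged numerically dependent receive exactly zero
#' coefficients (a *basic* solution), and the normal equations are never
#' formed. Real systems go through R's standard LINPACK path (as `lm()`
#' does) at its conventional relative tolerance `1e-7`; complex systems
#' are column-equilibrated (max-abs scaling) and solved by LAPACK
#' column-pivoted QR with the machine-precision rank rule
#' `max(m, n) * eps * |R[1, 1]|`, so rank decisions are independent of the
#' wildly different column scales that pole-power matrices carry.
#'
#' @param A Real or complex matrix with `nrow(A) >= ncol(A)`.
#' @param b Right-hand-side vector, `length(b) == nrow(A)`.
#' @param strategy `"classic"` for an exact square solve, `"ls"` for a
#'   QR least-squares solve.
#' @return Numeric or complex coefficient vector of length `ncol(A)`.
#' @examples
#' solve_linear(diag(2), c(3, 4))
#' solve_linear(matrix(1, 2, 1), c(1, 3), strategy = "ls")  # LS mean
#' @export
solve_linear <- function(A, b, strategy = c("ls", "classic")) {
  strategy <- match.arg(strategy)
  A <- as.matrix(A)
  b <- as.vector(b)
  m <- nrow(A)
  n <- ncol(A)
  if (length(b) != m) {
    abort("`b` must have one entry per row of `A`.",
          class = "pronyfit_error_usage")
  }
  if (m < n) {
    abort("`A` must have at least as many rows as columns.",
          class = "pronyfit_error_usage")
  }
  if (strategy == "classic") {
    if (m != n) {
      abort("strategy \"classic\" requires a square matrix.",
            class = "pronyfit_error_usage")
    }
    out <- tryCatch(
      solve(A, b),
      error = function(e) {
        kappa_est <- tryCatch(kappa(A, exact = FALSE), error = function(e2) Inf)
        abort(
          sprintf("square system is numerically singular (condition ~ %.3g).",
                  kappa_est),
          class = "pronyfit_error_singular",
          condition_number = kappa_est
        )
      }
    )
    return(as.vector(out))
  }
  qr_basic_solve(A, b)
}

# Rank-revealing QR least squares with left-division semantics: columns
# judged numerically dependent receive exactly zero coefficients -- a
# basic solution. Real systems go through R's standard LINPACK path (as
# lm() does) at its conventional relative tolerance 1e-7, which truncates
# decisively at the clean spectral gap of noiseless prediction systems.
# Complex systems are column-equilibrated and solved by LAPACK
# column-pivoted QR with the machine-precision rank rule
# max(m, n) * eps * |R[1, 1]| (the pseudoinverse convention); structurally
# dependent columns (e.g. repeated zero poles) drop out through it.
qr_basic_solve <- function(A, b, tol = NULL) {
  n <- ncol(A)
  if (!is.complex(A)) {
    coef <- qr.coef(qr(A, tol = tol %||% 1e-7), b)
    coef[is.na(coef)] <- 0
    return(as.vector(coef))
  }
  # Column equilibration (max-abs scaling) first: pole-power columns span
  # hundreds of orders of magnitude, and an unscaled rank rule would let
  # one huge column mask every well-scaled one. Scaling by the largest
  # modulus keeps clipped/overflowed columns finite; an all-zero column
  # keeps scale 1 and drops out through the rank rule.
  scale <- apply(abs(A), 2L, max)
  scale[scale == 0 | !is.finite(scale)] <- 1
  A <- sweep(A, 2L, scale, "/")
  qa <- qr(A, LAPACK = TRUE)
  R <- qr.R(qa)
  dR <- abs(diag(R))
  tol <- tol %||% (max(dim(A)) * .Machine$double.eps)
  r <- if (dR[1L] > 0) sum(dR >= tol * dR[1L]) else 0L
  coef <- complex(n)
  if (r == n) {
    coef <- qr.coef(qa, b)
  } else if (r > 0L) {
    qty <- qr.qty(qa, b)[seq_len(r)]
    head_coef <- solve(R[seq_len(r), seq_len(r), drop = FALSE], qty)
    coef[qa$pivot[seq_len(r)]] <- head_coef
  }
  as.vector(coef / scale)
}

#' Total least-squares solution of an overdetermined linear system
#'
#' Solves `A x ~ b` allowing perturbations in both `A` and `b`: the singular
#' value decomposition of the augmented matrix `C = [A : b]` is taken and the
#' solution is read off the last right singular vector,
#' `x = -v[1:n, n+1] / v[n+1, n+1]`. Non-finite entries of `A` and `b` are
#' clipped to the largest finite magnitude before the SVD.
#'
#' The solution exists only when the corner element `v[n+1, n+1]` is
#' non-zero; it is unique only when the two smallest singular values of `C`
#' are separated. A collapsed gap is reported in the `unique` field rather
#' than by a thrown condition so that batch callers can keep going.
#'
#' @param A Real or complex matrix, more rows than columns.
#' @param b Right-hand-side vector.
#' @return An object of class `"tls_solution"`: a list with fields
#'   `solution` (length-`ncol(A)` vector), `corner` (the `v[n+1, n+1]`
#'   element), `singular_values` (non-increasing singular values of the
#'   augmented matrix) and `unique` (`FALSE` when the relative gap between
#'   the two smallest singular values is below `1e-10`).
#' @examples
#' # Consistent system: TLS equals the exact solution
#' tls_solve(rbind(diag(2), 0), c(3, 4, 0))$solution
#' @export
tls_solve <- function(A, b) {
  A <- as.matrix(A)
  b <- as.vector(b)
  m <- nrow(A)
  n <- ncol(A)
  if (length(b) != m) {
    abort("`b` must have one entry per row of `A`.",
          class = "pronyfit_error_usage")
  }
  if (m <= n) {
    abort("TLS requires strictly more rows than columns.",
          class = "pronyfit_error_usage")
  }
  C <- cbind(clip_nonfinite(A), clip_nonfinite(b))
  sv <- svd(C, nu = 0, nv = n + 1L)
  v_last <- sv$v[, n + 1L]
  corner <- v_last[n + 1L]
  if (Mod(corner) < 1e-12) {
    abort("no TLS solution: corner element of the right singular matrix is zero.",
          class = "pronyfit_error_no_tls_solution")
  }
  d <- sv$d
  unique_sol <- TRUE
  if (length(d) >= n + 1L && d[n] > 0) {
    unique_sol <- (d[n] - d[n + 1L]) / d[n] >= 1e-10
  }
  structure(
    list(
      solution = as.vector(-v_last[seq_len(n)] / corner),
      corner = corner,
      singular_values = d,
      unique = unique_sol
    ),
    class = "tls_solution"
  )
}

#' @export
print.tls_solution <- function(x, ...) {
  cat("<tls_solution> n =", length(x$solution),
      if (!x$unique) "(non-unique: singular value gap collapsed)", "\n")
  cat("sigma: ", paste(signif(x$singular_values, 4), collapse = " "), "\n")
  invisible(x)
}

# Moore-Penrose pseudoinverse by SVD with the conventional numerical-rank
# tolerance max(dim) * eps * sigma_1.
pinv_svd <- function(A) {
  A <- as.matrix(A)
  sv <- svd(A)
  tol <- max(dim(A)) * .Machine$double.eps * sv$d[1L]
  keep <- sv$d > tol
  if (!any(keep)) {
    return(matrix(0, ncol(A), nrow(A)))
  }
  sv$v[, keep, drop = FALSE] %*%
    (Conj(t(sv$u[, keep, drop = FALSE])) / sv$d[keep])
}
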