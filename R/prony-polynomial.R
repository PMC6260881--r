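#' Build the forward linear-prediction system
#'
#' Step 1 of the polynomial Prony method writes the order-`p` autoregression
#' of the samples as a Toeplitz system `T a = -x[(p+1):N]` with
#' `T[i, j] = x[p + i - j]`, of shape `(N - p) x p` (square exactly when
#' `N = 2p`). Solving it yields the coefficients of the characteristic
#' polynomial.
#'
#' @param x Signal vector with `N >= 2p` samples.
#' @param p Model order.
#' @return A list of class `"lp_system"` with fields `T` (Toeplitz matrix),
#'   `rhs` (`-x[(p+1):N]`), `n`, `p`.
#' @examples
#' build_lp_system(c(1, 2, 3, 4), 2)$T  # rbind(c(2, 1), c(3, 2))
#' @export
build_lp_system <- function(x, p) {
  check_order(p)
  n <- length(x)
  if (n < 2 * p) {
    abort(sprintf("need N >= 2p samples (N = %d, p = %d).", n, p),
          class = "pronyfit_error_insufficient_data")
  }
  idx <- outer(p + seq_len(n - p), seq_len(p), `-`)
  T_mat <- matrix(x[idx], nrow = n - p, ncol = p)
  structure(
    list(T = T_mat, rhs = -x[(p + 1):n], n = n, p = as.integer(p)),
    class = "lp_system"
  )
}

check_order <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || p < 1 || p != round(p)) {
    abort("`p` must be a single integer >= 1.",
          class = "pronyfit_error_usage")
  }
  invisible(as.integer(p))
}

#' Roots of the characteristic (Prony) polynomial
#'
#' Given the linear-prediction coefficients `a[1..p]`, returns the `p` roots
#' of the monic polynomial
#' \eqn{z^p + a_1 z^{p-1} + \dots + a_p}, computed as the eigenvalues of the
#' balanced Frobenius companion matrix — the standard route of numerical
#' root finders. The result is an unordered multiset.
#'
#' @param a Coefficient vector (the implicit leading coefficient is 1).
#' @return Complex vector of `length(a)` roots.
#' @examples
#' sort(Re(characteristic_roots(c(-3, 2))))  # 1 2
#' @export
characteristic_roots <- function(a) {
  if (length(a) < 1L) {
    abort("`a` must have length >= 1.", class = "pronyfit_error_usage")
  }
  if (anyNA(a) || !all(is.finite(Re(a))) ||
      (is.complex(a) && !all(is.finite(Im(a))))) {
    abort("`a` must be finite.", class = "pronyfit_error_usage")
  }
  p <- length(a)
  if (p == 1L) {
    return(as.complex(-a))
  }
  C <- matrix(if (is.complex(a)) 0 + 0i else 0, p, p)
  C[1L, ] <- -a
  C[cbind(2:p, 1:(p - 1L))] <- 1
  eigen(C, only.values = TRUE)$values
}

#' Amplitude-and-phase step: solve the Vandermonde system for the weights
#'
#' Step 3 of both Prony families. Builds the `m x p` matrix
#' `Z[i, k] = z_k^(i-1)` (first row all ones; a zero pole's column is
#' `c(1, 0, 0, ...)`), solves `Z h = x[1:m]` with the requested strategy and
#' derives `amp = |h|`, `phase = atan2(Im h, Re h)`. Entries of `Z` that
#' overflow to non-finite values are clipped to the largest finite
#' magnitude before the solve. The `"ls"` strategy here is column-pivoted
#' QR with left-division semantics (machine-precision rank rule, zero
#' weight on dependent columns), so repeated zero poles from rank-deficient
#' pencils are handled structurally.
#'
#' @param x Signal vector (at least `m` samples).
#' @param poles Complex pole vector (length `p`).
#' @param m Number of equations: `p` for the classic method, `N` for the
#'   overdetermined ones.
#' @param strategy `"classic"` (square solve), `"ls"` or `"tls"`.
#' @return A list of class `"vandermonde_system"` with fields `Z`, `rhs`,
#'   `weights` (complex `h`), `amp`, `phase`, `m`, `strategy` and
#'   `tls` (the [tls_solve()] result, TLS only).
#' @export
amplitude_step <- function(x, poles, m = length(x),
                           strategy = c("ls", "classic", "tls")) {
  strategy <- match.arg(strategy)
  poles <- as.complex(poles)
  p <- length(poles)
  if (p < 1L) {
    abort("`poles` must be non-empty.", class = "pronyfit_error_usage")
  }
  if (anyNA(poles) || !all(is.finite(Re(poles)) & is.finite(Im(poles)))) {
    abort("`poles` must be finite.", class = "pronyfit_error_usage")
  }
  if (m < p && strategy != "classic") {
    abort("`m` must be at least the number of poles.",
          class = "pronyfit_error_usage")
  }
  if (length(x) < m) {
    abort("`x` has fewer than `m` samples.",
          class = "pronyfit_error_insufficient_data")
  }
  Z <- vapply(poles, pole_powers, complex(m), m = m)
  Z <- clip_nonfinite(matrix(Z, nrow = m, ncol = p))
  rhs <- as.complex(x[seq_len(m)])
  tls <- NULL
  h <- switch(strategy,
    classic = solve_linear(Z, rhs, strategy = "classic"),
    # pivoted-QR left division: structurally dependent columns (repeated
    # zero poles from rank-deficient pencils) get zero weight
    ls = qr_basic_solve(Z, rhs),
    tls = {
      tls <- tls_solve(Z, rhs)
      tls$solution
    }
  )
  structure(
    list(Z = Z, rhs = rhs, weights = h, amp = Mod(h), phase = Arg(h),
         m = as.integer(m), strategy = strategy, tls = tls),
    class = "vandermonde_system"
  )
}

#' Fit a Prony decomposition to a uniformly sampled signal
#'
#' Decomposes `x` into `p` damped complex exponentials
#' \eqn{x[n] \approx \sum_k h_k z_k^{\,n-1}} by one of four estimators:
#'
#' * `"classic"` — the original interpolation method; requires `N = 2p`.
#'   Square Toeplitz solve, companion-matrix roots, square Vandermonde
#'   solve.
#' * `"ls"` — overdetermined variant (`N >= 2p`); both linear steps solved
#'   by column-pivoted QR least squares.
#' * `"tls"` — as `"ls"` but both linear steps solved by total least
#'   squares ([tls_solve()]), appropriate when the data matrix itself is
#'   noise-contaminated.
#' * `"mpm"` — matrix pencil method (`1 <= p <= N - 1`): the poles are the
#'   eigenvalues of \eqn{Y_1^{+} Y_2} built from a Hankel matrix of the
#'   signal ([build_pencil()], [pencil_poles()]); only the amplitude step
#'   is a least-squares solve. Rank-deficient pencils yield "zero poles"
#'   (reported with `damping = -Inf` and flagged `zero_pole`).
#'
#' Components are returned sorted by `|freq|` ascending, ties by larger
#' `damping`, then non-negative `freq` first, making downstream filtering
#' deterministic. Poles with multiplicity greater than one are outside the
#' model (the exponential-sum representation requires distinct poles);
#' behaviour on such signals is undefined.
#'
#' @param x Real or complex signal vector.
#' @param p Model order (polynomial methods) or pencil parameter (MPM).
#' @param ts Sampling period in seconds.
#' @param method One of `"ls"`, `"tls"`, `"classic"`, `"mpm"`.
#' @return An object of class `"prony_fit"`: list with `components` (tibble,
#'   see [prony_components()]), `order`, `ts`, `method`, `n`, `x`, `fitted`
#'   (real part of the resynthesized signal), `g` (goodness of fit
#'   [goodness_g()] against `Re(x)`, `NA` if undefined) and `diagnostics`
#'   (rank and conditioning information).
#' @examples
#' ts <- 1 / 100
#' t <- (0:63) * ts
#' x <- 3 * exp(-2 * t) * cos(2 * pi * 5 * t + 0.4)
#' fit <- prony_fit(x, p = 4, ts = ts, method = "ls")
#' glance(fit)
#' @export
prony_fit <- function(x, p, ts = 1, method = c("ls", "tls", "classic", "mpm")) {
  method <- match.arg(method)
  check_signal(x)
  p <- check_order(p)
  check_ts(ts)
  n <- length(x)
  if (method == "classic" && n != 2L * p) {
    abort(sprintf("classic method requires N = 2p (N = %d, p = %d).", n, p),
          class = "pronyfit_error_usage")
  }
  if (method %in% c("ls", "tls") && n < 2L * p) {
    abort(sprintf("method \"%s\" requires N >= 2p (N = %d, p = %d).",
                  method, n, p),
          class = "pronyfit_error_insufficient_data")
  }
  if (method == "mpm" && p > n - 1L) {
    abort(sprintf("matrix pencil requires 1 <= p <= N - 1 (N = %d, p = %d).",
                  n, p),
          class = "pronyfit_error_usage")
  }

  diagnostics <- list()
  if (method == "mpm") {
    pp <- pencil_poles(build_pencil(x, p))
    poles <- pp$poles
    diagnostics$effective_rank <- pp$rank
    diagnostics$n_zero_poles <- pp$n_zero
  } else {
    lp <- build_lp_system(x, p)
    a <- switch(method,
      classic = solve_linear(lp$T, lp$rhs, strategy = "classic"),
      ls = solve_linear(lp$T, lp$rhs, strategy = "ls"),
      tls = {
        sol <- tls_solve(lp$T, lp$rhs)
        diagnostics$tls_lp_unique <- sol$unique
        diagnostics$tls_lp_sigma_ratio <-
          sol$singular_values[length(sol$singular_values)] /
          sol$singular_values[1L]
        sol$solution
      }
    )
    poles <- characteristic_roots(a)
  }

  m <- if (method == "classic") p else n
  amp_strategy <- switch(method, classic = "classic", tls = "tls", "ls")
  vand <- amplitude_step(x, poles, m = m, strategy = amp_strategy)
  if (!is.null(vand$tls)) {
    diagnostics$tls_vand_unique <- vand$tls$unique
  }

  comps <- components_from_poles(vand$weights, poles, ts)
  comps <- sort_components(comps)
  fitted_c <- prony_synthesize(comps, n)
  fitted <- if (is.complex(x)) fitted_c else Re(fitted_c)
  g <- tryCatch(goodness_g(x, fitted), error = function(e) NA_real_)
  structure(
    list(components = comps, order = p, ts = ts, method = method, n = n,
         x = x, fitted = fitted, g = g, diagnostics = diagnostics),
    class = "prony_fit"
  )
}

# Stable component order: |freq| ascending, larger damping first on ties
# (puts -Inf zero poles after DC), non-negative frequency before its
# conjugate partner.
sort_components <- function(comps) {
  ord <- order(abs(comps$freq), -comps$damping, comps$freq < 0)
  comps[ord, , drop = FALSE]
}

#' @export
print.prony_fit <- function(x, ...) {
  cat(sprintf("<prony_fit> method = %s, p = %d, N = %d, ts = %g s\n",
              x$method, x$order, x$n, x$ts))
  nz <- sum(x$components$zero_pole)
  cat(sprintf("components: %d (%d zero pole%s); goodness G = %s\n",
              nrow(x$components), nz, if (nz == 1) "" else "s",
              ifelse(is.na(x$g), "NA", sprintf("%.4f", x$g))))
  print(x$components, n = 6)
  invisible(x)
}

#' @export
fitted.prony_fit <- function(object, ...) object$fitted

#' @export
residuals.prony_fit <- function(object, ...) object$x - object$fitted
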