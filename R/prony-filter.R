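#' Keep the lowest-frequency components of a decomposition
#'
#' Prony-domain band selection: zero poles are set aside first, then the
#' `keep` components with the smallest `|freq|` are retained (ties broken
#' by larger damping, then non-negative frequency first — the stable order
#' of [prony_fit()]). Conjugate partners count individually, so keeping 10
#' components of a real decomposition retains roughly the DC mode plus the
#' five slowest oscillatory pairs. If `keep` is at least the total
#' component count the decomposition is returned unchanged.
#'
#' @param object A [prony_fit] object or component tibble.
#' @param keep Number of components to retain (default 10).
#' @return Same type as `object`, with the reduced component set; kept
#'   components are bit-for-bit identical to the input ones.
#' @export
prony_bandpass <- function(object, keep = 10) {
  if (!is.numeric(keep) || length(keep) != 1L || keep < 1) {
    abort("`keep` must be a single count >= 1.",
          class = "pronyfit_error_usage")
  }
  comps <- as_components(object)
  if (nrow(comps) == 0L) {
    abort("decomposition has no components.",
          class = "pronyfit_error_usage")
  }
  if (keep >= nrow(comps)) {
    return(object)
  }
  pool <- sort_components(comps[!comps$zero_pole, , drop = FALSE])
  kept <- pool[seq_len(min(keep, nrow(pool))), , drop = FALSE]
  if (inherits(object, "prony_fit")) {
    object$components <- kept
    object$fitted <- {
      fc <- prony_synthesize(kept, object$n)
      if (is.complex(object$x)) fc else Re(fc)
    }
    object$g <- tryCatch(goodness_g(object$x, object$fitted),
                         error = function(e) NA_real_)
    object
  } else {
    kept
  }
}

#' Filter a signal in the Prony domain
#'
#' Convenience chain: fit a Prony decomposition, keep the `keep`
#' lowest-frequency components, resynthesize, and return the real part —
#' a low-pass filter whose passband adapts to the signal's own estimated
#' modes.
#'
#' @inheritParams prony_fit
#' @param keep Number of components to retain.
#' @return Real filtered signal of the same length as `x`.
#' @export
prony_filter <- function(x, p, ts = 1, method = c("ls", "tls", "classic", "mpm"),
                         keep = 10) {
  fit <- prony_fit(x, p, ts, method)
  prony_reconstruct(prony_bandpass(fit, keep), length(x))
}

#' Brick-wall DFT low-pass filter
#'
#' The conventional mfVEP filter: forward FFT, zero every bin whose
#' frequency magnitude exceeds `cutoff` (bin `k` sits at `k * fs / N` Hz,
#' folded to the signed range; positive and negative bins are zeroed
#' together), inverse FFT, real part. The DC bin is always retained. The
#' filter is idempotent and length-preserving.
#'
#' @param x Real signal.
#' @param fs Sampling frequency, Hz.
#' @param cutoff Cut-off frequency in Hz, strictly below Nyquist
#'   (default 35).
#' @return Real filtered signal, same length as `x`.
#' @examples
#' x <- cos(2 * pi * 10 * (0:599) / 1200)
#' max(abs(dft_lowpass(x, 1200, 35) - x)) < 1e-9  # 10 Hz passes intact
#' @export
dft_lowpass <- function(x, fs, cutoff = 35) {
  check_signal(x)
  if (!is.numeric(fs) || fs <= 0) {
    abort("`fs` must be a positive sampling frequency.",
          class = "pronyfit_error_usage")
  }
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff < 0 ||
      cutoff >= fs / 2) {
    abort("`cutoff` must lie in [0, fs / 2).",
          class = "pronyfit_error_usage")
  }
  n <- length(x)
  k <- 0:(n - 1L)
  f <- ifelse(k <= n / 2, k, k - n) * fs / n
  X <- fft(x)
  X[abs(f) > cutoff] <- 0 + 0i
  Re(fft(X, inverse = TRUE)) / n
}
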