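#' Build a table of Prony components
#'
#' A Prony decomposition represents a signal as
#' \deqn{x[n] = \sum_k h_k z_k^{\,n-1}, \qquad n = 1, \dots, N,}
#' where each component is equivalently described by four real parameters:
#' amplitude `amp` (\eqn{A_k = |h_k|}), damping `damping` (\eqn{\alpha_k},
#' 1/s), frequency `freq` (\eqn{f_k}, Hz) and phase `phase` (\eqn{\theta_k},
#' rad), with pole \eqn{z_k = e^{(\alpha_k + 2\pi i f_k) T_s}} and complex
#' weight \eqn{h_k = A_k e^{i\theta_k}}. `prony_components()` constructs the
#' component table from either parameterization; the other half is filled in.
#'
#' A pole of modulus zero ("zero pole", produced by rank-deficient matrix
#' pencils) is represented with `damping = -Inf`, `freq = 0`; it contributes
#' only to the first sample.
#'
#' @param amp,damping,freq,phase Real parameter vectors (recycled to a
#'   common length). Either supply these four, or `weight` and `pole`.
#' @param weight,pole Complex vectors \eqn{h_k} and \eqn{z_k}.
#' @param ts Sampling period in seconds.
#' @return A tibble with columns `amp`, `damping`, `freq`, `phase`,
#'   `pole` (complex), `weight` (complex) and `zero_pole` (logical).
#' @examples
#' prony_components(amp = 1, damping = -2, freq = 5, phase = 0, ts = 1e-3)
#' @export
prony_components <- function(amp = NULL, damping = NULL, freq = NULL,
                             phase = NULL, weight = NULL, pole = NULL,
                             ts = 1) {
  check_ts(ts)
  from_polar <- !is.null(amp) || !is.null(damping) || !is.null(freq) ||
    !is.null(phase)
  from_cart <- !is.null(weight) || !is.null(pole)
  if (from_polar && from_cart) {
    abort("supply either (amp, damping, freq, phase) or (weight, pole), not both.",
          class = "pronyfit_error_usage")
  }
  if (from_cart) {
    weight <- as.complex(weight)
    pole <- as.complex(pole)
    k <- max(length(weight), length(pole))
    weight <- rep_len(weight, k)
    pole <- rep_len(pole, k)
    return(components_from_poles(weight, pole, ts))
  }
  k <- max(length(amp), length(damping), length(freq), length(phase))
  amp <- rep_len(amp %||% 1, k)
  damping <- rep_len(damping %||% 0, k)
  freq <- rep_len(freq %||% 0, k)
  phase <- rep_len(phase %||% 0, k)
  if (any(amp < 0)) {
    abort("`amp` must be non-negative.", class = "pronyfit_error_usage")
  }
  zero <- is.infinite(damping) & damping < 0
  pole <- complex(modulus = exp(damping * ts), argument = 2 * pi * freq * ts)
  pole[zero] <- 0 + 0i
  tibble(
    amp = amp, damping = damping, freq = freq, phase = phase,
    pole = pole, weight = complex(modulus = amp, argument = phase),
    zero_pole = zero
  )
}

# (h, z) -> full component table; the inverse parameter maps are
# alpha = log|z| / ts and f = atan2(Im z, Re z) / (2 pi ts).
components_from_poles <- function(weight, pole, ts) {
  par <- poles_to_params(pole, ts)
  tibble(
    amp = Mod(weight),
    damping = par$damping,
    freq = par$freq,
    phase = Arg(weight),
    pole = pole,
    weight = weight,
    zero_pole = Mod(pole) == 0
  )
}

#' Convert complex poles to damping factors and frequencies
#'
#' For a pole \eqn{z} at sampling period `ts`,
#' \eqn{\alpha = \log|z| / T_s} (1/s) and
#' \eqn{f = \mathrm{atan2}(\Im z, \Re z) / (2\pi T_s)} (Hz), so `freq` lies
#' in `(-1/(2 ts), 1/(2 ts)]`. A zero pole maps to `damping = -Inf`,
#' `freq = 0`.
#'
#' @param pole Complex vector of poles.
#' @param ts Sampling period in seconds.
#' @return A tibble with columns `pole`, `damping`, `freq`.
#' @examples
#' poles_to_params(c(1 + 0i, 0.5 + 0i), ts = 1)
#' @export
poles_to_params <- function(pole, ts) {
  check_ts(ts)
  pole <- as.complex(pole)
  damping <- log(Mod(pole)) / ts
  freq <- atan2(Im(pole), Re(pole)) / (2 * pi * ts)
  zero <- Mod(pole) == 0
  freq[zero] <- 0
  tibble(pole = pole, damping = damping, freq = freq)
}

# Vandermonde-style column of successive pole powers z^(0:(m-1)), computed
# by cumulative products so that an exact zero pole yields [1, 0, 0, ...]
# (the 0^0 = 1 convention) and overflow stays localized.
pole_powers <- function(z, m) {
  if (m == 1L) return(as.complex(1))
  cumprod(c(1 + 0i, rep(z, m - 1L)))
}

#' Synthesize a signal from a Prony decomposition
#'
#' Evaluates \eqn{x[n] = \sum_k h_k z_k^{\,n-1}} for `n = 1..n_out`. The
#' result is complex; use [prony_reconstruct()] (or `Re()`) for real-signal
#' work. The convention \eqn{0^0 = 1} applies, so a zero pole contributes
#' its weight to the first sample only.
#'
#' @param object A [prony_fit] object or a component tibble from
#'   [prony_components()].
#' @param n_out Number of samples to synthesize.
#' @return Complex vector of length `n_out`.
#' @examples
#' comps <- prony_components(weight = 2 * exp(1i * pi), pole = 1 + 0i, ts = 1)
#' prony_synthesize(comps, 3)  # -2 -2 -2
#' @export
prony_synthesize <- function(object, n_out) {
  comps <- as_components(object)
  if (!is.numeric(n_out) || length(n_out) != 1L || n_out < 1) {
    abort("`n_out` must be a single count >= 1.",
          class = "pronyfit_error_usage")
  }
  n_out <- as.integer(n_out)
  if (nrow(comps) == 0L) {
    abort("decomposition has no components.",
          class = "pronyfit_error_invalid_decomposition")
  }
  h <- comps$weight
  z <- comps$pole
  if (anyNA(h) || anyNA(z) ||
      !all(is.finite(Re(h)) & is.finite(Im(h)) &
             is.finite(Re(z)) & is.finite(Im(z)))) {
    abort("components carry non-finite weights or poles.",
          class = "pronyfit_error_invalid_decomposition")
  }
  x <- complex(n_out)
  for (k in seq_along(z)) {
    x <- x + h[k] * pole_powers(z[k], n_out)
  }
  x
}

#' @rdname prony_synthesize
#' @export
prony_reconstruct <- function(object, n_out = NULL) {
  comps <- as_components(object)
  if (is.null(n_out)) {
    n_out <- if (inherits(object, "prony_fit")) object$n else
      abort("`n_out` is required when `object` is a component table.",
            class = "pronyfit_error_usage")
  }
  Re(prony_synthesize(comps, n_out))
}

as_components <- function(object) {
  if (inherits(object, "prony_fit")) {
    return(object$components)
  }
  if (is.data.frame(object)) {
    need <- c("weight", "pole")
    if (!all(need %in% names(object))) {
      abort("component table must have `weight` and `pole` columns.",
            class = "pronyfit_error_usage")
    }
    return(object)
  }
  abort("`object` must be a prony_fit or a component tibble.",
        class = "pronyfit_error_usage")
}

#' Goodness of approximation G (one minus normalized RMS error)
#'
#' \deqn{G = 1 - \frac{\lVert g - \hat g \rVert_2}
#'                    {\lVert g - \bar g \rVert_2}}
#' where \eqn{\bar g} is the mean of the reference. `G = 1` for an exact
#' match, `G = 0` for the mean predictor; the statistic is unbounded below.
#' An approximation with `G` at or above a chosen threshold (0.60 for the
#' synthetic benchmark, 0.45 for mfVEP records) is considered correct.
#'
#' @param reference Reference signal (must not be constant).
#' @param estimate Approximating signal of the same length.
#' @return A single number `<= 1`.
#' @examples
#' goodness_g(c(1, 2, 3), c(1, 2, 4))  # 1 - 1/sqrt(2)
#' @export
goodness_g <- function(reference, estimate) {
  if (length(reference) != length(estimate)) {
    abort("`reference` and `estimate` must have equal length.",
          class = "pronyfit_error_usage")
  }
  denom <- vec_norm(reference - mean(reference))
  if (denom == 0) {
    abort("`reference` is constant: G is undefined.",
          class = "pronyfit_error_degenerate_reference")
  }
  1 - vec_norm(reference - estimate) / denom
}

#' Windowed RMS amplitude of a record
#'
#' Converts a window given in milliseconds to sample indices (bounds rounded
#' to the nearest sample, both ends inclusive; sample `n` sits at time
#' `(n - 1) / fs`) and returns the root-mean-square amplitude over it.
#'
#' @param x Real record.
#' @param fs Sampling frequency in Hz.
#' @param window_ms Length-2 numeric, window bounds in ms.
#' @return RMS amplitude (same units as `x`).
#' @export
window_rms <- function(x, fs, window_ms) {
  idx <- window_indices(length(x), fs, window_ms)
  sqrt(mean(x[idx]^2))
}

window_indices <- function(n, fs, window_ms) {
  if (length(window_ms) != 2L || window_ms[1] > window_ms[2]) {
    abort("`window_ms` must be c(lo, hi) with lo <= hi.",
          class = "pronyfit_error_usage")
  }
  lo <- round(window_ms[1] / 1000 * fs) + 1L
  hi <- round(window_ms[2] / 1000 * fs) + 1L
  if (lo < 1L || hi > n) {
    abort(sprintf("window [%g, %g] ms is outside the %d-sample record.",
                  window_ms[1], window_ms[2], n),
          class = "pronyfit_error_window")
  }
  seq.int(lo, hi)
}

#' Windowed signal-to-noise ratio of one record
#'
#' \deqn{\mathrm{SNR} = \mathrm{RMS}_{45\text{--}150\,\mathrm{ms}} /
#'       \overline{\mathrm{RMS}}_{325\text{--}430\,\mathrm{ms}}}
#' The numerator is the RMS amplitude of this record over the signal window
#' (where the physiological response lives); the denominator is the *mean*
#' noise-window RMS over a set of comparable records — pass it as
#' `noise_rms_mean`. When omitted, the record's own noise-window RMS is
#' used (a "group" of one). See [snr_records()] for the grouped,
#' data-frame-first version.
#'
#' @param x Real record covering both windows.
#' @param fs Sampling frequency, Hz.
#' @param noise_rms_mean Positive scalar denominator; default: this record's
#'   own noise-window RMS.
#' @param signal_window,noise_window Window bounds in ms.
#' @return A single positive number.
#' @export
record_snr <- function(x, fs, noise_rms_mean = NULL,
                       signal_window = c(45, 150),
                       noise_window = c(325, 430)) {
  if (is.null(noise_rms_mean)) {
    noise_rms_mean <- window_rms(x, fs, noise_window)
  }
  if (!is.numeric(noise_rms_mean) || length(noise_rms_mean) != 1L ||
      !is.finite(noise_rms_mean) || noise_rms_mean <= 0) {
    abort("`noise_rms_mean` must be a single positive number.",
          class = "pronyfit_error_degenerate_noise")
  }
  window_rms(x, fs, signal_window) / noise_rms_mean
}

#' Grouped signal-to-noise ratios for a table of records
#'
#' Data-frame-first SNR: each row of `data` holds one record in the
#' list-column `samples`. Noise-window RMS values are averaged within groups
#' defined by `group_vars` (by default subject/eye/channel, i.e. across the
#' visual-field sectors of one electrode trace) and each record's signal
#' window RMS is divided by its group's mean noise RMS.
#'
#' @param data Tibble with a `samples` list-column of equal-length records.
#' @param fs Sampling frequency, Hz.
#' @param group_vars Character vector of grouping columns present in
#'   `data`; columns that are absent are ignored.
#' @param signal_window,noise_window Window bounds in ms.
#' @return `data` with columns `signal_rms`, `noise_rms`,
#'   `group_noise_rms`, `snr` appended.
#' @export
snr_records <- function(data, fs,
                        group_vars = c("group", "subject", "eye", "channel"),
                        signal_window = c(45, 150),
                        noise_window = c(325, 430)) {
  if (!is.data.frame(data) || !"samples" %in% names(data)) {
    abort("`data` must be a data frame with a `samples` list-column.",
          class = "pronyfit_error_usage")
  }
  group_vars <- intersect(group_vars, names(data))
  out <- data
  out$signal_rms <- purrr::map_dbl(out$samples, window_rms, fs = fs,
                                   window_ms = signal_window)
  out$noise_rms <- purrr::map_dbl(out$samples, window_rms, fs = fs,
                                  window_ms = noise_window)
  out <- dplyr::group_by(out, dplyr::across(dplyr::all_of(group_vars)))
  out <- dplyr::mutate(out, group_noise_rms = mean(.data$noise_rms))
  out <- dplyr::ungroup(out)
  if (any(out$group_noise_rms <= 0)) {
    abort("a record group has zero mean noise RMS; SNR is undefined.",
          class = "pronyfit_error_degenerate_noise")
  }
  out$snr <- out$signal_rms / out$group_noise_rms
  out
}

#' Area under the ROC curve by the Mann-Whitney pair statistic
#'
#' The probability that a randomly drawn positive-group score exceeds a
#' randomly drawn negative-group score, with ties credited one half:
#' the mean over all (positive, negative) pairs of
#' `1 (pos > neg) + 0.5 (pos == neg)`. Computed via midranks, which is
#' algebraically identical to the pair enumeration.
#'
#' @param scores_pos,scores_neg Non-empty numeric score vectors.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc_mann_whitney(c(2, 3), c(0, 1))  # 1
#' auc_mann_whitney(c(1, 3), c(2, 0))  # 0.75
#' @export
auc_mann_whitney <- function(scores_pos, scores_neg) {
  if (length(scores_pos) == 0L || length(scores_neg) == 0L) {
    abort("both score vectors must be non-empty.",
          class = "pronyfit_error_usage")
  }
  if (anyNA(scores_pos) || anyNA(scores_neg)) {
    abort("scores must not contain missing values.",
          class = "pronyfit_error_usage")
  }
  n1 <- length(scores_pos)
  n2 <- length(scores_neg)
  r <- rank(c(scores_pos, scores_neg), ties.method = "average")
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}
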