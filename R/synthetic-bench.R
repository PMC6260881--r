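#' The 38 (N, p) benchmark configurations
#'
#' Sample-length / order pairs over which the estimators are scored on the
#' random damped-cosine family: ten orders each at N = 1024, 512 and 256,
#' five at N = 128 and three at N = 64. Every pair satisfies `N >= 2p`.
#'
#' @return Tibble with integer columns `n` and `p`, 38 rows.
#' @export
benchmark_configs <- function() {
  tibble(
    n = c(rep(1024L, 10), rep(512L, 10), rep(256L, 10), rep(128L, 5),
          rep(64L, 3)),
    p = c(30L, 40L, 50L, 100L, 150L, 200L, 250L, 300L, 400L, 500L,
          30L, 40L, 50L, 60L, 70L, 100L, 150L, 200L, 220L, 250L,
          30L, 40L, 50L, 60L, 70L, 80L, 90L, 100L, 110L, 120L,
          20L, 30L, 40L, 50L, 60L,
          20L, 25L, 30L)
  )
}

#' Generate one random damped-cosine test function
#'
#' Draws a ten-term sum of exponentially damped cosines
#' \deqn{g[n] = \sum_{k=0}^{9} A_k e^{\alpha_k n T_s}
#'       \cos(2\pi f_k n T_s + \theta_k), \qquad n = 0, \dots, N - 1,}
#' with independent uniform parameters: amplitudes `A` on \[1, 10\],
#' dampings `alpha` on \[-4, 0\] 1/s, phases `theta` on \[-pi, pi\], and
#' integer frequencies with `f[0] = 0` and `f[1..9]` drawn without
#' replacement from 1..31 Hz (distinct by construction). The DC-frequency
#' term contributes one real pole and each cosine a conjugate pole pair, so
#' the implied exponential model has exactly M = 19 distinct poles.
#'
#' The default sampling period `ts = 1/64` s holds the sampling rate fixed
#' at 64 Hz for every record length: the Nyquist frequency (32 Hz) then
#' just clears the 31 Hz top of the frequency grid, so the pole angles
#' spread over the whole unit semicircle. (Sampling instead at rates far
#' above 62 Hz crowds all poles near `z = 1` and makes every estimator's
#' linear algebra catastrophically ill-conditioned, which is inconsistent
#' with the benchmark's observed behaviour.)
#'
#' @param n Number of samples (>= 40, i.e. at least 2M).
#' @param ts Sampling period in seconds (default `1/64`).
#' @param seed Optional integer; when supplied the draw is deterministic
#'   and the caller's RNG state is left untouched.
#' @return A list with `signal` (real vector of length `n`) and `params`
#'   (tibble with columns `amp`, `damping`, `freq`, `phase`, one row per
#'   cosine term), plus `n`, `ts`.
#' @export
generate_prony_function <- function(n, ts = 1 / 64, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 40) {
    abort("`n` must be a single count >= 40 (twice the 19-pole model).",
          class = "pronyfit_error_usage")
  }
  n <- as.integer(n)
  check_ts(ts)
  draw <- function() {
    tibble(
      amp = runif(10, 1, 10),
      damping = runif(10, -4, 0),
      freq = c(0, sample(1:31, 9)),
      phase = runif(10, -pi, pi)
    )
  }
  params <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  t_n <- (0:(n - 1L)) * ts
  signal <- numeric(n)
  for (k in seq_len(10)) {
    signal <- signal + params$amp[k] * exp(params$damping[k] * t_n) *
      cos(2 * pi * params$freq[k] * t_n + params$phase[k])
  }
  list(signal = signal, params = params, n = n, ts = ts)
}

#' Fit one signal and score the approximation
#'
#' Fits the requested estimator, resynthesizes the real part and computes
#' the goodness factor [goodness_g()]. An estimator failure (singular
#' system, absent TLS solution, non-finite reconstruction) is a recorded
#' outcome, not an error: it scores `g = -Inf`, `correct = FALSE`,
#' `failed = TRUE`.
#'
#' @inheritParams prony_fit
#' @param g_min Correctness threshold on G (default 0.60).
#' @return One-row tibble: `g`, `correct`, `failed`, `message`.
#' @export
evaluate_prony_fit <- function(x, p, ts = 1,
                               method = c("ls", "tls", "classic", "mpm"),
                               g_min = 0.60) {
  method <- match.arg(method)
  res <- tryCatch(
    {
      fit <- prony_fit(x, p, ts, method)
      g <- fit$g
      if (is.na(g) || !is.finite(g)) g <- -Inf
      list(g = g, failed = FALSE, message = NA_character_)
    },
    error = function(e) {
      list(g = -Inf, failed = TRUE, message = conditionMessage(e))
    }
  )
  tibble(
    g = res$g,
    correct = res$g >= g_min,
    failed = res$failed,
    message = res$message
  )
}

#' Score the estimators on the random damped-cosine benchmark
#'
#' For every `(n, p)` configuration, generates `replicates` random test
#' functions ([generate_prony_function()]) and counts, per method, how many
#' are approximated with `G >= g_min`. All methods of one configuration are
#' scored on the *same* functions, so method comparisons are paired. Child
#' seeds are derived deterministically from `seed` in the row order of the
#' canonical configuration table, making each configuration's counts
#' reproducible in isolation.
#'
#' @param configs Tibble with columns `n`, `p` (default
#'   [benchmark_configs()]).
#' @param methods Methods to score (default `c("ls", "tls", "mpm")`).
#' @param replicates Functions per configuration (the reference experiment
#'   uses 1000; 100 is a proportionally rescalable desk size).
#' @param g_min Correctness threshold on G.
#' @param seed Master seed (integer).
#' @param progress Print one line per configuration as it completes.
#' @return A tibble of class `"prony_benchmark"` with one row per
#'   `(n, p, method)`: columns `n`, `p`, `method`, `correct`, `failed`,
#'   `replicates`; attributes `g_min` and `seed`.
#' @export
run_benchmark <- function(configs = benchmark_configs(),
                          methods = c("ls", "tls", "mpm"),
                          replicates = 100, g_min = 0.60, seed = 1,
                          progress = FALSE) {
  if (!is.data.frame(configs) || !all(c("n", "p") %in% names(configs)) ||
      nrow(configs) == 0L) {
    abort("`configs` must be a data frame with columns `n` and `p`.",
          class = "pronyfit_error_config")
  }
  if (!is.numeric(replicates) || replicates < 1) {
    abort("`replicates` must be >= 1.", class = "pronyfit_error_config")
  }
  methods <- match.arg(methods, c("ls", "tls", "mpm", "classic"),
                       several.ok = TRUE)
  bad <- configs$n < 2 * configs$p
  if (any(bad)) {
    abort(sprintf("configuration rows violating N >= 2p: %s",
                  paste(which(bad), collapse = ", ")),
          class = "pronyfit_error_config")
  }
  replicates <- as.integer(replicates)
  canon <- benchmark_configs()
  config_seed <- function(n, p) {
    hit <- which(canon$n == n & canon$p == p)
    offset <- if (length(hit) == 1L) hit else nrow(canon) + n %% 1000L + p
    # double arithmetic: exact below 2^53, reduced below 2^31 for set.seed()
    (as.numeric(seed) * 2654435 + as.numeric(offset) * 97) %% 2147483647
  }
  rows <- vector("list", nrow(configs))
  for (i in seq_len(nrow(configs))) {
    n_i <- configs$n[i]
    p_i <- configs$p[i]
    counts <- setNames(integer(length(methods)), methods)
    fails <- setNames(integer(length(methods)), methods)
    withr::with_seed(config_seed(n_i, p_i), {
      for (r in seq_len(replicates)) {
        gen <- generate_prony_function(n_i)
        for (m in methods) {
          sc <- evaluate_prony_fit(gen$signal, p_i, gen$ts, m, g_min)
          counts[m] <- counts[m] + sc$correct
          fails[m] <- fails[m] + sc$failed
        }
      }
    })
    rows[[i]] <- tibble(n = n_i, p = p_i, method = methods,
                        correct = as.integer(counts),
                        failed = as.integer(fails),
                        replicates = replicates)
    if (isTRUE(progress)) {
      message(sprintf("config %d/%d (N = %d, p = %d): %s",
                      i, nrow(configs), n_i, p_i,
                      paste(methods, counts, sep = "=", collapse = " ")))
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "g_min") <- g_min
  attr(out, "seed") <- seed
  class(out) <- c("prony_benchmark", class(out))
  out
}

#' Per-method summary of a benchmark run
#'
#' @param result A `"prony_benchmark"` tibble from [run_benchmark()].
#' @return Tibble with one row per method: `mean_correct` (mean per-config
#'   count), `mean_correct_per_1000` (the same rescaled to a 1000-replicate
#'   experiment), `perfect_configs`, `perfect_pct` (percentage of
#'   configurations in which every replicate passed) and `configs`.
#' @export
summarize_benchmark <- function(result) {
  if (!all(c("method", "correct", "replicates") %in% names(result))) {
    abort("`result` must come from run_benchmark().",
          class = "pronyfit_error_usage")
  }
  dplyr::summarise(
    dplyr::group_by(as_tibble(result), .data$method),
    configs = dplyr::n(),
    mean_correct = mean(.data$correct),
    mean_correct_per_1000 = mean(.data$correct / .data$replicates) * 1000,
    perfect_configs = sum(.data$correct == .data$replicates),
    perfect_pct = 100 * .data$perfect_configs / .data$configs,
    .groups = "drop"
  )
}
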