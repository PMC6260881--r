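test_that("linear-prediction system has the Toeplitz shift structure", {
  lp <- build_lp_system(c(1, 2, 3, 4), 2)
  expect_equal(lp$T, rbind(c(2, 1), c(3, 2)))
  expect_equal(lp$rhs, -c(3, 4))

  lp1 <- build_lp_system(c(1, 1, 1), 1)
  expect_equal(lp1$T, matrix(1, 2, 1))
  expect_equal(lp1$rhs, -c(1, 1))

  # geometric signal: the single AR coefficient recovers the ratio
  lp2 <- build_lp_system(c(1, 2, 4, 8), 1)
  a <- solve_linear(lp2$T, lp2$rhs, "ls")
  expect_equal(a, -2, tolerance = 1e-12)
  expect_equal(Re(characteristic_roots(a)), 2, tolerance = 1e-12)

  expect_error(build_lp_system(1:3, 2),
               class = "pronyfit_error_insufficient_data")
})

test_that("characteristic roots come from the companion matrix", {
  expect_equal(characteristic_roots(-1), 1 + 0i)
  # z^2 - 3z + 2 = (z - 1)(z - 2)
  r <- sort(Re(characteristic_roots(c(-3, 2))))
  expect_equal(r, c(1, 2), tolerance = 1e-12)
  # z^2 + 1
  r2 <- characteristic_roots(c(0, 1))
  expect_equal(sort(Im(r2)), c(-1, 1), tolerance = 1e-12)
  expect_equal(Re(r2), c(0, 0), tolerance = 1e-12)
  expect_error(characteristic_roots(c(NA, 1)),
               class = "pronyfit_error_usage")
})

test_that("pole-to-parameter conversion covers unit, real and damped poles", {
  expect_equal(poles_to_params(1 + 0i, 2)[, c("damping", "freq")],
               tibble::tibble(damping = 0, freq = 0))
  p2 <- poles_to_params(0.5 + 0i, 1)
  expect_equal(p2$damping, log(0.5), tolerance = 1e-12)
  expect_equal(p2$freq, 0)
  # z = exp((-100 + 2 pi i 5) * 0.001): hand evaluation
  z <- exp(complex(real = -0.1, imaginary = 2 * pi * 5 * 0.001))
  p3 <- poles_to_params(z, 0.001)
  expect_equal(p3$damping, -100, tolerance = 1e-9)
  expect_equal(p3$freq, 5, tolerance = 1e-9)
  # zero pole sentinel
  p0 <- poles_to_params(0 + 0i, 1)
  expect_identical(p0$damping, -Inf)
  expect_identical(p0$freq, 0)
})

test_that("frequencies stay inside the principal Nyquist interval", {
  set.seed(12)
  ts <- 1 / 50
  z <- complex(modulus = runif(40, 0.2, 1.2),
               argument = runif(40, -pi, pi))
  par <- poles_to_params(z, ts)
  expect_true(all(par$freq > -1 / (2 * ts) - 1e-12))
  expect_true(all(par$freq <= 1 / (2 * ts) + 1e-12))
})

test_that("amplitude step recovers weights, amplitudes and phases", {
  v <- amplitude_step(c(3, 3, 3), 1 + 0i, m = 3, strategy = "ls")
  expect_equal(v$weights, 3 + 0i, tolerance = 1e-12)
  expect_equal(v$amp, 3, tolerance = 1e-12)
  expect_equal(v$phase, 0)
  expect_equal(v$Z[1, ], 1 + 0i)  # first Vandermonde row is all ones

  # negative real weight: phase pi
  v2 <- amplitude_step(-2 * 0.8^(0:5), 0.8 + 0i, m = 6, strategy = "ls")
  expect_equal(v2$amp, 2, tolerance = 1e-12)
  expect_equal(abs(v2$phase), pi, tolerance = 1e-12)  # +/- pi are one angle

  # two distinct real poles, known weights: synthesis round trip
  z <- c(0.9 + 0i, 0.4 + 0i)
  h <- c(2.5 + 0i, -1.25 + 0i)
  x <- Re(prony_synthesize(prony_components(weight = h, pole = z, ts = 1), 12))
  v3 <- amplitude_step(x, z, m = 12, strategy = "ls")
  expect_equal(v3$weights, h, tolerance = 1e-9)

  # classic on a rank-deficient square Vandermonde (duplicate pole)
  expect_error(
    amplitude_step(c(1, 1), c(1 + 0i, 1 + 0i), m = 2, strategy = "classic"),
    class = "pronyfit_error_singular"
  )
})

test_that("full polynomial fits recover generating parameters", {
  # single exponential, classic, N = 2p
  ts <- 0.01
  fit <- prony_fit(0.9^(0:1), 1, ts, "classic")
  expect_equal(fit$components$amp, 1, tolerance = 1e-9)
  expect_equal(fit$components$damping, log(0.9) / ts, tolerance = 1e-9)
  expect_equal(fit$components$freq, 0)
  expect_equal(fit$components$phase, 0)

  # noiseless two-cosine signal, LS, N = 64, p = 8
  amp <- c(2, 1.5); damping <- c(-1, -0.5); freq <- c(5, 12)
  phase <- c(0.3, -1)
  x <- damped_cosines(64, ts, amp, damping, freq, phase)
  for (method in c("ls", "tls", "mpm")) {
    fit <- prony_fit(x, 8, ts, method)
    expect_gt(fit$g, 0.999)
    truth <- cosine_components(amp, damping, freq, phase, ts)
    expect_lt(match_components(fit$components, truth), 1e-6)
  }
})

test_that("method preconditions are enforced before any computation", {
  x <- rnorm(10)
  expect_error(prony_fit(x, 6, 1, "classic"), class = "pronyfit_error_usage")
  expect_error(prony_fit(x, 6, 1, "ls"),
               class = "pronyfit_error_insufficient_data")
  expect_error(prony_fit(x, 10, 1, "mpm"), class = "pronyfit_error_usage")
  expect_error(prony_fit(c(1, NA, 3, 4), 2, 1, "ls"),
               class = "pronyfit_error_usage")
})

test_that("real input yields conjugate-closed pole sets", {
  set.seed(64)
  ts <- 1 / 64
  for (method in c("classic", "ls", "tls")) {
    x <- damped_cosines(16, ts, c(3, 1), c(-0.5, -2), c(7, 19), c(0.4, -0.9))
    # classic needs N = 2p with p equal to the true pole count (4), else
    # its square Toeplitz system is singular
    p <- if (method == "classic") 4 else 6
    n_use <- if (method == "classic") 8 else 16
    fit <- prony_fit(x[seq_len(n_use)], p, ts, method)
    z <- fit$components$pole
    for (zi in z) {
      expect_lt(min(Mod(z - Conj(zi))), 1e-6 * max(Mod(z)))
    }
  }
})

test_that("classic interpolation is exact and LS reduces to classic at N = 2p", {
  set.seed(3)
  ts <- 1 / 64
  amp <- c(4, 2, 1); damping <- c(-0.2, -1, -2.5); freq <- c(3, 11, 24)
  phase <- c(0.1, 1.2, -2)
  x <- damped_cosines(12, ts, amp, damping, freq, phase)  # p = 6 poles
  classic <- prony_fit(x, 6, ts, "classic")
  expect_lt(sqrt(sum((x - classic$fitted)^2)) / sqrt(sum(x^2)), 1e-6)
  ls <- prony_fit(x, 6, ts, "ls")
  expect_equal(ls$components$pole, classic$components$pole, tolerance = 1e-9)
  expect_equal(ls$components$weight, classic$components$weight,
               tolerance = 1e-9)
})

test_that("fits expose tidy, glance, fitted and residuals views", {
  ts <- 1 / 64
  x <- damped_cosines(32, ts, 2, -1, 5, 0)
  fit <- prony_fit(x, 4, ts, "ls")
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("amp", "damping", "freq", "phase", "pole", "weight",
                     "zero_pole"))
  gl <- glance(fit)
  expect_equal(gl$n_components, 4L)
  expect_equal(gl$method, "ls")
  expect_equal(fitted(fit) + residuals(fit), x, tolerance = 1e-12)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_poles(fit), "ggplot")
})
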