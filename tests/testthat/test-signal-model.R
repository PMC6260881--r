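test_that("synthesis reproduces closed-form exponential sums", {
  # identity pole
  c1 <- prony_components(weight = 1 + 0i, pole = 1 + 0i, ts = 1)
  expect_equal(prony_synthesize(c1, 4), rep(1 + 0i, 4))

  # constant with phase pi
  c2 <- prony_components(weight = 2 * exp(1i * pi), pole = 1 + 0i, ts = 1)
  expect_equal(Re(prony_synthesize(c2, 3)), rep(-2, 3), tolerance = 1e-12)

  # conjugate pair vs direct damped-cosine evaluation
  ts <- 1 / 200
  A <- 3.2; al <- -1.7; f <- 12; th <- 0.8
  comps <- cosine_components(A, al, f, th, ts)
  got <- prony_synthesize(comps, 64)
  want <- damped_cosines(64, ts, A, al, f, th)
  expect_equal(Re(got), want, tolerance = 1e-12)
  expect_lt(max(abs(Im(got))), 1e-9 * sqrt(sum(want^2)))
})

test_that("a zero pole contributes only to the first sample", {
  comps <- prony_components(weight = c(2 + 0i, 5 + 0i),
                            pole = c(0.5 + 0i, 0 + 0i), ts = 1)
  x <- prony_synthesize(comps, 4)
  expect_equal(Re(x), c(2 + 5, 1, 0.5, 0.25), tolerance = 1e-12)
  expect_true(comps$zero_pole[comps$pole == 0])
  expect_equal(comps$damping[comps$pole == 0], -Inf)
})

test_that("polar and cartesian component parameterizations agree", {
  set.seed(101)
  for (rep in 1:10) {
    k <- 4
    amp <- runif(k, 0.5, 5)
    damping <- runif(k, -3, 0.5)
    freq <- runif(k, -40, 40)
    phase <- runif(k, -pi, pi)
    ts <- 1 / 100
    from_par <- prony_components(amp = amp, damping = damping, freq = freq,
                                 phase = phase, ts = ts)
    from_hz <- prony_components(weight = from_par$weight,
                                pole = from_par$pole, ts = ts)
    x1 <- prony_synthesize(from_par, 32)
    x2 <- prony_synthesize(from_hz, 32)
    expect_equal(x1, x2, tolerance = 1e-9)
    expect_equal(from_hz$amp, amp, tolerance = 1e-9)
    expect_equal(from_hz$damping, damping, tolerance = 1e-9)
    expect_equal(from_hz$freq, freq, tolerance = 1e-9)
  }
})

test_that("synthesis rejects degenerate decompositions", {
  comps <- prony_components(weight = NaN + 0i, pole = 1 + 0i, ts = 1)
  expect_error(prony_synthesize(comps, 3),
               class = "pronyfit_error_invalid_decomposition")
  ok <- prony_components(weight = 1 + 0i, pole = 1 + 0i, ts = 1)
  expect_error(prony_synthesize(ok[0, ], 3),
               class = "pronyfit_error_invalid_decomposition")
})

test_that("goodness factor matches its closed forms", {
  g <- c(1, 2, 3)
  expect_equal(goodness_g(g, g), 1)
  expect_equal(goodness_g(g, rep(mean(g), 3)), 0)
  # hand-computed norms: |g - ghat| = 1, |g - mean| = sqrt(2)
  expect_equal(goodness_g(g, c(1, 2, 4)), 1 - 1 / sqrt(2), tolerance = 1e-12)
  expect_error(goodness_g(rep(2, 5), 1:5),
               class = "pronyfit_error_degenerate_reference")
})

test_that("goodness depends only on the error and the centred reference", {
  set.seed(7)
  for (rep in 1:20) {
    g <- rnorm(50)
    e <- rnorm(50, sd = 0.3)
    expect_equal(goodness_g(g, g - e),
                 1 - sqrt(sum(e^2)) / sqrt(sum((g - mean(g))^2)),
                 tolerance = 1e-12)
  }
})

test_that("windowed SNR follows the group-mean denominator convention", {
  fs <- 1200
  n <- 600
  # constant record: signal and noise windows identical -> SNR 1
  expect_equal(record_snr(rep(3, n), fs), 1)

  # two-record group, one silent noise window: hand computation
  r1 <- rep(2, n)
  r2 <- rep(2, n)
  r2[window_indices_oracle(325, 430, fs)] <- 0
  tbl <- tibble::tibble(group = "g", subject = 1, eye = 1, channel = 1,
                        sector = 1:2, samples = list(r1, r2))
  out <- snr_records(tbl, fs)
  # group mean noise rms = (2 + 0) / 2 = 1; both signal windows have rms 2
  expect_equal(out$snr, c(2, 2))

  # all-zero group noise -> degenerate
  z <- tibble::tibble(group = "g", subject = 1, eye = 1, channel = 1,
                      sector = 1, samples = list(c(rep(1, 380), rep(0, 220))))
  expect_error(snr_records(z, fs), class = "pronyfit_error_degenerate_noise")
  expect_error(record_snr(rep(1, 100), fs), class = "pronyfit_error_window")
})

test_that("AUC equals the pair-enumeration oracle and complements itself", {
  expect_equal(auc_mann_whitney(c(2, 3), c(0, 1)), 1)
  expect_equal(auc_mann_whitney(1, 1), 0.5)
  expect_equal(auc_mann_whitney(c(1, 3), c(2, 0)), 0.75)
  set.seed(33)
  for (rep in 1:25) {
    pos <- sample(0:8, sample(2:12, 1), replace = TRUE)  # many ties
    neg <- sample(0:8, sample(2:12, 1), replace = TRUE)
    expect_equal(auc_mann_whitney(pos, neg), auc_bruteforce(pos, neg))
    expect_identical(auc_mann_whitney(pos, neg) +
                       auc_mann_whitney(neg, pos), 1)
  }
  expect_error(auc_mann_whitney(numeric(0), 1),
               class = "pronyfit_error_usage")
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  pos <- rnorm(40, 1)
  neg <- rnorm(35)
  ref <- as.numeric(pROC::auc(
    pROC::roc(response = c(rep(1, 40), rep(0, 35)), predictor = c(pos, neg),
              direction = "<", quiet = TRUE)
  ))
  expect_equal(auc_mann_whitney(pos, neg), ref, tolerance = 1e-12)
})
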