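# Small cohorts keep the suite fast; sectors play the role of repeated
# records within one (subject, eye, channel) SNR group.
small_spec <- function(...) {
  cohort_spec(n_control = 6, n_ms = 6, eyes = 1, sectors = 8, channels = 1,
              ...)
}

test_that("cohort generation is deterministic and shaped as labelled records", {
  spec <- small_spec()
  c1 <- generate_cohort(spec, seed = 2)
  c2 <- generate_cohort(spec, seed = 2)
  expect_identical(c1$samples, c2$samples)
  expect_equal(nrow(c1), 2 * 6 * 8)
  expect_true(all(lengths(c1$samples) == 600))
  expect_setequal(unique(c1$group), c("control", "ms"))
  expect_equal(attr(c1, "fs"), 1200)
})

test_that("response energy is confined to the 45-150 ms window", {
  spec <- small_spec(noise_rms = 1e-9, amp_median_control = 3,
                     amp_median_ms = 2, amp_sdlog = 0.2)
  coh <- generate_cohort(spec, seed = 4)
  for (x in coh$samples[1:5]) {
    inside <- window_rms(x, 1200, c(45, 150))
    outside <- window_rms(x, 1200, c(200, 499))
    expect_gt(inside, 100 * outside)
  }
})

test_that("a null cohort separates at chance and a one-sided cohort perfectly", {
  null_spec <- small_spec(amp_median_control = 0, amp_median_ms = 0)
  coh <- generate_cohort(null_spec, seed = 11)
  rep_dft <- run_mfvep_pipeline(coh, method = "dft")
  # binomial CI around 0.5 for 48 x 48 correlated pairs: generous band
  expect_gt(rep_dft$summary$auc, 0.3)
  expect_lt(rep_dft$summary$auc, 0.7)

  strong <- small_spec(amp_median_control = 60, amp_median_ms = 0,
                       amp_sdlog = 0.2)
  coh2 <- generate_cohort(strong, seed = 12)
  rep2 <- run_mfvep_pipeline(coh2, method = "dft")
  expect_gt(rep2$summary$auc, 0.99)
  expect_gt(rep2$summary$snr_control_mean, 10 * rep2$summary$snr_ms_mean)
})

test_that("empirical AUC matches the lognormal closed form at high amplitude", {
  # with responses far above noise, the SNR score is proportional to the
  # drawn lognormal amplitude, so AUC -> Phi(dlog / (sqrt(2) sdlog))
  sdlog <- 0.5
  spec <- cohort_spec(n_control = 10, n_ms = 10, eyes = 1, sectors = 12,
                      channels = 1, amp_median_control = 80,
                      amp_median_ms = 50, amp_sdlog = sdlog)
  coh <- generate_cohort(spec, seed = 21)
  rep <- run_mfvep_pipeline(coh, method = "dft")
  closed_form <- pnorm((log(80) - log(50)) / (sqrt(2) * sdlog))
  expect_equal(rep$summary$auc, closed_form, tolerance = 0.08)
})

test_that("the DFT baseline path skips approximation bookkeeping", {
  coh <- generate_cohort(small_spec(), seed = 5)
  rep <- run_mfvep_pipeline(coh, method = "dft")
  expect_identical(rep$summary$method, "dft")
  expect_true(is.na(rep$summary$well_pct_control))
  expect_true(is.na(rep$summary$well_pct_ms))
  expect_equal(rep$summary$n_scored, nrow(coh))
  expect_false(anyNA(tidy(rep)$snr))
})

test_that("Prony pipeline accounts for every record and reuses the pair oracle", {
  spec <- cohort_spec(n_control = 3, n_ms = 3, eyes = 1, sectors = 6,
                      channels = 1)
  coh <- generate_cohort(spec, seed = 8)
  rep <- run_mfvep_pipeline(coh, method = "ls", p = 100)
  rec <- tidy(rep)
  # well-approximated + failed = total, per group
  for (grp in c("control", "ms")) {
    n_grp <- sum(rec$group == grp)
    n_well <- sum(rec$group == grp & rec$well_approximated)
    pct <- if (grp == "control") rep$summary$well_pct_control else
      rep$summary$well_pct_ms
    expect_equal(n_well / n_grp * 100, pct)
    expect_equal(n_well + sum(rec$group == grp & !rec$well_approximated),
                 n_grp)
  }
  # excluded records carry no SNR
  expect_true(all(is.na(rec$snr[!rec$well_approximated])))
  # AUC equals brute-force enumeration on the surviving scores
  snr_c <- rec$snr[rec$group == "control" & !is.na(rec$snr)]
  snr_m <- rec$snr[rec$group == "ms" & !is.na(rec$snr)]
  expect_equal(rep$summary$auc, auc_bruteforce(snr_c, snr_m))

  # determinism of the whole pipeline
  rep2 <- run_mfvep_pipeline(generate_cohort(spec, seed = 8),
                             method = "ls", p = 100)
  expect_identical(rep$summary, rep2$summary)
})

test_that("records of uneven length are rejected", {
  coh <- generate_cohort(small_spec(), seed = 3)
  coh$samples[[1]] <- coh$samples[[1]][-1]
  expect_error(run_mfvep_pipeline(coh, method = "dft"),
               class = "pronyfit_error_usage")
})
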