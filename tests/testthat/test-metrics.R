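test_that("concentration series validate their structure", {
  expect_error(concentration_series(c(0.1, 0), list(1:5, 1:5)), "ascending")
  expect_error(concentration_series(c(0.1, 0.2), list(1:5, 1:5)), "blank")
  expect_error(concentration_series(c(0, 0.1), list(1:5, 3)), "at least 2")
})

test_that("CNR follows the differential-over-noise definition", {
  s <- concentration_series(c(0, 1), list(c(2, 2, 2, 2, 2) + c(-2, -1, 0, 1, 2),
                                          c(12, 12, 12, 12, 12) + c(-2, -1, 0, 1, 2)))
  expect_equal(cnr(s, 1), (12 - 2) / sd(c(-2, -1, 0, 1, 2)))
  expect_equal(cnr(s, 0), 0)  # self-difference
  expect_error(cnr(s, 0.5), "not in the series")
  # caption variant: maximum blank fluctuation
  expect_equal(cnr(s, 1, noise = "max_fluctuation"), 10 / 2)
  sd0 <- concentration_series(c(0, 1), list(c(1, 1), c(2, 2)))
  expect_error(cnr(sd0, 1), "degenerate")
})

test_that("simulated CNR matches its analytic expectation", {
  # known linear signal law + additive Gaussian noise, n = 5 repeats:
  # E[CNR] = contrast * E[1/S] with E[1/S] = sqrt((n-1)/2) *
  # gamma((n-2)/2) / gamma((n-1)/2) / sigma (mean and sd independent)
  sigma <- 0.4; slope <- 10; n <- 5
  inv_sd_factor <- sqrt((n - 1) / 2) * gamma((n - 2) / 2) / gamma((n - 1) / 2)
  set.seed(5)
  concs <- c(0, 0.5, 1)
  cnrs <- replicate(400, {
    meas <- lapply(concs, function(cc) slope * cc + rnorm(n, sd = sigma))
    cnr(concentration_series(concs, meas), 1)
  })
  expect_equal(mean(cnrs), slope * 1 * inv_sd_factor / sigma, tolerance = 0.05)
})

test_that("detection limit is the smallest concentration above the noise level", {
  concs <- c(0, 0.01, 0.05, 0.1)
  # noiseless-mean construction: signal 10*c, blank sd 0.4
  meas <- lapply(concs, function(cc) 10 * cc + c(-0.4, -0.2, 0, 0.2, 0.4))
  s <- concentration_series(concs, meas)
  level <- sd(c(-0.4, -0.2, 0, 0.2, 0.4))
  expected <- min(concs[concs > 0 & 10 * concs > level])
  expect_equal(detection_limit(s), expected)
  # max-fluctuation variant uses a higher threshold
  expect_equal(detection_limit(s, noise = "max_fluctuation"),
               min(concs[concs > 0 & 10 * concs > 0.4]))
  # nothing detected -> Inf sentinel
  flat <- concentration_series(c(0, 1), list(c(0, 1, -1), c(0.1, -0.1, 0)))
  expect_equal(detection_limit(flat), Inf)
  # non-increasing as noise shrinks
  lims <- vapply(c(2, 0.5, 0.2, 0.02), function(sg) {
    m <- lapply(concs, function(cc) 10 * cc + sg * c(-1, -0.5, 0, 0.5, 1))
    detection_limit(concentration_series(concs, m))
  }, numeric(1))
  expect_true(all(diff(lims) <= 0))
})

test_that("TTD beats the single-wavelength method when background fluctuation dominates", {
  # gain-fluctuation-dominated regime with a 5% blood background
  concs <- c(0, 0.002, 0.005, 0.01, 0.02)
  n_series <- 20
  cnr_t <- cnr_s <- matrix(0, n_series, length(concs) - 1)
  lim_ok <- logical(n_series)
  for (i in seq_len(n_series)) {
    ser <- simulate_concentration_series(concs, "blood", noise_sd = 0.005,
                                         gain_jitter_sd = 0.05,
                                         seed = 600 + i)
    cnr_t[i, ] <- vapply(concs[-1], function(cc) cnr(ser$TTD, cc), numeric(1))
    cnr_s[i, ] <- vapply(concs[-1], function(cc) cnr(ser$single_660, cc),
                         numeric(1))
    lim_ok[i] <- detection_limit(ser$TTD) <= detection_limit(ser$single_660)
  }
  expect_true(all(colMeans(cnr_t) > colMeans(cnr_s)))
  expect_gt(mean(lim_ok), 0.9)
})

test_that("ROI time-course normalizes and baselines correctly", {
  mask <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
  const <- replicate(3, matrix(2, 2, 2), simplify = FALSE)
  tc <- roi_timecourse(const, mask, c(0, 10, 20))
  expect_equal(tc$normalized, rep(1, 3))
  expect_equal(tc$change, rep(0, 3))
  expect_equal(tc$ratio, rep(1, 3))
  # saturating uptake is reproduced exactly
  times <- c(0, 5, 15, 40)
  up <- 3 * (1 - exp(-times / 8))
  imgs <- lapply(up, function(u) matrix(u, 2, 2))
  tc2 <- roi_timecourse(imgs, mask, times)
  expect_equal(tc2$mean_signal, up)
  expect_equal(tc2$normalized, up / max(up))
  expect_equal(tc2$change, up - up[1])
  expect_error(roi_timecourse(const, matrix(FALSE, 2, 2), c(0, 1, 2)), "empty")
  expect_error(roi_timecourse(const, mask, c(1, 2, 3)), "include 0")
})

test_that("sweeps compose the forward model and are seed-stable", {
  p1 <- quick_params(monomer_fraction = 1, k_q = 0, tau_monomer_0 = 2)
  sch <- quick_scheme()
  delays <- c(0.1, 0.5, 1, 2, 4)
  sw <- run_sweep("delay", delays, sch, p1, concentration = 1, repeats = 1)
  a0 <- ttd_amplitude(1, quick_scheme(delay_us = 0), p1)
  expect_equal(sw$mean_amplitude, a0 * exp(-delays / 2))
  # seed schedule: extending the grid does not perturb earlier points
  s1 <- run_sweep("delay", delays, sch, p1, concentration = 1, noise_sd = 0.05,
                  repeats = 3, base_seed = 50)
  s2 <- run_sweep("delay", c(delays, 8), sch, p1, concentration = 1,
                  noise_sd = 0.05, repeats = 3, base_seed = 50)
  expect_equal(s1$mean_amplitude, s2$mean_amplitude[1:5])
  expect_error(run_sweep("bogus", 1:3), "arg")
  # oxygen sweep: fitted lifetimes strictly ordered 7.5% > 21% > 45%
  taus <- vapply(c(7.5, 21, 45), function(o2) {
    par_o <- quick_params(oxygen_percent = o2)
    sw_o <- run_sweep("delay", delay_grid("oxygen"), sch, par_o,
                      concentration = 2, repeats = 1)
    fit_decay(sw_o$value, sw_o$mean_amplitude)$tau_eff
  }, numeric(1))
  expect_true(all(diff(taus) < 0))
})

test_that("sample comparison flags only genuine differences", {
  set.seed(9)
  vals <- list(ref = rnorm(5, 10), same = rnorm(5, 10),
               diff = rnorm(5, 20, 0.5))
  out <- compare_samples(vals, "ref")
  expect_equal(out$stars[out$sample == "same"], "")
  expect_true(out$stars[out$sample == "diff"] %in% c("**", "***"))
  expect_true(is.na(out$p_value[out$sample == "ref"]))
  expect_error(compare_samples(vals, "missing"), "not found")
})
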