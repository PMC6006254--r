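test_that("TTD extraction is the element-wise frame subtraction", {
  mk <- function(a, b, c) list(pump_frame = matrix(a, 2, 2),
                               probe_frame = matrix(b, 2, 2),
                               pumpprobe_frame = matrix(c, 2, 2))
  expect_equal(extract_ttd(mk(2, 3, 5))$ttd_map, matrix(0, 2, 2))
  expect_equal(extract_ttd(mk(2, 3, 5.5))$ttd_map, matrix(0.5, 2, 2))
  bad <- mk(1, 1, 2); bad$probe_frame <- matrix(1, 3, 3)
  expect_error(extract_ttd(bad), "identical shape")
  # linearity: extraction of a sum of triples is the sum of extractions
  set.seed(3)
  t1 <- mk(runif(1), runif(1), runif(1)); t2 <- mk(runif(1), runif(1), runif(1))
  sum_t <- Map(`+`, t1, t2)
  expect_equal(extract_ttd(sum_t)$ttd_map,
               extract_ttd(t1)$ttd_map + extract_ttd(t2)$ttd_map)
})

test_that("the active-set NNLS matches direct solve and reference solver", {
  A <- diag(3)
  expect_equal(nnls_solve(A, c(0, 0, 2))$x, c(0, 0, 2))
  expect_equal(nnls_solve(A, c(1, -1, 2))$x, c(1, 0, 2))
  set.seed(101)
  for (i in 1:50) {
    sys <- random_unmix_system()
    got <- nnls_solve(sys$A, sys$b)
    x0 <- solve(sys$A, sys$b)
    if (all(x0 >= 0)) {
      expect_equal(got$x, as.numeric(x0), tolerance = 1e-8)
    } else {
      oracle <- support_nnls_oracle(sys$A, sys$b)
      expect_equal(got$x, oracle$x, tolerance = 1e-6)
      expect_equal(got$residual, oracle$res, tolerance = 1e-8)
    }
    if (requireNamespace("pracma", quietly = TRUE)) {
      ref <- pracma::lsqnonneg(sys$A, sys$b)
      expect_equal(got$x, as.numeric(ref$x), tolerance = 1e-6)
    }
  }
})

test_that("spectral unmixing closes on data generated from its own model", {
  A <- absorption_matrix()
  truth <- list(hb = 0.02, hbo2 = 0.03, mbnp = 1.5)
  pa <- A %*% c(truth$hb, truth$hbo2, truth$mbnp)
  frames <- list("570" = matrix(pa[1], 2, 2), "606" = matrix(pa[2], 2, 2),
                 "660" = matrix(pa[3], 2, 2))
  um <- spectral_unmix(frames)
  expect_equal(um$hb_map, matrix(truth$hb, 2, 2), tolerance = 1e-9)
  expect_equal(um$hbo2_map, matrix(truth$hbo2, 2, 2), tolerance = 1e-9)
  expect_equal(um$mbnp_map, matrix(truth$mbnp, 2, 2), tolerance = 1e-9)
  expect_equal(um$residual_map, matrix(0, 2, 2), tolerance = 1e-9)
  # dye absent in truth: dye map is exactly zero (noise-free)
  pa0 <- A %*% c(0.02, 0.03, 0)
  frames0 <- list("570" = matrix(pa0[1], 1, 1), "606" = matrix(pa0[2], 1, 1),
                  "660" = matrix(pa0[3], 1, 1))
  expect_equal(spectral_unmix(frames0)$mbnp_map[1, 1], 0, tolerance = 1e-10)
  expect_error(spectral_unmix(frames[1:2]), "missing frames")
  expect_error(spectral_unmix(list("570" = matrix(1, 1, 1),
                                   "606" = matrix(1, 2, 2),
                                   "660" = matrix(1, 1, 1))), "same shape")
})

test_that("a collinear absorption matrix is refused with the pair named", {
  A <- absorption_matrix()
  A[, 2] <- 2 * A[, 1]   # make HbO2 proportional to Hb
  frames <- list("570" = matrix(1, 1, 1), "606" = matrix(1, 1, 1),
                 "660" = matrix(1, 1, 1))
  expect_error(spectral_unmix(frames, A = A), "collinear")
})

test_that("an unmodeled ink chromophore biases unmixing but not TTD", {
  p <- quick_params()
  sch <- quick_scheme()
  ser <- make_sample_series(nr = 8, nc = 8, radius = 2)
  mask <- attr(ser$MBNP_blood, "inclusion_mask")
  unmix_mean <- function(ph) {
    frames <- lapply(c(570, 606, 660), function(w)
      initial_pressure(ph, w, sch$pump_fluence))
    names(frames) <- c(570, 606, 660)
    mean(spectral_unmix(frames)$mbnp_map[mask])
  }
  ttd_mean <- function(ph)
    mean(extract_ttd(simulate_triple(ph, sch, p))$ttd_map[mask])
  # ink inflates the apparent dye concentration under unmixing ...
  expect_gt(unmix_mean(ser$MBNP_blood_ink), 1.5 * unmix_mean(ser$MBNP_blood))
  # ... while the TTD signal is invariant to it
  expect_equal(ttd_mean(ser$MBNP_blood_ink), ttd_mean(ser$MBNP_blood),
               tolerance = 1e-10)
  # and the single-wavelength differential at 660 nm grows with the ink
  base660 <- initial_pressure(ser$blood, 660, sch$pump_fluence)
  d_ink <- single_wavelength_diff(initial_pressure(ser$MBNP_blood_ink, 660,
                                                   sch$pump_fluence), base660)
  d_plain <- single_wavelength_diff(initial_pressure(ser$MBNP, 660,
                                                     sch$pump_fluence), base660)
  expect_gt(mean(d_ink[mask]), mean(d_plain[mask]))
})

test_that("single-wavelength differential subtracts element-wise, keeping negatives", {
  a <- matrix(c(3.5, 0.5), 1, 2); b <- matrix(1.0, 1, 2)
  expect_equal(single_wavelength_diff(a, b), matrix(c(2.5, -0.5), 1, 2))
  expect_equal(single_wavelength_diff(b, b), matrix(0, 1, 2))
  expect_error(single_wavelength_diff(a, matrix(1, 2, 2)), "identical shape")
})

test_that("normalization maps the series maximum to exactly 1", {
  x <- matrix(runif(9), 3)
  expect_equal(max(normalize_to_max(x)), 1)
  lst <- list(a = matrix(1:4, 2), b = matrix(5:8, 2))
  nl <- normalize_to_max(lst)
  expect_equal(max(unlist(nl)), 1)
  expect_equal(nl$a[1, 1], 1 / 8)
  expect_equal(normalize_to_max(matrix(0, 2, 2)), matrix(0, 2, 2))
})
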