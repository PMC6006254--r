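test_that("built-in spectra peak at the stated wavelengths", {
  wl <- seq(500, 900, by = 1)
  expect_equal(wl[which.max(specific_absorption("MBNP_ground", wl))], 660)
  expect_equal(wl[which.max(specific_absorption("MBNP_triplet", wl))], 840)
  expect_equal(wl[which.max(specific_absorption("GNP", wl))], 532)
  for (sp in chromophore_species()) {
    v <- specific_absorption(sp, c(570, 606, 660, 840))
    expect_true(all(v >= 0), info = sp)
  }
  # blue ink tracks the dye ground state over the unmixing wavelengths
  wl3 <- c(570, 606, 660)
  ink <- specific_absorption("blue_ink", wl3)
  dye <- specific_absorption("MBNP_ground", wl3)
  cosine <- sum(ink * dye) / sqrt(sum(ink^2) * sum(dye^2))
  expect_gt(cosine, 0.99)
  # 570 nm sits near the Hb/HbO2 isosbestic region
  expect_equal(specific_absorption("Hb", 570) / specific_absorption("HbO2", 570),
               1, tolerance = 0.1)
  expect_error(specific_absorption("Hb", 500), "extrapolation")
  spec <- chromophore_spectrum("GNP", c(532, 570))
  expect_equal(spec$specific_absorption[1], 80)
})

test_that("phantom construction validates maps", {
  m <- matrix(1, 4, 4)
  expect_error(phantom(list(m)), "named list")
  expect_error(phantom(list(unknown = m)), "unknown species")
  expect_error(phantom(list(Hb = -m)), "nonnegative")
  expect_error(phantom(list(Hb = m, HbO2 = matrix(1, 3, 3))), "same shape")
  ph <- phantom(list(Hb = m), pixel_size = 0.02)
  expect_equal(unname(ph$shape), c(4L, 4L))
})

test_that("initial pressure is the fluence-weighted absorption sum", {
  # single pixel identity: [MBNP]=2, a scaled to 1, fluence 1, gain 1
  ph <- phantom(list(MBNP_ground = matrix(2, 1, 1)), gruneisen_gain = 1)
  a660 <- specific_absorption("MBNP_ground", 660)
  expect_equal(initial_pressure(ph, 660, 1)[1, 1], 2 * a660)
  expect_equal(initial_pressure(ph, 660, 1 / a660)[1, 1], 2)
  # all-zero maps give all-zero signal
  ph0 <- phantom(list(Hb = matrix(0, 3, 2)))
  expect_equal(initial_pressure(ph0, 660, 20), matrix(0, 3, 2))
  # two-chromophore pixel at depth vs hand-computed sum
  ph2 <- phantom(list(Hb = matrix(0.3, 3, 1), MBNP_ground = matrix(1.5, 3, 1)),
                 pixel_size = 0.05, gruneisen_gain = 2)
  mu_eff <- tissue_mu_eff(ph2$background, 660)
  z <- c(0, 0.05, 0.10)
  hand <- 2 * 20 * exp(-mu_eff * z) *
    (0.3 * specific_absorption("Hb", 660) + 1.5 * a660)
  expect_equal(as.numeric(initial_pressure(ph2, 660, 20)), hand)
  # linearity in the lumped gain
  ph3 <- ph2; ph3$gruneisen_gain <- 4
  expect_equal(initial_pressure(ph3, 660, 20), 2 * initial_pressure(ph2, 660, 20))
})

test_that("simulated triples reproduce the kinetics amplitude law", {
  p <- quick_params()
  sch <- quick_scheme()
  ph <- ttdpa:::composition_phantom(mbnp = 2, nr = 1, nc = 1, radius = 1)
  tr <- simulate_triple(ph, sch, p)
  expect_equal(extract_ttd(tr)$ttd_map[1, 1], ttd_amplitude(2, sch, p),
               tolerance = 1e-12)
  # no dye -> the triple is exactly additive
  ph0 <- ttdpa:::composition_phantom(blood = 0.05, nr = 6, nc = 6, radius = 2)
  tr0 <- simulate_triple(ph0, sch, p)
  expect_lt(max(abs(extract_ttd(tr0)$ttd_map)), 1e-12)
  # pump+probe dominates both single-beam frames pixel-wise (noise-free)
  ph2 <- ttdpa:::composition_phantom(mbnp = 1, blood = 0.05, nr = 6, nc = 6,
                                     radius = 2)
  tr2 <- simulate_triple(ph2, sch, p)
  expect_true(all(tr2$pumpprobe_frame >= tr2$pump_frame))
  expect_true(all(tr2$pumpprobe_frame >= tr2$probe_frame))
  # seeded noise is reproducible; gain doubles every frame
  n1 <- simulate_triple(ph2, sch, p, noise_sd = 0.1, repeats = 3, seed = 11)
  n2 <- simulate_triple(ph2, sch, p, noise_sd = 0.1, repeats = 3, seed = 11)
  expect_identical(n1$pumpprobe_frame, n2$pumpprobe_frame)
  ph2x <- ph2; ph2x$gruneisen_gain <- 2
  t1 <- simulate_triple(ph2, sch, p); t2 <- simulate_triple(ph2x, sch, p)
  expect_equal(t2$pump_frame, 2 * t1$pump_frame)
  expect_equal(t2$pumpprobe_frame, 2 * t1$pumpprobe_frame)
})

test_that("the six-sample series has the stated compositions", {
  ser <- make_sample_series()
  expect_length(ser, 6)
  expect_named(ser, c("MBNP", "MBNP_blood", "MBNP_blood_ink", "MBNP_blood_GNP",
                      "blood", "water"))
  mask <- attr(ser$MBNP, "inclusion_mask")
  expect_true(all(ser$MBNP$maps$MBNP_ground[mask] == 2.0))
  expect_true(all(ser$MBNP_blood$maps$Hb[mask] +
                    ser$MBNP_blood$maps$HbO2[mask] == 0.05))
  expect_true(all(ser$MBNP_blood_ink$maps$blue_ink[mask] == 0.1))
  expect_true(all(ser$MBNP_blood_GNP$maps$GNP[mask] == 0.05))
  # two dye-free controls
  expect_equal(sum(ser$blood$maps$MBNP_ground), 0)
  expect_equal(sum(ser$water$maps$MBNP_ground), 0)
  # water control: only the water map is populated
  for (sp in setdiff(names(ser$water$maps), "water"))
    expect_equal(sum(ser$water$maps[[sp]]), 0)
  expect_gt(sum(ser$water$maps$water), 0)
  # oxygen saturation splits blood
  ser2 <- make_sample_series(so2 = 0.6)
  expect_equal(ser2$blood$maps$HbO2[mask] / 0.05, rep(0.6, sum(mask)))
})

test_that("tumor time-lapse follows saturating uptake", {
  tl <- make_tumor_timelapse(times = c(0, 1, 30, 60, 90), c_max = 1,
                             tau_uptake = 8)
  mask <- attr(tl, "tumor_mask")
  expect_equal(sum(tl$t0$maps$MBNP_ground), 0)  # pre-injection
  means <- vapply(tl, function(ph) mean(ph$maps$MBNP_ground[mask]), numeric(1))
  expect_true(all(diff(means) >= 0))
  # plateau: 30/60/90 min within 5% of each other
  expect_lt(diff(range(means[3:5])) / means[5], 0.05)
  # blood background constant over time
  expect_equal(tl$t90$maps$Hb, tl$t0$maps$Hb)
  expect_error(make_tumor_timelapse(times = c(1, 30)), "include 0")
})
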