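#' Weakly attenuating water-bath background
#'
#' Default optical background for phantoms: a nearly transparent coupling
#' medium (flat mu_a = 0.01 cm^-1, mu_s' = 0.1 cm^-1 over 500-900 nm), so the
#' fluence is close to constant over a small phantom, consistent with the
#' constant-fluence assumption of the spectral-unmixing model.
#'
#' @return A [tissue_optical_properties()] object.
#' @export
water_bath_background <- function() {
  tissue_optical_properties("water_bath", c(500, 900), c(0.01, 0.01),
                            c(0.1, 0.1))
}

#' Gridded phantom
#'
#' A 2-D phantom: per-species concentration maps on a common grid, an optical
#' background for fluence attenuation, and a lumped Grueneisen-times-system
#' gain. Row 1 is the illuminated surface; depth grows with row index.
#'
#' @param maps Named list of nonnegative numeric matrices, one per species
#'   (names from [chromophore_species()]); all the same shape. Units match
#'   [specific_absorption()]: mg/mL for MBNP_ground and blue_ink (% volume for
#'   ink), volume fraction for Hb/HbO2/GNP/water.
#' @param pixel_size Pixel edge, cm; default 0.01.
#' @param background A [tissue_optical_properties()] object used for fluence
#'   attenuation inside the phantom (inclusions do not perturb the fluence).
#' @param gruneisen_gain Lumped constant converting absorbed energy density to
#'   signal (Grueneisen parameter x system sensitivity).
#' @return An object of class `phantom`.
#' @export
phantom <- function(maps, pixel_size = 0.01,
                    background = water_bath_background(),
                    gruneisen_gain = 1) {
  if (!is.list(maps) || is.null(names(maps)) || any(names(maps) == ""))
    stop("maps must be a named list of matrices")
  unknown <- setdiff(names(maps), chromophore_species())
  if (length(unknown) > 0)
    stop("unknown species in maps: ", paste(unknown, collapse = ", "))
  maps <- lapply(maps, function(m) {
    m <- as.matrix(m)
    if (any(m < 0)) stop("concentration maps must be nonnegative")
    m
  })
  dims <- vapply(maps, dim, integer(2))
  if (length(maps) > 1 && any(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1]))
    stop("all concentration maps must share the same shape")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  if (gruneisen_gain < 0) stop("gruneisen_gain must be nonnegative")
  stopifnot(inherits(background, "tissue_optical_properties"))
  structure(list(maps = maps, pixel_size = pixel_size,
                 background = background, gruneisen_gain = gruneisen_gain,
                 shape = dims[, 1]),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("Phantom %d x %d (pixel %.3g cm), species: %s\n",
              x$shape[1], x$shape[2], x$pixel_size,
              paste(names(x$maps), collapse = ", ")))
  invisible(x)
}

# depth (cm) of each row; row 1 is the illuminated surface at z = 0
phantom_depths <- function(ph) (seq_len(ph$shape[1]) - 1) * ph$pixel_size

# per-row fluence attenuation factor exp(-mu_eff z) at a wavelength
phantom_fluence_factor <- function(ph, wavelength_nm) {
  mu_eff <- tissue_mu_eff(ph$background, wavelength_nm)
  exp(-mu_eff * phantom_depths(ph))
}

#' Initial photoacoustic pressure map
#'
#' Linear forward model: per pixel,
#' signal = gain * fluence(depth) * sum_x \[x\] a_x(lambda), with the fluence
#' attenuated by the background tissue's effective attenuation coefficient.
#'
#' @param ph A [phantom()].
#' @param wavelength_nm Illumination wavelength, nm.
#' @param surface_fluence Surface fluence, mJ/cm^2.
#' @return Signal matrix of the phantom's shape.
#' @export
initial_pressure <- function(ph, wavelength_nm, surface_fluence) {
  stopifnot(inherits(ph, "phantom"))
  mu_a_map <- matrix(0, ph$shape[1], ph$shape[2])
  for (sp in names(ph$maps))
    mu_a_map <- mu_a_map + ph$maps[[sp]] * specific_absorption(sp, wavelength_nm)
  fluence <- surface_fluence * phantom_fluence_factor(ph, wavelength_nm)
  ph$gruneisen_gain * fluence * mu_a_map
}

# noise-free TTD contribution map: the kinetics amplitude law evaluated with
# both beams attenuated to the pixel's depth
ttd_contribution_map <- function(ph, scheme, params) {
  fp <- phantom_fluence_factor(ph, scheme$pump_nm)
  fr <- phantom_fluence_factor(ph, scheme$probe_nm)
  conc <- ph$maps[["MBNP_ground"]]
  if (is.null(conc)) return(matrix(0, ph$shape[1], ph$shape[2]))
  tf <- triplet_fraction_after_pump(scheme$pump_fluence * fp, params)
  surv <- triplet_survival(scheme$delay_us, params)
  probe_local <- scheme$probe_fluence * fr
  ph$gruneisen_gain * params$triplet_specific_signal * conc *
    (tf * surv * probe_local)  # per-row factors recycle down columns
}

#' Simulate a pump / probe / pump+probe measurement triple
#'
#' Generates the three frames of one TTD acquisition: pump-only at the pump
#' wavelength, probe-only at the probe wavelength (ground-state absorption
#' only), and pump+probe, which adds the triplet differential contribution of
#' the dye. Noise is additive i.i.d. Gaussian per pixel per repeat; an
#' optional multiplicative gain jitter, drawn once per repeat and shared by
#' the three frames, models slow acquisition-gain / coupling fluctuations
#' (default off). Frames are averaged over repeats.
#'
#' @param ph A [phantom()].
#' @param scheme An [excitation_scheme()].
#' @param params A [photophysics_params()] object.
#' @param noise_sd Additive noise standard deviation, signal units.
#' @param repeats Number of repeated acquisitions averaged; >= 1.
#' @param seed Integer seed making the noise reproducible; NULL leaves the
#'   RNG state alone.
#' @param gain_jitter_sd Fractional standard deviation of the per-repeat
#'   common gain factor; default 0.
#' @return An object of class `measurement_triple` with `pump_frame`,
#'   `probe_frame`, `pumpprobe_frame`, the scheme, and the noise-free
#'   `ttd_true` map.
#' @export
simulate_triple <- function(ph, scheme, params, noise_sd = 0, repeats = 1,
                            seed = NULL, gain_jitter_sd = 0) {
  stopifnot(inherits(ph, "phantom"), inherits(scheme, "excitation_scheme"),
            inherits(params, "photophysics_params"))
  if (repeats < 1) stop("repeats must be >= 1")
  if (noise_sd < 0 || gain_jitter_sd < 0)
    stop("noise parameters must be nonnegative")
  if (!is.null(seed)) set.seed(as.integer(seed))
  pump0 <- initial_pressure(ph, scheme$pump_nm, scheme$pump_fluence)
  probe0 <- initial_pressure(ph, scheme$probe_nm, scheme$probe_fluence)
  ttd0 <- ttd_contribution_map(ph, scheme, params)
  pp0 <- pump0 + probe0 + ttd0
  npx <- length(pump0)
  acc <- list(pump = 0, probe = 0, pp = 0)
  for (r in seq_len(repeats)) {
    g <- if (gain_jitter_sd > 0) 1 + stats::rnorm(1, sd = gain_jitter_sd) else 1
    nz <- function() if (noise_sd > 0)
      matrix(stats::rnorm(npx, sd = noise_sd), nrow(pump0)) else 0
    acc$pump <- acc$pump + g * pump0 + nz()
    acc$probe <- acc$probe + g * probe0 + nz()
    acc$pp <- acc$pp + g * pp0 + nz()
  }
  structure(list(pump_frame = acc$pump / repeats,
                 probe_frame = acc$probe / repeats,
                 pumpprobe_frame = acc$pp / repeats,
                 scheme = scheme, repeats = repeats, noise_sd = noise_sd,
                 gain_jitter_sd = gain_jitter_sd, seed = seed,
                 pixel_size = ph$pixel_size,
                 ttd_true = ttd0, mode = "frame"),
            class = "measurement_triple")
}

# circular inclusion mask (tube cross-section) on an nr x nc grid
tube_mask <- function(nr = 24, nc = 24, radius = 6,
                      center = c((nr + 1) / 2, (nc + 1) / 2)) {
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  (rows - center[1])^2 + (cols - center[2])^2 <= radius^2
}

# build a phantom whose tube contains the given composition
composition_phantom <- function(mbnp = 0, blood = 0, ink = 0, gnp = 0,
                                water = 1, so2 = 0.75, nr = 24, nc = 24,
                                radius = 6, pixel_size = 0.01,
                                gruneisen_gain = 1,
                                center = c((nr + 1) / 2, (nc + 1) / 2)) {
  mask <- tube_mask(nr, nc, radius, center)
  m <- function(v) v * mask + 0  # numeric matrix
  maps <- list(MBNP_ground = m(mbnp),
               Hb = m(blood * (1 - so2)),
               HbO2 = m(blood * so2),
               blue_ink = m(ink),
               GNP = m(gnp),
               water = m(water))
  ph <- phantom(maps, pixel_size = pixel_size, gruneisen_gain = gruneisen_gain)
  attr(ph, "inclusion_mask") <- mask
  ph
}

#' The six-sample background-comparison series
#'
#' Builds the six tube phantoms used to compare recovery methods across
#' backgrounds: 2.0 mg/mL dye alone; dye in 5% blood; dye in 5% blood +
#' 0.1% blue ink; dye in 5% blood + 5% gold nanoparticles; 5% blood only;
#' and distilled water. The last two are the dye-free controls. Blood is
#' split between Hb and HbO2 by the oxygen-saturation fraction.
#'
#' @param mbnp Dye concentration in the dye-containing samples, mg/mL.
#' @param blood Blood volume fraction in blood-containing samples.
#' @param ink Blue-ink concentration, % volume.
#' @param gnp Gold-nanoparticle volume fraction.
#' @param so2 Blood oxygen saturation fraction splitting blood into HbO2/Hb.
#' @param ... Grid arguments passed to the phantom builder
#'   (`nr`, `nc`, `radius`, `pixel_size`, `gruneisen_gain`).
#' @return Named list of six [phantom()] objects, in presentation order.
#' @export
make_sample_series <- function(mbnp = 2.0, blood = 0.05, ink = 0.1,
                               gnp = 0.05, so2 = 0.75, ...) {
  list(
    MBNP = composition_phantom(mbnp = mbnp, so2 = so2, ...),
    MBNP_blood = composition_phantom(mbnp = mbnp, blood = blood, so2 = so2, ...),
    MBNP_blood_ink = composition_phantom(mbnp = mbnp, blood = blood, ink = ink,
                                         so2 = so2, ...),
    MBNP_blood_GNP = composition_phantom(mbnp = mbnp, blood = blood, gnp = gnp,
                                         so2 = so2, ...),
    blood = composition_phantom(blood = blood, so2 = so2, ...),
    water = composition_phantom(...)
  )
}

#' Tumor accumulation time-lapse phantoms
#'
#' Emulates post-injection accumulation of the dye nanoparticles in a
#' subcutaneous tumor: the dye concentration inside a circular tumor mask
#' follows a saturating uptake curve `C_max * (1 - exp(-t / tau_uptake))`
#' (zero just before injection), while the blood background stays constant.
#'
#' @param times Time points, minutes; must include 0 (pre-injection).
#' @param c_max Plateau dye concentration in the tumor, mg/mL.
#' @param tau_uptake Uptake time constant, minutes; the default 8 min puts the
#'   plateau within a few percent by 30 min.
#' @param blood Background blood volume fraction (uniform, constant in time).
#' @param so2 Blood oxygen saturation fraction.
#' @param nr,nc,radius,pixel_size,gruneisen_gain Grid parameters.
#' @return Named list (one element per time, names like "t0", "t30") of
#'   [phantom()] objects; attribute `times` carries the time vector and
#'   attribute `tumor_mask` the logical ROI mask.
#' @export
make_tumor_timelapse <- function(times = c(0, 1, 30, 60, 90), c_max = 1.0,
                                 tau_uptake = 8, blood = 0.02, so2 = 0.75,
                                 nr = 24, nc = 24, radius = 6,
                                 pixel_size = 0.01, gruneisen_gain = 1) {
  if (!0 %in% times) stop("times must include 0 (pre-injection)")
  mask <- tube_mask(nr, nc, radius)
  out <- lapply(times, function(t) {
    conc <- c_max * (1 - exp(-t / tau_uptake))
    maps <- list(MBNP_ground = conc * mask + 0,
                 Hb = matrix(blood * (1 - so2), nr, nc),
                 HbO2 = matrix(blood * so2, nr, nc),
                 water = matrix(1, nr, nc))
    phantom(maps, pixel_size = pixel_size, gruneisen_gain = gruneisen_gain)
  })
  names(out) <- paste0("t", times)
  attr(out, "times") <- times
  attr(out, "tumor_mask") <- mask
  out
}
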