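#' Concentration series of repeated measurements
#'
#' Per-concentration repeated scalar measurements for one recovery method,
#' as produced by a dilution-series experiment.
#'
#' @param concentrations Concentrations, mg/mL, sorted ascending, including 0.
#' @param measurements List of numeric vectors, one per concentration, each
#'   holding the repeat measurements (>= 2 repeats).
#' @param method Method label: one of `"single_660"`, `"SU"`, `"TTD"`.
#' @return An object of class `concentration_series`.
#' @export
concentration_series <- function(concentrations, measurements,
                                 method = c("TTD", "SU", "single_660")) {
  method <- match.arg(method)
  concentrations <- as.numeric(concentrations)
  if (length(concentrations) != length(measurements))
    stop("one measurement vector per concentration is required")
  if (is.unsorted(concentrations, strictly = TRUE))
    stop("concentrations must be sorted strictly ascending")
  if (!0 %in% concentrations)
    stop("the series must include the blank (concentration 0)")
  if (any(vapply(measurements, length, integer(1)) < 2))
    stop("each concentration needs at least 2 repeats")
  structure(list(concentrations = concentrations,
                 measurements = lapply(measurements, as.numeric),
                 method = method),
            class = "concentration_series")
}

series_means <- function(series)
  vapply(series$measurements, mean, numeric(1))

blank_index <- function(series) match(0, series$concentrations)

# noise level of a series per the two published definitions
series_noise_level <- function(series, noise = c("blank_sd", "max_fluctuation")) {
  noise <- match.arg(noise)
  blank <- series$measurements[[blank_index(series)]]
  if (noise == "blank_sd") stats::sd(blank) else max(abs(blank - mean(blank)))
}

#' Contrast-to-noise ratio at one concentration
#'
#' `(mean signal at c - mean signal at blank) / noise`, where the noise is by
#' default the standard deviation of the repeats at concentration `c`; the
#' alternative `"max_fluctuation"` definition divides by the maximum absolute
#' deviation of the blank repeats from their mean.
#'
#' @param series A [concentration_series()].
#' @param concentration A concentration present in the series, mg/mL.
#' @param noise `"repeat_sd"` (default) or `"max_fluctuation"`.
#' @return Dimensionless CNR.
#' @export
cnr <- function(series, concentration, noise = c("repeat_sd", "max_fluctuation")) {
  stopifnot(inherits(series, "concentration_series"))
  noise <- match.arg(noise)
  i <- match(concentration, series$concentrations)
  if (is.na(i)) stop("concentration ", concentration, " is not in the series")
  contrast <- mean(series$measurements[[i]]) -
    mean(series$measurements[[blank_index(series)]])
  denom <- if (noise == "repeat_sd") stats::sd(series$measurements[[i]])
           else series_noise_level(series, "max_fluctuation")
  if (denom == 0) stop("zero noise estimate: degenerate noise-free input")
  contrast / denom
}

#' Detection limit (sensitivity) of a series
#'
#' The smallest concentration whose mean differential signal (mean at c minus
#' mean at blank) exceeds the noise level. The noise level is by default one
#' standard deviation of the blank repeats; `"max_fluctuation"` uses the
#' maximum absolute blank deviation instead. Returns `Inf` if no
#' concentration is detected.
#'
#' @param series A [concentration_series()].
#' @param noise `"blank_sd"` (default) or `"max_fluctuation"`.
#' @return Detection limit, mg/mL (`Inf` if nothing is detected).
#' @export
detection_limit <- function(series, noise = c("blank_sd", "max_fluctuation")) {
  stopifnot(inherits(series, "concentration_series"))
  level <- series_noise_level(series, match.arg(noise))
  m <- series_means(series)
  diff_sig <- m - m[blank_index(series)]
  detected <- series$concentrations > 0 & diff_sig > level
  if (!any(detected)) return(Inf)
  min(series$concentrations[detected])
}

#' ROI mean time-course with normalization and baseline change
#'
#' Per time point, the mean signal over a region-of-interest mask; reported
#' normalized to the series maximum, as change versus the pre-injection
#' baseline (t = 0), and as a ratio to baseline.
#'
#' @param images List of signal matrices, one per time point.
#' @param mask Logical matrix of the images' shape; must select >= 1 pixel.
#' @param times Numeric time points (minutes); must include 0.
#' @return Data frame with `time`, `mean_signal`, `normalized`, `change`
#'   (mean(t) - mean(0)) and `ratio` (mean(t) / mean(0), NA if baseline is 0).
#' @export
roi_timecourse <- function(images, mask, times) {
  if (!any(mask)) stop("ROI mask is empty")
  if (length(images) != length(times))
    stop("one image per time point is required")
  if (!0 %in% times) stop("times must include 0 (baseline)")
  means <- vapply(images, function(img) {
    if (!identical(dim(img), dim(mask)))
      stop("image and mask shapes differ")
    mean(img[mask])
  }, numeric(1))
  base <- means[match(0, times)]
  mx <- max(means)
  data.frame(time = times, mean_signal = means,
             normalized = if (mx == 0) means else means / mx,
             change = means - base,
             ratio = if (base == 0) NA_real_ else means / base)
}

# one scalar TTD amplitude: tube-mean of the extracted TTD map
triple_ttd_mean <- function(triple, mask = NULL) {
  m <- extract_ttd(triple)$ttd_map
  if (is.null(mask)) mean(m) else mean(m[mask])
}

#' Sweep the TTD amplitude over an acquisition parameter
#'
#' Runs the forward simulation and TTD extraction over a grid of one
#' acquisition variable (`delay`, `oxygen`, `concentration`, `pump_energy`,
#' `probe_energy`) or over a 2-D `pump_energy` x `probe_energy` grid, with
#' `repeats` independent acquisitions per grid point. Seeds follow
#' `base_seed + grid index` so grids are extensible without perturbing
#' earlier points.
#'
#' @param variable One of `"delay"`, `"oxygen"`, `"concentration"`,
#'   `"pump_energy"`, `"probe_energy"`, `"pump_probe_energy"`.
#' @param grid Numeric vector of values; for `"pump_probe_energy"` a list
#'   with elements `pump` and `probe`.
#' @param scheme Base [excitation_scheme()].
#' @param params Base [photophysics_params()].
#' @param concentration Dye concentration of the sample, mg/mL (ignored when
#'   sweeping concentration).
#' @param noise_sd,gain_jitter_sd Noise configuration per acquisition.
#' @param repeats Acquisitions per grid point.
#' @param base_seed Integer seed anchoring the seed schedule; NULL for
#'   unseeded noise.
#' @param nr,nc,radius,pixel_size Phantom grid (defaults: a single pixel).
#' @return An object of class `sweep_result`: a data frame with the swept
#'   value(s), `mean_amplitude` and `sd`, plus attributes `variable` and
#'   `normalization` (the maximum mean amplitude).
#' @export
run_sweep <- function(variable, grid, scheme = excitation_scheme(),
                      params = photophysics_params(), concentration = 2.0,
                      noise_sd = 0, gain_jitter_sd = 0, repeats = 5,
                      base_seed = NULL, nr = 1, nc = 1, radius = 1,
                      pixel_size = 0.01) {
  variable <- match.arg(variable, c("delay", "oxygen", "concentration",
                                    "pump_energy", "probe_energy",
                                    "pump_probe_energy"))
  if (variable == "pump_probe_energy") {
    if (!is.list(grid) || !all(c("pump", "probe") %in% names(grid)))
      stop("for a 2-D energy sweep, grid must be list(pump = ..., probe = ...)")
    pts <- expand.grid(pump_energy = grid$pump, probe_energy = grid$probe,
                       KEEP.OUT.ATTRS = FALSE)
  } else {
    if (length(grid) == 0) stop("grid must be nonempty")
    pts <- data.frame(value = as.numeric(grid))
  }
  one_point <- function(i) {
    sch <- scheme; par <- params; conc <- concentration
    if (variable == "delay") sch$delay_us <- pts$value[i]
    if (variable == "oxygen") par$oxygen_percent <- pts$value[i]
    if (variable == "concentration") conc <- pts$value[i]
    if (variable == "pump_energy") sch$pump_fluence <- pts$value[i]
    if (variable == "probe_energy") sch$probe_fluence <- pts$value[i]
    if (variable == "pump_probe_energy") {
      sch$pump_fluence <- pts$pump_energy[i]
      sch$probe_fluence <- pts$probe_energy[i]
    }
    ph <- composition_phantom(mbnp = conc, nr = nr, nc = nc, radius = radius,
                              pixel_size = pixel_size)
    mask <- attr(ph, "inclusion_mask")
    vals <- vapply(seq_len(repeats), function(r) {
      seed <- if (is.null(base_seed)) NULL else base_seed + (i - 1L) * repeats + r
      triple_ttd_mean(simulate_triple(ph, sch, par, noise_sd = noise_sd,
                                      repeats = 1, seed = seed,
                                      gain_jitter_sd = gain_jitter_sd), mask)
    }, numeric(1))
    c(mean(vals), stats::sd(vals))
  }
  stats_m <- t(vapply(seq_len(nrow(pts)), one_point, numeric(2)))
  out <- cbind(pts, mean_amplitude = stats_m[, 1], sd = stats_m[, 2])
  attr(out, "variable") <- variable
  attr(out, "normalization") <- max(out$mean_amplitude)
  class(out) <- c("sweep_result", class(out))
  out
}

#' Pairwise comparison of sample TTD/SU amplitudes against a reference
#'
#' Two-sided two-sample t-tests of each sample's repeat values against the
#' reference sample's (the dye-only sample, by convention), with the
#' significance stars used in the background-comparison figure
#' (`**` p < 0.01, `***` p < 0.001).
#'
#' @param values Named list of numeric vectors of repeat values per sample.
#' @param reference Name of the reference sample; default the first.
#' @return Data frame with `sample`, `mean`, `p_value`, `stars`.
#' @export
compare_samples <- function(values, reference = names(values)[1]) {
  if (!reference %in% names(values))
    stop("reference sample ", reference, " not found")
  ref <- values[[reference]]
  rows <- lapply(names(values), function(nm) {
    p <- if (nm == reference) NA_real_ else
      stats::t.test(values[[nm]], ref)$p.value
    data.frame(sample = nm, mean = mean(values[[nm]]), p_value = p,
               stars = if (is.na(p)) "" else if (p < 0.001) "***"
                       else if (p < 0.01) "**" else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate a dilution-series experiment for the three recovery methods
#'
#' Generates, per concentration and repeat, the full acquisition set of one
#' tube sample (frames at 570/606/660/840 nm and pump+probe) on a single-pixel
#' phantom and reduces it by the three methods: raw 660 nm signal
#' (single-wavelength method), constrained spectral unmixing of 570/606/660,
#' and TTD extraction. A per-repeat multiplicative gain factor is shared by
#' all frames of one acquisition set, on top of additive per-frame noise.
#'
#' @param concentrations Dye concentrations, mg/mL, ascending, including 0.
#' @param background `"blood"` (5% whole blood) or `"water"`.
#' @param scheme [excitation_scheme()]; its pump fluence is used for all
#'   unmixing wavelengths (constant-fluence assumption).
#' @param params [photophysics_params()].
#' @param noise_sd Additive noise sd per frame.
#' @param gain_jitter_sd Fractional sd of the per-acquisition gain factor.
#' @param repeats Repeats per concentration.
#' @param seed Integer seed; NULL leaves RNG state alone.
#' @param blood Blood volume fraction for the blood background.
#' @param so2 Blood oxygen saturation.
#' @return Named list of three [concentration_series()]: `single_660`, `SU`,
#'   `TTD`. SU is skipped (NULL) for the water background, which contains no
#'   hemoglobin.
#' @export
simulate_concentration_series <- function(concentrations,
                                          background = c("blood", "water"),
                                          scheme = excitation_scheme(delay_us = 0.2),
                                          params = photophysics_params(),
                                          noise_sd = 0.12,
                                          gain_jitter_sd = 0.05,
                                          repeats = 5, seed = NULL,
                                          blood = 0.05, so2 = 0.75) {
  background <- match.arg(background)
  if (!is.null(seed)) set.seed(as.integer(seed))
  bl <- if (background == "blood") blood else 0
  wl_su <- c(570, 606, 660)
  A <- absorption_matrix(wl_su)
  out <- list(single_660 = list(), SU = list(), TTD = list())
  for (k in seq_along(concentrations)) {
    ph <- composition_phantom(mbnp = concentrations[k], blood = bl, so2 = so2,
                              nr = 1, nc = 1, radius = 1)
    # noise-free scalar signals of the acquisition set
    su_clean <- vapply(wl_su, function(w)
      initial_pressure(ph, w, scheme$pump_fluence)[1, 1], numeric(1))
    pump_clean <- su_clean[wl_su == 660]
    probe_clean <- initial_pressure(ph, scheme$probe_nm,
                                    scheme$probe_fluence)[1, 1]
    ttd_clean <- ttd_contribution_map(ph, scheme, params)[1, 1]
    v_single <- v_su <- v_ttd <- numeric(repeats)
    for (r in seq_len(repeats)) {
      g <- 1 + if (gain_jitter_sd > 0) stats::rnorm(1, sd = gain_jitter_sd) else 0
      nz <- function(n) stats::rnorm(n, sd = noise_sd)
      su_meas <- g * su_clean + nz(3)
      probe_meas <- g * probe_clean + nz(1)
      pp_meas <- g * (pump_clean + probe_clean + ttd_clean) + nz(1)
      v_single[r] <- su_meas[3]
      v_su[r] <- nnls_solve(A, su_meas)$x[3]
      v_ttd[r] <- pp_meas - su_meas[3] - probe_meas
    }
    out$single_660[[k]] <- v_single
    out$SU[[k]] <- v_su
    out$TTD[[k]] <- v_ttd
  }
  res <- list(
    single_660 = concentration_series(concentrations, out$single_660, "single_660"),
    SU = if (background == "blood")
      concentration_series(concentrations, out$SU, "SU") else NULL,
    TTD = concentration_series(concentrations, out$TTD, "TTD")
  )
  res
}
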