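#' Run configuration
#'
#' One serializable object controlling a full experiment run: photophysics
#' parameters, excitation scheme, phantom recipe, noise configuration, seed
#' and output directory. Re-running the same config reproduces all outputs.
#'
#' @param photophysics Named list of overrides for [photophysics_params()].
#' @param scheme Named list of overrides for [excitation_scheme()].
#' @param phantom Named list with `recipe` (e.g. `"six_samples"`,
#'   `"tumor_timelapse"`, `"tube"`) and recipe overrides.
#' @param noise_sd Additive noise sd, signal units.
#' @param gain_jitter_sd Fractional per-acquisition gain jitter sd.
#' @param repeats Repeats per acquisition.
#' @param seed Integer master seed; every stochastic stage derives its seed
#'   from it.
#' @param output_dir Directory for experiment outputs.
#' @return An object of class `run_config`.
#' @export
run_config <- function(photophysics = list(), scheme = list(),
                       phantom = list(recipe = "tube"), noise_sd = 0.12,
                       gain_jitter_sd = 0.05, repeats = 5, seed = 1,
                       output_dir = tempfile("ttd_run_")) {
  cfg <- list(photophysics = photophysics, scheme = scheme, phantom = phantom,
              noise_sd = noise_sd, gain_jitter_sd = gain_jitter_sd,
              repeats = repeats, seed = as.integer(seed),
              output_dir = output_dir)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

.config_keys <- c("photophysics", "scheme", "phantom", "noise_sd",
                  "gain_jitter_sd", "repeats", "seed", "output_dir")

validate_run_config <- function(cfg) {
  unknown <- setdiff(names(cfg), .config_keys)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  bad_pp <- setdiff(names(cfg$photophysics), names(formals(photophysics_params)))
  if (length(bad_pp) > 0)
    stop("unknown photophysics key(s): ", paste(bad_pp, collapse = ", "))
  bad_sc <- setdiff(names(cfg$scheme), names(formals(excitation_scheme)))
  if (length(bad_sc) > 0)
    stop("unknown scheme key(s): ", paste(bad_sc, collapse = ", "))
  if (cfg$noise_sd < 0 || cfg$gain_jitter_sd < 0 || cfg$repeats < 1)
    stop("invalid noise/repeats configuration")
  invisible(cfg)
}

config_params <- function(cfg) do.call(photophysics_params, cfg$photophysics)
config_scheme <- function(cfg) do.call(excitation_scheme, cfg$scheme)

#' Write / read a run configuration as YAML
#'
#' Reading validates the schema and rejects unknown keys by name.
#'
#' @param cfg A [run_config()].
#' @param path YAML file path.
#' @return `read_config` returns a [run_config()]; `write_config` the path,
#'   invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' Write / read a signal frame as CSV
#'
#' Plain numeric matrix CSV (no header); write-then-read is identity.
#'
#' @param frame Numeric matrix.
#' @param path CSV path.
#' @return `read_frame_csv` returns the matrix.
#' @export
write_frame_csv <- function(frame, path) {
  utils::write.table(frame, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_frame_csv
#' @export
read_frame_csv <- function(path) {
  as.matrix(utils::read.table(path, sep = ","))
}

#' Write / read a phantom as a directory of CSV maps plus YAML metadata
#'
#' One CSV per species map, plus `meta.yaml` holding pixel size, gain and the
#' background tissue table. Write-then-read is identity.
#'
#' @param ph A [phantom()].
#' @param dir Directory (created if needed).
#' @return `read_phantom` returns the [phantom()].
#' @export
write_phantom <- function(ph, dir) {
  stopifnot(inherits(ph, "phantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sp in names(ph$maps))
    write_frame_csv(ph$maps[[sp]], file.path(dir, paste0("map_", sp, ".csv")))
  bg <- ph$background
  yaml::write_yaml(list(schema_version = 1L,
                        pixel_size = ph$pixel_size,
                        gruneisen_gain = ph$gruneisen_gain,
                        species = names(ph$maps),
                        background = list(tissue_name = bg$tissue_name,
                                          wavelengths = bg$wavelengths,
                                          mu_a = bg$mu_a,
                                          mu_s_prime = bg$mu_s_prime)),
                   file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(dir) {
  meta_path <- file.path(dir, "meta.yaml")
  if (!file.exists(meta_path)) stop("no meta.yaml found in ", dir)
  meta <- yaml::read_yaml(meta_path)
  if (!identical(as.integer(meta$schema_version), 1L))
    stop("unsupported phantom schema version: ", meta$schema_version)
  maps <- lapply(meta$species, function(sp)
    read_frame_csv(file.path(dir, paste0("map_", sp, ".csv"))))
  names(maps) <- meta$species
  bg <- meta$background
  phantom(maps, pixel_size = meta$pixel_size,
          background = tissue_optical_properties(bg$tissue_name,
                                                 unlist(bg$wavelengths),
                                                 unlist(bg$mu_a),
                                                 unlist(bg$mu_s_prime)),
          gruneisen_gain = meta$gruneisen_gain)
}

#' Write / read a concentration series as tidy CSV
#'
#' Long format: one row per (concentration, repeat) with columns
#' `method`, `concentration`, `repeat_index`, `value`.
#'
#' @param series A [concentration_series()].
#' @param path CSV path.
#' @return `read_series_csv` returns the [concentration_series()].
#' @export
write_series_csv <- function(series, path) {
  stopifnot(inherits(series, "concentration_series"))
  rows <- do.call(rbind, lapply(seq_along(series$concentrations), function(i) {
    v <- series$measurements[[i]]
    data.frame(method = series$method,
               concentration = series$concentrations[i],
               repeat_index = seq_along(v), value = v)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  df <- utils::read.csv(path)
  concs <- sort(unique(df$concentration))
  meas <- lapply(concs, function(cc)
    df$value[df$concentration == cc][order(df$repeat_index[df$concentration == cc])])
  concentration_series(concs, meas, unique(df$method))
}

# manifest: config hash, seed, package version -- enough to audit a run
write_manifest <- function(cfg, dir, files) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  hashed <- unclass(cfg)
  hashed$output_dir <- NULL  # the science config, not where it is written
  yaml::write_yaml(hashed, tmp)
  manifest <- list(config_md5 = unname(tools::md5sum(tmp)),
                   seed = cfg$seed,
                   package = "ttdpa",
                   version = as.character(utils::packageVersion("ttdpa")),
                   files = basename(files))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  path
}

#' Run a named end-to-end experiment from one configuration
#'
#' Regenerates one of the figure-level analyses from a single config:
#' \describe{
#'   \item{waveforms}{pump/probe/pump+probe A-line traces and their raw
#'     subtraction for a tube sample.}
#'   \item{kinetic_sweeps}{delay, oxygen and concentration sweeps of the TTD
#'     amplitude, with decay fits.}
#'   \item{energy_depth}{2-D pump x probe energy sweep and the
#'     penetration-depth table for the bundled skin/breast tissue files.}
#'   \item{cnr_sensitivity}{dilution series in blood and water for the three
#'     methods; CNR table and detection limits.}
#'   \item{backgrounds}{the six-sample background comparison with t-tests.}
#'   \item{timelapse}{tumor accumulation time-lapse and ROI time-courses.}
#' }
#' Writes tidy CSV tables plus a JSON manifest into `cfg$output_dir` and
#' returns the result tables invisibly.
#'
#' @param cfg A [run_config()].
#' @param experiment Experiment name (see Details).
#' @return Invisibly, a named list of result data frames (also written as
#'   CSV files).
#' @export
run_experiment <- function(cfg, experiment = c("waveforms", "kinetic_sweeps",
                                               "energy_depth",
                                               "cnr_sensitivity",
                                               "backgrounds", "timelapse")) {
  stopifnot(inherits(cfg, "run_config"))
  experiment <- match.arg(experiment)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(cfg$output_dir))
    stop("cannot create output directory ", cfg$output_dir)
  results <- switch(experiment,
                    waveforms = exp_waveforms(cfg),
                    kinetic_sweeps = exp_kinetic_sweeps(cfg),
                    energy_depth = exp_energy_depth(cfg),
                    cnr_sensitivity = exp_cnr_sensitivity(cfg),
                    backgrounds = exp_backgrounds(cfg),
                    timelapse = exp_timelapse(cfg))
  files <- character(0)
  for (nm in names(results)) {
    f <- file.path(cfg$output_dir, paste0(experiment, "_", nm, ".csv"))
    utils::write.csv(results[[nm]], f, row.names = FALSE)
    files <- c(files, f)
  }
  write_manifest(cfg, cfg$output_dir, files)
  message(sprintf("experiment '%s': wrote %d table(s) to %s (seed %d)",
                  experiment, length(files), cfg$output_dir, cfg$seed))
  invisible(results)
}

exp_waveforms <- function(cfg) {
  params <- config_params(cfg)
  scheme <- config_scheme(cfg)
  # a single absorbing voxel a little below the surface keeps the pump and
  # probe wavelets cleanly separated
  ph <- composition_phantom(mbnp = 2.0, nr = 12, nc = 1, radius = 0.5,
                            center = c(7, 1))
  triple <- simulate_triple(ph, scheme, params)
  al <- synthesize_alines(triple)
  ttd <- extract_ttd(al)
  list(traces = data.frame(time_us = al$time_us,
                           pump = al$pump_frame[, 1],
                           probe = al$probe_frame[, 1],
                           pumpprobe = al$pumpprobe_frame[, 1],
                           ttd = ttd$ttd_map[, 1]))
}

exp_kinetic_sweeps <- function(cfg) {
  params <- config_params(cfg)
  scheme <- config_scheme(cfg)
  delays <- delay_grid("full")
  sw_delay <- run_sweep("delay", delays, scheme, params, concentration = 3.9,
                        noise_sd = cfg$noise_sd,
                        gain_jitter_sd = cfg$gain_jitter_sd,
                        repeats = cfg$repeats, base_seed = cfg$seed)
  fit <- fit_decay(sw_delay$value, pmax(sw_delay$mean_amplitude, 1e-9))
  oxy_rows <- lapply(c(7.5, 21, 45), function(o2) {
    par_o <- params; par_o$oxygen_percent <- o2
    sw <- run_sweep("delay", delay_grid("oxygen"), scheme, par_o,
                    concentration = 2.0, noise_sd = cfg$noise_sd,
                    gain_jitter_sd = cfg$gain_jitter_sd,
                    repeats = cfg$repeats, base_seed = cfg$seed + round(o2 * 10))
    f <- fit_decay(sw$value, pmax(sw$mean_amplitude, 1e-9))
    cbind(oxygen_percent = o2, sw[, c("value", "mean_amplitude", "sd")],
          tau_fit = f$tau_eff)
  })
  conc_grid <- c(0.005, 0.01, 0.05, 0.1, 0.5, 1, 2, 3.5)
  sch_c <- scheme; sch_c$delay_us <- 0.2
  sw_conc <- run_sweep("concentration", conc_grid, sch_c, params,
                       noise_sd = cfg$noise_sd,
                       gain_jitter_sd = cfg$gain_jitter_sd,
                       repeats = cfg$repeats, base_seed = cfg$seed + 9000)
  list(delay_sweep = cbind(delay_us = sw_delay$value,
                           sw_delay[, c("mean_amplitude", "sd")],
                           tau_fit = fit$tau_eff, r_squared = fit$r_squared),
       oxygen_sweep = do.call(rbind, oxy_rows),
       concentration_sweep = cbind(concentration = sw_conc$value,
                                   sw_conc[, c("mean_amplitude", "sd")]))
}

exp_energy_depth <- function(cfg) {
  params <- config_params(cfg)
  scheme <- config_scheme(cfg)
  grid <- list(pump = c(0.5, 1, 2, 4, 6, 8, 10, 12, 14, 16, 18.2),
               probe = c(1.6, 2.7, 4.3, 6.4, 9.5))
  sw <- run_sweep("pump_probe_energy", grid, scheme, params,
                  concentration = 0.6125, repeats = 1)
  depth_rows <- lapply(c("skin", "breast"), function(tn) {
    props <- read_tissue_csv(system.file("extdata",
                                         paste0("tissue_", tn, "_synthetic.csv"),
                                         package = "ttdpa"), tn)
    d <- max_ttd_depth(props, scheme$pump_nm, scheme$probe_nm)
    data.frame(tissue = tn, max_depth_cm = d$max_depth,
               limiting_wavelength = d$limiting_wavelength,
               pump_depth_cm = d$pump_depth, probe_depth_cm = d$probe_depth)
  })
  list(energy_sweep = as.data.frame(sw),
       depth_table = do.call(rbind, depth_rows))
}

exp_cnr_sensitivity <- function(cfg) {
  params <- config_params(cfg)
  scheme <- config_scheme(cfg); scheme$delay_us <- 0.2
  concs <- c(0, 0.001, 0.005, 0.01, 0.05, 0.1, 0.5, 1, 2)
  rows <- list(); lims <- list()
  for (bg in c("blood", "water")) {
    ser <- simulate_concentration_series(concs, bg, scheme, params,
                                         noise_sd = cfg$noise_sd,
                                         gain_jitter_sd = cfg$gain_jitter_sd,
                                         repeats = cfg$repeats,
                                         seed = cfg$seed + ifelse(bg == "blood", 0, 1))
    for (m in names(ser)) {
      s <- ser[[m]]
      if (is.null(s)) next
      for (cc in concs[concs > 0])
        rows[[length(rows) + 1]] <- data.frame(background = bg, method = m,
                                               concentration = cc,
                                               cnr = cnr(s, cc))
      lims[[length(lims) + 1]] <- data.frame(background = bg, method = m,
                                             detection_limit = detection_limit(s))
    }
  }
  list(cnr = do.call(rbind, rows), detection_limits = do.call(rbind, lims))
}

exp_backgrounds <- function(cfg) {
  params <- config_params(cfg)
  scheme <- config_scheme(cfg)
  series <- make_sample_series()
  wl_su <- c(570, 606, 660)
  ttd_vals <- list(); su_vals <- list(); amp_rows <- list()
  set.seed(cfg$seed)
  for (nm in names(series)) {
    ph <- series[[nm]]
    mask <- attr(ph, "inclusion_mask")
    v_ttd <- numeric(cfg$repeats); v_su <- numeric(cfg$repeats)
    amps <- matrix(0, cfg$repeats, 5)
    for (r in seq_len(cfg$repeats)) {
      g <- 1 + if (cfg$gain_jitter_sd > 0)
        stats::rnorm(1, sd = cfg$gain_jitter_sd) else 0
      nz <- function(m) m + matrix(stats::rnorm(length(m), sd = cfg$noise_sd),
                                   nrow(m))
      frames <- lapply(c(wl_su, 840), function(w)
        nz(g * initial_pressure(ph, w, scheme$pump_fluence)))
      names(frames) <- c(wl_su, 840)
      pump <- frames[["660"]]
      probe <- nz(g * initial_pressure(ph, scheme$probe_nm, scheme$probe_fluence))
      pp <- nz(g * (initial_pressure(ph, scheme$pump_nm, scheme$pump_fluence) +
                      initial_pressure(ph, scheme$probe_nm, scheme$probe_fluence) +
                      ttd_contribution_map(ph, scheme, params)))
      v_ttd[r] <- mean((pp - pump - probe)[mask])
      um <- spectral_unmix(frames[as.character(wl_su)])
      v_su[r] <- mean(um$mbnp_map[mask])
      amps[r, ] <- c(vapply(frames, function(f) mean(f[mask]), numeric(1)),
                     mean(pp[mask]))
    }
    ttd_vals[[nm]] <- v_ttd
    su_vals[[nm]] <- v_su
    amp_rows[[nm]] <- data.frame(sample = nm,
                                 wavelength = c("570", "606", "660", "840",
                                                "660+840"),
                                 mean_amplitude = colMeans(amps),
                                 sd = apply(amps, 2, stats::sd))
  }
  ttd_t <- compare_samples(ttd_vals, "MBNP")
  su_t <- compare_samples(su_vals, "MBNP")
  summary <- data.frame(sample = rep(names(series), times = 3),
                        method = rep(c("TTD", "SU", "single_660"),
                                     each = length(series)),
                        mean = c(vapply(ttd_vals, mean, numeric(1)),
                                 vapply(su_vals, mean, numeric(1)),
                                 vapply(amp_rows, function(a)
                                   a$mean_amplitude[a$wavelength == "660"],
                                   numeric(1))),
                        sd = c(vapply(ttd_vals, stats::sd, numeric(1)),
                               vapply(su_vals, stats::sd, numeric(1)),
                               vapply(amp_rows, function(a)
                                 a$sd[a$wavelength == "660"], numeric(1))))
  list(summary = summary,
       spectra = do.call(rbind, amp_rows),
       ttd_ttests = ttd_t,
       su_ttests = su_t)
}

exp_timelapse <- function(cfg) {
  params <- config_params(cfg)
  scheme <- config_scheme(cfg)
  tl <- make_tumor_timelapse()
  times <- attr(tl, "times")
  mask <- attr(tl, "tumor_mask")
  wl_su <- c(570, 606, 660)
  imgs <- list(ttd = list(), su = list(), single = list())
  for (i in seq_along(tl)) {
    ph <- tl[[i]]
    # in vivo mode: 50 averaged acquisitions
    triple <- simulate_triple(ph, scheme, params, noise_sd = cfg$noise_sd,
                              repeats = 50, seed = cfg$seed + i,
                              gain_jitter_sd = cfg$gain_jitter_sd)
    imgs$ttd[[i]] <- extract_ttd(triple)$ttd_map
    frames <- lapply(wl_su, function(w) {
      f0 <- initial_pressure(ph, w, scheme$pump_fluence)
      acc <- 0
      for (r in 1:50)
        acc <- acc + f0 + matrix(stats::rnorm(length(f0), sd = cfg$noise_sd),
                                 nrow(f0))
      acc / 50
    })
    names(frames) <- wl_su
    imgs$su[[i]] <- spectral_unmix(frames)$mbnp_map
    imgs$single[[i]] <- frames[["660"]]
  }
  out <- lapply(names(imgs), function(m) {
    tc <- roi_timecourse(imgs[[m]], mask, times)
    cbind(method = c(ttd = "TTD", su = "SU", single = "single_660")[[m]], tc)
  })
  list(roi_timecourse = do.call(rbind, out))
}
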