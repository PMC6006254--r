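#' Effective optical attenuation coefficient
#'
#' Computes the effective attenuation coefficient of a turbid medium in the
#' diffusion regime, \eqn{\mu_{eff} = \sqrt{3 \mu_a (\mu_a + \mu_s')}}, which
#' governs the exponential decay of diffuse light fluence with depth.
#'
#' @param mu_a Absorption coefficient (cm^-1), nonnegative. Vectorised.
#' @param mu_s_prime Reduced scattering coefficient (cm^-1), nonnegative.
#' @return Effective attenuation coefficient (cm^-1).
#' @examples
#' effective_attenuation(1, 2)   # exactly 3
#' effective_attenuation(0.1, 10)
#' @export
effective_attenuation <- function(mu_a, mu_s_prime) {
  if (any(!is.finite(mu_a)) || any(!is.finite(mu_s_prime)))
    stop("mu_a and mu_s_prime must be finite numbers")
  if (any(mu_a < 0)) stop("mu_a must be nonnegative")
  if (any(mu_s_prime < 0)) stop("mu_s_prime must be nonnegative")
  sqrt(3 * mu_a * (mu_a + mu_s_prime))
}

#' Fluence at depth under exponential attenuation
#'
#' Beer-Lambert style decay of surface fluence with depth using an effective
#' attenuation coefficient: \eqn{\phi(z) = \phi(0) e^{-\mu_{eff} z}}.
#'
#' @param surface_fluence Fluence at the surface, mJ/cm^2 (\eqn{\phi(0)}).
#' @param mu_eff Effective attenuation coefficient, cm^-1.
#' @param depth Depth below the illuminated surface, cm; nonnegative. Vectorised.
#' @return Fluence at `depth`, mJ/cm^2.
#' @export
fluence_at_depth <- function(surface_fluence, mu_eff, depth) {
  if (any(surface_fluence < 0)) stop("surface_fluence must be nonnegative")
  if (any(depth < 0)) stop("depth must be nonnegative")
  surface_fluence * exp(-mu_eff * depth)
}

#' Tissue optical properties table
#'
#' Container for per-wavelength absorption and reduced scattering
#' coefficients of a named tissue.
#'
#' @param tissue_name Character label, e.g. "skin".
#' @param wavelengths Strictly increasing wavelengths, nm.
#' @param mu_a Absorption coefficients, cm^-1, one per wavelength.
#' @param mu_s_prime Reduced scattering coefficients, cm^-1, one per wavelength.
#' @return An object of class `tissue_optical_properties`.
#' @export
tissue_optical_properties <- function(tissue_name, wavelengths, mu_a, mu_s_prime) {
  if (length(wavelengths) != length(mu_a) || length(mu_a) != length(mu_s_prime))
    stop("wavelengths, mu_a and mu_s_prime must have equal length")
  if (length(wavelengths) < 1) stop("at least one wavelength is required")
  if (any(diff(wavelengths) <= 0)) stop("wavelengths must be strictly increasing")
  if (any(mu_a < 0) || any(mu_s_prime < 0))
    stop("optical coefficients must be nonnegative")
  structure(list(tissue_name = as.character(tissue_name),
                 wavelengths = as.numeric(wavelengths),
                 mu_a = as.numeric(mu_a),
                 mu_s_prime = as.numeric(mu_s_prime)),
            class = "tissue_optical_properties")
}

#' @export
print.tissue_optical_properties <- function(x, ...) {
  cat("Tissue optical properties:", x$tissue_name, "\n")
  print(data.frame(wavelength_nm = x$wavelengths, mu_a_cm1 = x$mu_a,
                   mu_s_prime_cm1 = x$mu_s_prime), row.names = FALSE)
  invisible(x)
}

#' Read tissue optical properties from CSV
#'
#' Expects columns `wavelength_nm`, `mu_a_cm1`, `mu_s_prime_cm1`; one file per
#' tissue. The tissue name defaults to the file name stem.
#'
#' @param path Path to a CSV file.
#' @param tissue_name Optional name; defaults to the file name without extension.
#' @return A [tissue_optical_properties()] object.
#' @export
read_tissue_csv <- function(path, tissue_name = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("wavelength_nm", "mu_a_cm1", "mu_s_prime_cm1")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0)
    stop("tissue CSV ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  if (is.null(tissue_name))
    tissue_name <- sub("\\.[^.]*$", "", basename(path))
  o <- order(df$wavelength_nm)
  tissue_optical_properties(tissue_name, df$wavelength_nm[o],
                            df$mu_a_cm1[o], df$mu_s_prime_cm1[o])
}

# interpolate mu_a / mu_s' at a wavelength; linear in log(mu) because optical
# spectra are smooth and positive. Extrapolation is refused on purpose.
interp_coef <- function(wavelengths, values, wavelength_nm, what) {
  if (wavelength_nm < min(wavelengths) || wavelength_nm > max(wavelengths))
    stop(sprintf("wavelength %g nm outside tabulated range [%g, %g] for %s; extrapolation is not supported",
                 wavelength_nm, min(wavelengths), max(wavelengths), what))
  i <- match(wavelength_nm, wavelengths)
  if (!is.na(i)) return(values[i])
  if (any(values <= 0)) # log interpolation needs positive values
    return(stats::approx(wavelengths, values, xout = wavelength_nm)$y)
  exp(stats::approx(wavelengths, log(values), xout = wavelength_nm)$y)
}

#' Effective attenuation of a tissue at a wavelength
#'
#' Looks up (or log-linearly interpolates) mu_a and mu_s' at the requested
#' wavelength and returns the effective attenuation coefficient.
#'
#' @param props A [tissue_optical_properties()] object.
#' @param wavelength_nm Wavelength, nm; must lie inside the tabulated range.
#' @return mu_eff, cm^-1.
#' @export
tissue_mu_eff <- function(props, wavelength_nm) {
  stopifnot(inherits(props, "tissue_optical_properties"))
  mu_a <- interp_coef(props$wavelengths, props$mu_a, wavelength_nm,
                      paste0(props$tissue_name, " mu_a"))
  mu_s <- interp_coef(props$wavelengths, props$mu_s_prime, wavelength_nm,
                      paste0(props$tissue_name, " mu_s_prime"))
  effective_attenuation(mu_a, mu_s)
}

#' Fluence-vs-depth profile in a tissue
#'
#' @param props A [tissue_optical_properties()] object.
#' @param wavelength_nm Wavelength, nm.
#' @param surface_fluence Surface fluence, mJ/cm^2.
#' @param depths Depth grid, cm; default 0 to 2 cm in 0.001 cm steps.
#' @return An object of class `fluence_profile` with fields `depths`,
#'   `fluence`, `surface_fluence`, `wavelength`.
#' @export
fluence_profile <- function(props, wavelength_nm, surface_fluence,
                            depths = seq(0, 2, by = 0.001)) {
  if (any(depths < 0)) stop("depths must be nonnegative")
  if (any(diff(depths) <= 0)) stop("depths must be strictly increasing")
  mu_eff <- tissue_mu_eff(props, wavelength_nm)
  structure(list(depths = depths,
                 fluence = fluence_at_depth(surface_fluence, mu_eff, depths),
                 surface_fluence = surface_fluence,
                 wavelength = wavelength_nm,
                 mu_eff = mu_eff),
            class = "fluence_profile")
}

#' Maximum imaging depth for a pump/probe pair
#'
#' For each beam the maximum usable depth is where the attenuated fluence
#' falls to the minimum energy that still generates a detectable triplet
#' differential signal: \eqn{z_{max} = \ln(\phi_0 / E_{min}) / \mu_{eff}}.
#' The overall limit is the smaller of the pump and probe depths; the
#' wavelength attaining it is reported as limiting.
#'
#' @param props A [tissue_optical_properties()] object.
#' @param pump_nm,probe_nm Pump and probe wavelengths, nm.
#' @param min_pump,min_probe Minimum usable fluence per beam, mJ/cm^2;
#'   must be positive and not exceed `surface_fluence` (else depth 0 with a
#'   warning).
#' @param surface_fluence Delivered surface fluence, mJ/cm^2 (e.g. the
#'   20 mJ/cm^2 maximum permissible exposure).
#' @return An object of class `depth_limit_result` with fields `max_depth`,
#'   `limiting_wavelength`, `pump_depth`, `probe_depth` (cm / nm).
#' @export
max_ttd_depth <- function(props, pump_nm = 660, probe_nm = 840,
                          min_pump = 1.6, min_probe = 2.7,
                          surface_fluence = 20) {
  if (min_pump <= 0 || min_probe <= 0)
    stop("minimum energies must be positive")
  one_depth <- function(wavelength_nm, e_min) {
    if (e_min > surface_fluence) {
      warning("minimum energy ", e_min,
              " mJ/cm^2 exceeds surface fluence; depth is 0")
      return(0)
    }
    log(surface_fluence / e_min) / tissue_mu_eff(props, wavelength_nm)
  }
  pump_depth <- one_depth(pump_nm, min_pump)
  probe_depth <- one_depth(probe_nm, min_probe)
  limiting <- if (pump_depth <= probe_depth) pump_nm else probe_nm
  structure(list(max_depth = min(pump_depth, probe_depth),
                 limiting_wavelength = limiting,
                 pump_depth = pump_depth,
                 probe_depth = probe_depth),
            class = "depth_limit_result")
}

#' @export
print.depth_limit_result <- function(x, ...) {
  cat(sprintf("Max TTD imaging depth: %.3f cm (limited by %g nm)\n",
              x$max_depth, x$limiting_wavelength))
  cat(sprintf("  pump depth:  %.3f cm\n  probe depth: %.3f cm\n",
              x$pump_depth, x$probe_depth))
  invisible(x)
}
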