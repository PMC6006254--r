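#' Photophysical parameters of the triplet contrast agent
#'
#' Bundles the parameters of the triplet-state population model for a
#' methylene-blue-type phosphorescent dye nanoparticle: intersystem-crossing
#' yield, monomer/dimer split, triplet lifetimes, Stern-Volmer oxygen
#' quenching and pump saturation.
#'
#' Defaults are order-of-magnitude choices for a methylene-blue conjugated
#' nanoparticle: a ~1:1 monomer/dimer ratio, a zero-oxygen monomer triplet
#' lifetime of 10 us (inside the reported monomer range of 1-100 us), a dimer
#' lifetime of 0.01 us (1e-8 s scale), and a quenching constant set so the
#' effective monomer lifetime at air-saturated oxygen (21%) is about 2 us.
#'
#' @param isc_yield Intersystem-crossing quantum yield, in \[0, 1\].
#' @param monomer_fraction Fraction of dye in the monomer state, in \[0, 1\];
#'   the dimer fraction is `1 - monomer_fraction`.
#' @param tau_monomer_0 Zero-oxygen monomer triplet lifetime, us.
#' @param tau_dimer Dimer triplet lifetime, us; must be < `tau_monomer_0`.
#' @param k_q Stern-Volmer quenching rate constant, us^-1 per % dissolved oxygen.
#' @param oxygen_percent Dissolved-oxygen level, %.
#' @param pump_saturation_fluence Pump fluence scale at which triplet pumping
#'   saturates, mJ/cm^2.
#' @param triplet_specific_signal Photoacoustic signal per unit concentration
#'   (mg/mL) per unit probe fluence (mJ/cm^2) at full triplet population;
#'   the default matches the triplet specific-absorption scale at the probe
#'   peak, so TTD amplitudes are directly comparable to ground-state frames.
#' @return An object of class `photophysics_params`.
#' @export
photophysics_params <- function(isc_yield = 0.5,
                                monomer_fraction = 0.5,
                                tau_monomer_0 = 10,
                                tau_dimer = 0.01,
                                k_q = 0.019,
                                oxygen_percent = 21,
                                pump_saturation_fluence = 4,
                                triplet_specific_signal = 8) {
  vals <- c(isc_yield, monomer_fraction, tau_monomer_0, tau_dimer, k_q,
            oxygen_percent, pump_saturation_fluence, triplet_specific_signal)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all photophysics parameters must be finite and nonnegative")
  if (isc_yield > 1) stop("isc_yield must lie in [0, 1]")
  if (monomer_fraction > 1) stop("monomer_fraction must lie in [0, 1]")
  if (tau_dimer >= tau_monomer_0)
    stop("tau_dimer must be smaller than tau_monomer_0")
  structure(list(isc_yield = isc_yield,
                 monomer_fraction = monomer_fraction,
                 tau_monomer_0 = tau_monomer_0,
                 tau_dimer = tau_dimer,
                 k_q = k_q,
                 oxygen_percent = oxygen_percent,
                 pump_saturation_fluence = pump_saturation_fluence,
                 triplet_specific_signal = triplet_specific_signal),
            class = "photophysics_params")
}

#' Pump/probe excitation scheme
#'
#' @param pump_nm Pump wavelength, nm (ground-state absorption peak; default 660).
#' @param probe_nm Probe wavelength, nm (triplet absorption peak; default 840).
#' @param delay_us Pump-to-probe delay, us; nonnegative.
#' @param pump_fluence,probe_fluence Surface fluences of the two beams, mJ/cm^2.
#' @return An object of class `excitation_scheme`.
#' @export
excitation_scheme <- function(pump_nm = 660, probe_nm = 840, delay_us = 0.5,
                              pump_fluence = 12, probe_fluence = 6.4) {
  if (delay_us < 0) stop("delay_us must be nonnegative")
  if (pump_fluence < 0 || probe_fluence < 0)
    stop("fluences must be nonnegative")
  structure(list(pump_nm = pump_nm, probe_nm = probe_nm, delay_us = delay_us,
                 pump_fluence = pump_fluence, probe_fluence = probe_fluence),
            class = "excitation_scheme")
}

#' Triplet population pumped into T1
#'
#' Fraction of ground-state molecules promoted to the triplet manifold by a
#' pump pulse of given fluence: `isc_yield * (1 - exp(-F / F_sat))`. Linear in
#' fluence at low fluence, saturating at the intersystem-crossing yield.
#'
#' @param pump_fluence Pump fluence, mJ/cm^2; nonnegative. Vectorised.
#' @param params A [photophysics_params()] object.
#' @return Triplet fraction in \[0, 1\].
#' @export
triplet_fraction_after_pump <- function(pump_fluence, params) {
  stopifnot(inherits(params, "photophysics_params"))
  if (any(pump_fluence < 0)) stop("pump_fluence must be nonnegative")
  params$isc_yield * (1 - exp(-pump_fluence / params$pump_saturation_fluence))
}

#' Triplet survival after a pump-probe delay
#'
#' Biexponential decay of the pumped triplet population: the monomer decays
#' with an oxygen-quenched effective lifetime
#' `1/tau_m_eff = 1/tau_monomer_0 + k_q * oxygen_percent` (Stern-Volmer), the
#' dimer with its short intrinsic lifetime.
#'
#' @param delay_us Delay between pump and probe pulses, us. Vectorised.
#' @param params A [photophysics_params()] object.
#' @return Surviving triplet fraction in \[0, 1\] (1 at zero delay).
#' @export
triplet_survival <- function(delay_us, params) {
  stopifnot(inherits(params, "photophysics_params"))
  if (any(delay_us < 0)) stop("delay_us must be nonnegative")
  tau_m_eff <- effective_monomer_lifetime(params)
  f <- params$monomer_fraction
  f * exp(-delay_us / tau_m_eff) + (1 - f) * exp(-delay_us / params$tau_dimer)
}

#' Oxygen-quenched effective monomer triplet lifetime
#'
#' @param params A [photophysics_params()] object.
#' @param oxygen_percent Optional oxygen level override, %.
#' @return Effective monomer lifetime, us.
#' @export
effective_monomer_lifetime <- function(params, oxygen_percent = NULL) {
  stopifnot(inherits(params, "photophysics_params"))
  o2 <- if (is.null(oxygen_percent)) params$oxygen_percent else oxygen_percent
  1 / (1 / params$tau_monomer_0 + params$k_q * o2)
}

#' Transient triplet differential amplitude
#'
#' Forward model for the TTD signal of a uniformly illuminated sample:
#' proportional to concentration, to the pumped triplet fraction, to the
#' fraction surviving the delay, and strictly linear in probe fluence.
#'
#' @param concentration Dye concentration, mg/mL; nonnegative. Vectorised.
#' @param scheme An [excitation_scheme()].
#' @param params A [photophysics_params()] object.
#' @return TTD amplitude, signal units.
#' @export
ttd_amplitude <- function(concentration, scheme, params) {
  stopifnot(inherits(scheme, "excitation_scheme"),
            inherits(params, "photophysics_params"))
  if (any(concentration < 0)) stop("concentration must be nonnegative")
  params$triplet_specific_signal * concentration *
    triplet_fraction_after_pump(scheme$pump_fluence, params) *
    triplet_survival(scheme$delay_us, params) *
    scheme$probe_fluence
}

#' Fit an exponential decay to delay-sweep amplitudes
#'
#' Least-squares fit of `A0 * exp(-t / tau)` (optionally a biexponential
#' `A0 * (f * exp(-t/tau1) + (1-f) * exp(-t/tau2))`) to TTD amplitude versus
#' pump-probe delay, as used to read the effective triplet lifetime off a
#' delay sweep.
#'
#' @param delays Delay times, us; at least 3 distinct values.
#' @param amplitudes Measured amplitudes, positive, same length as `delays`.
#' @param model `"single"` (default) or `"biexponential"`.
#' @return A list with `tau_eff` (us), `amplitude0`, `r_squared`, the fitted
#'   model object, and for the biexponential model also `tau2` and
#'   `monomer_fraction`. For the biexponential fit `tau_eff` is the slower
#'   component.
#' @export
fit_decay <- function(delays, amplitudes, model = c("single", "biexponential")) {
  model <- match.arg(model)
  if (length(delays) != length(amplitudes))
    stop("delays and amplitudes must have equal length")
  if (length(unique(delays)) < 3)
    stop("at least 3 distinct delays are required to fit a decay")
  if (any(amplitudes <= 0))
    stop("amplitudes must be positive to fit an exponential decay")
  df <- data.frame(t = as.numeric(delays), y = as.numeric(amplitudes))
  # log-linear start values
  lf <- stats::lm(log(y) ~ t, data = df)
  tau0 <- -1 / min(unname(stats::coef(lf)[2]), -1e-6)
  a0 <- exp(unname(stats::coef(lf)[1]))
  fit <- if (model == "single") {
    minpack.lm::nlsLM(y ~ A0 * exp(-t / tau), data = df,
                      start = list(A0 = a0, tau = tau0),
                      lower = c(0, 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    minpack.lm::nlsLM(y ~ A0 * (f * exp(-t / tau1) + (1 - f) * exp(-t / tau2)),
                      data = df,
                      start = list(A0 = a0, f = 0.5, tau1 = tau0,
                                   tau2 = tau0 / 100),
                      lower = c(0, 0, 1e-9, 1e-9), upper = c(Inf, 1, Inf, Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 500))
  }
  pred <- stats::predict(fit)
  r2 <- 1 - sum((df$y - pred)^2) / sum((df$y - mean(df$y))^2)
  cf <- stats::coef(fit)
  if (model == "single") {
    list(tau_eff = unname(cf["tau"]), amplitude0 = unname(cf["A0"]),
         r_squared = r2, fit = fit)
  } else {
    taus <- sort(c(cf[["tau1"]], cf[["tau2"]]))
    f_slow <- if (cf[["tau1"]] >= cf[["tau2"]]) cf[["f"]] else 1 - cf[["f"]]
    list(tau_eff = taus[2], tau2 = taus[1], monomer_fraction = unname(f_slow),
         amplitude0 = unname(cf["A0"]), r_squared = r2, fit = fit)
  }
}

#' The pump-probe delay grid of a full delay sweep
#'
#' The 32-point delay grid used for delay sweeps (0.02-10 us, log-like
#' spacing), and the shorter 7-point grid used for oxygen-level comparisons.
#'
#' @param which `"full"` (32 points) or `"oxygen"` (7 points).
#' @return Numeric vector of delays, us.
#' @export
delay_grid <- function(which = c("full", "oxygen")) {
  which <- match.arg(which)
  if (which == "full") {
    c(0.02, 0.04, 0.06, 0.08, 0.10, 0.15, 0.20, 0.25, 0.30, 0.35, 0.40,
      0.50, 0.60, 0.70, 0.80, 0.90, 1.00, 1.20, 1.40, 1.60, 1.80, 2.00,
      2.50, 3.00, 3.50, 4.00, 5.00, 6.00, 7.00, 8.00, 9.00, 10.00)
  } else {
    c(0.1, 0.2, 0.5, 1.0, 2.0, 3.0, 5.0)
  }
}
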