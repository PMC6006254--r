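# bipolar (derivative-of-Gaussian) acoustic wavelet, peak-normalised to 1
bipolar_wavelet <- function(t_rel, sigma_us) {
  x <- t_rel / sigma_us
  -x * exp(0.5 - x^2 / 2)  # max value 1 at x = -1
}

#' Convert a frame triple into time-domain A-line traces
#'
#' Each depth column of the frames becomes a time-resolved acoustic trace:
#' every absorbing pixel contributes a bipolar wavelet whose arrival time is
#' depth / sound_speed on the acquisition clock. Pump and probe lasers share
#' one master trigger, so probe-generated signals — in both the probe-only
#' and the pump+probe trace — arrive `delay_us` later than pump-generated
#' ones; the raw-trace subtraction of the triple therefore needs no
#' realignment and isolates the triplet-differential wavelet at the probe
#' arrival time.
#'
#' @param triple A frame-mode [simulate_triple()] result.
#' @param sound_speed Speed of sound, mm/us; default 1.5.
#' @param sampling_rate Sampling rate, MSa/s (samples per us); default 250.
#' @param wavelet_sigma_us Wavelet width parameter, us; default 0.02.
#' @param n_samples Optional trace length; if too short for the deepest
#'   delayed arrival an error is raised. Default: fitted automatically.
#' @return An object of class `measurement_triple` with `mode = "aline"`:
#'   `pump_frame`, `probe_frame`, `pumpprobe_frame` are (samples x columns)
#'   trace stacks, plus `time_us`.
#' @export
synthesize_alines <- function(triple, sound_speed = 1.5, sampling_rate = 250,
                              wavelet_sigma_us = 0.02, n_samples = NULL) {
  stopifnot(inherits(triple, "measurement_triple"))
  if (!identical(triple$mode, "frame"))
    stop("synthesize_alines expects a frame-mode triple")
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  if (sound_speed <= 0) stop("sound_speed must be positive")
  nr <- nrow(triple$pump_frame); nc <- ncol(triple$pump_frame)
  pixel_cm <- if (!is.null(triple$pixel_size)) triple$pixel_size else 0.01
  depths_mm <- (seq_len(nr) - 1) * pixel_cm * 10
  arrival_us <- depths_mm / sound_speed
  delay <- triple$scheme$delay_us
  tail_us <- 6 * wavelet_sigma_us
  needed <- ceiling((max(arrival_us) + delay + tail_us) * sampling_rate) + 1
  if (is.null(n_samples)) n_samples <- needed
  if (n_samples < needed)
    stop("delay and depth extent exceed the trace length (need ",
         needed, " samples, have ", n_samples, ")")
  time_us <- (seq_len(n_samples) - 1) / sampling_rate
  render <- function(amps, shift_us) {
    out <- matrix(0, n_samples, ncol(amps))
    for (j in seq_len(ncol(amps))) {
      nzi <- which(amps[, j] != 0)
      for (i in nzi) {
        out[, j] <- out[, j] +
          amps[i, j] * bipolar_wavelet(time_us - arrival_us[i] - shift_us,
                                       wavelet_sigma_us)
      }
    }
    out
  }
  # pump-generated signal arrives un-shifted; everything probe-generated
  # (probe-only frame and the probe+TTD part of pump+probe) is delayed
  pump_tr <- render(triple$pump_frame, 0)
  probe_tr <- render(triple$probe_frame, delay)
  pp_tr <- render(triple$pump_frame, 0) +
    render(triple$pumpprobe_frame - triple$pump_frame, delay)
  structure(list(pump_frame = pump_tr, probe_frame = probe_tr,
                 pumpprobe_frame = pp_tr, scheme = triple$scheme,
                 repeats = triple$repeats, noise_sd = triple$noise_sd,
                 seed = triple$seed, time_us = time_us,
                 sampling_rate = sampling_rate, sound_speed = sound_speed,
                 mode = "aline"),
            class = "measurement_triple")
}
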