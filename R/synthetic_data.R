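#' Noise specification for synthetic bioreactor traces
#'
#' The generator superimposes two noise sources on the deterministic
#' poroelastic response, emulating what the bioreactor records: a sinusoid
#' from the cyclic motion of the stepper motor and Gaussian noise from the
#' force sensor. Defaults (resolved at generation time, when the signal
#' scale `E3 * eps0` is known) put the motor amplitude at 5% and the sensor
#' standard deviation at 2% of the equilibrium stress, making the periodic
#' component the dominant disturbance. The motor phase is drawn from the
#' seed so that downstream recovery is not tuned to a particular phase.
#'
#' @param motor_amplitude sinusoid amplitude, kPa (`NULL` = 5% of `E3*eps0`).
#' @param motor_frequency sinusoid frequency, Hz.
#' @param sensor_sigma Gaussian noise standard deviation, kPa (`NULL` = 2%
#'   of `E3*eps0`).
#' @param seed integer seed driving phase and sensor noise.
#' @return An object of class `"noise_spec"`.
#' @export
noise_spec <- function(motor_amplitude = NULL, motor_frequency = 1,
                       sensor_sigma = NULL, seed = 1L) {
  if (!is.null(motor_amplitude) && motor_amplitude < 0) {
    stop("motor_amplitude must be non-negative")
  }
  if (!is.null(sensor_sigma) && sensor_sigma < 0) {
    stop("sensor_sigma must be non-negative")
  }
  if (motor_frequency < 0) stop("motor_frequency must be non-negative")
  structure(list(motor_amplitude = motor_amplitude,
                 motor_frequency = motor_frequency,
                 sensor_sigma = sensor_sigma, seed = as.integer(seed)),
            class = "noise_spec")
}

## run code under a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic bioreactor raw trace
#'
#' Samples the analytic ramp-and-hold load intensity at `sample_rate`, adds
#' motor and sensor noise per the [noise_spec()], and converts the result to
#' a sensor voltage through the calibration, producing the raw-CSV dialect
#' the preprocessing stage consumes. With both noise amplitudes zero the
#' trace equals the forward-model output exactly; with a fixed seed the
#' trace is fully reproducible.
#'
#' @param ec [engineering_constants()] of the scaffold.
#' @param tp [transport_parameters()] with `tg` (and optionally the radius,
#'   from which the default cross-section is derived).
#' @param protocol a [ramp_protocol()].
#' @param noise a [noise_spec()].
#' @param sample_rate sampling frequency, Hz (default 100).
#' @param calibration sensor calibration (gain N/V, offset V,
#'   cross_section_area m^2); the default uses a 0.5 N/V gain, a 10 mV
#'   offset and the specimen cross-section.
#' @param n_roots series terms used for the clean response.
#' @return A data frame with columns `time_s`, `signal_V`, carrying
#'   attributes `calibration`, `protocol`, `noise`, and `clean_kPa` (the
#'   noise-free stress, for testing).
#' @export
generate_trace <- function(ec, tp, protocol, noise = noise_spec(),
                           sample_rate = 100, calibration = NULL,
                           n_roots = 20) {
  stopifnot(inherits(ec, "engineering_constants"),
            inherits(tp, "transport_parameters"),
            inherits(protocol, "ramp_protocol"),
            inherits(noise, "noise_spec"))
  if (noise$motor_frequency >= sample_rate / 2) {
    stop("motor_frequency (", noise$motor_frequency,
         " Hz) must be below the Nyquist frequency ", sample_rate / 2, " Hz")
  }
  if (is.null(calibration)) {
    area <- if (!is.null(tp$a)) pi * tp$a^2 else pi * 1e-3^2
    calibration <- list(gain = 0.5, offset = 0.01, cross_section_area = area)
  }
  C <- stiffness_from_engineering(ec)
  roots <- characteristic_roots(1 - C$C12 / C$C11, n_roots)
  sol <- step_response(C, roots, tp$tg)
  times <- seq(0, protocol$ramp_time + protocol$hold_time, by = 1 / sample_rate)
  clean <- load_intensity(sol, protocol, times)$stress_kPa

  scale <- equilibrium_E3(C) * protocol$total_strain
  amp <- if (is.null(noise$motor_amplitude)) 0.05 * scale else
    noise$motor_amplitude
  sig <- if (is.null(noise$sensor_sigma)) 0.02 * scale else noise$sensor_sigma
  stress <- with_seed(noise$seed, {
    phase <- stats::runif(1, 0, 2 * pi)
    clean + amp * sin(2 * pi * noise$motor_frequency * times + phase) +
      stats::rnorm(length(times), 0, sig)
  })

  signal_V <- stress * 1000 * calibration$cross_section_area /
    calibration$gain + calibration$offset
  out <- data.frame(time_s = times, signal_V = signal_V)
  attr(out, "calibration") <- calibration
  attr(out, "protocol") <- protocol
  attr(out, "noise") <- noise
  attr(out, "clean_kPa") <- clean
  out
}

## the two porosity anchor parameter sets estimated at 1%/s, used as the
## default study conditions throughout the package
study_anchor_sets <- function() {
  list(
    `0.5` = list(ec = engineering_constants(8.49, 19.19, 0.75, 0.24),
                 tp = transport_parameters(tg = 40.62, a = 1e-3,
                                           porosity = 0.5)),
    `0.7` = list(ec = engineering_constants(5.61, 11.97, 0.82, 0.24),
                 tp = transport_parameters(tg = 17.58, a = 1e-3,
                                           porosity = 0.7))
  )
}

#' Generate the full synthetic study
#'
#' Produces the cross of the two porosity anchor parameter sets (50% and
#' 70%) with the four loading rates 0.25, 0.5, 1 and 3 %/s, at 10% total
#' strain and 100 s hold — the study conditions of the relaxation
#' experiments. Each trace gets a distinct sub-seed derived from the global
#' seed by a fixed counter scheme (`seed * 97 + index`), so traces are
#' mutually independent yet the whole study is reproducible.
#'
#' @param seed global integer seed.
#' @param rates loading rates, 1/s.
#' @param total_strain applied strain (default 0.1).
#' @param hold_time hold duration, s (default 100).
#' @param noiseless if `TRUE`, generate with both noise amplitudes zero.
#' @param out_dir optional directory; when given, each trace is written as
#'   `trace_<i>.csv` with a JSON metadata sidecar `trace_<i>.json`.
#' @return A list of raw traces; each element also carries a `meta` attribute
#'   (porosity, rate, sub-seed, generating parameters).
#' @export
generate_study <- function(seed = 7L, rates = c(0.0025, 0.005, 0.01, 0.03),
                           total_strain = 0.1, hold_time = 100,
                           noiseless = FALSE, out_dir = NULL) {
  sets <- study_anchor_sets()
  grid <- expand.grid(porosity = as.numeric(names(sets)), rate = rates,
                      KEEP.OUT.ATTRS = FALSE)
  traces <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    set <- sets[[as.character(grid$porosity[i])]]
    sub_seed <- (as.integer(seed) * 97L + i) %% 2147483647L
    ns <- if (noiseless) {
      noise_spec(motor_amplitude = 0, sensor_sigma = 0, seed = sub_seed)
    } else noise_spec(seed = sub_seed)
    protocol <- ramp_protocol(grid$rate[i], total_strain, hold_time)
    tr <- generate_trace(set$ec, set$tp, protocol, ns)
    meta <- list(porosity = grid$porosity[i], strain_rate = grid$rate[i],
                 total_strain = total_strain, hold_time = hold_time,
                 sub_seed = sub_seed,
                 truth = list(E1_kPa = set$ec$E1, E3_kPa = set$ec$E3,
                              nu21 = set$ec$nu21, nu31 = set$ec$nu31,
                              tg_s = set$tp$tg),
                 calibration = attr(tr, "calibration"),
                 motor_frequency_Hz = ns$motor_frequency)
    attr(tr, "meta") <- meta
    traces[[i]] <- tr
    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      write_trace_csv(tr, file.path(out_dir, sprintf("trace_%02d.csv", i)))
      jsonlite::write_json(meta,
                           file.path(out_dir, sprintf("trace_%02d.json", i)),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  names(traces) <- paste0("phi", round(100 * grid$porosity),
                          "_rate", grid$rate * 100)
  traces
}
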