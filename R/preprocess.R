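#' Convert a raw sensor trace to stress
#'
#' Applies the affine sensor calibration and the specimen cross-section to
#' turn a voltage (or force) signal into a load intensity in kPa:
#' `stress = (signal - offset) * gain / area`, with the N/m^2 result reported
#' in kPa.
#'
#' @param raw a data frame with columns `time_s` and `signal_V` (or
#'   `signal_N`, in which case the gain is interpreted as 1).
#' @param calibration list with fields `gain` (N per signal unit), `offset`
#'   (signal units) and `cross_section_area` (m^2).
#' @return A `relaxation_trace` data frame (`time_s`, `stress_kPa`).
#' @export
convert_raw <- function(raw, calibration) {
  need <- c("gain", "offset", "cross_section_area")
  miss <- setdiff(need, names(calibration))
  if (length(miss)) stop("calibration is missing field(s): ",
                         paste(miss, collapse = ", "))
  if (calibration$cross_section_area <= 0) {
    stop("cross_section_area must be positive")
  }
  sig_col <- intersect(c("signal_V", "signal_N"), names(raw))
  if (length(sig_col) == 0) stop("raw trace must have a signal_V or signal_N column")
  force_N <- (raw[[sig_col[1]]] - calibration$offset) * calibration$gain
  stress_kPa <- force_N / calibration$cross_section_area / 1000
  relaxation_trace(raw$time_s, stress_kPa, attr(raw, "protocol"))
}

#' Savitzky-Golay frame length matched to the motor noise
#'
#' The frame length that makes a moving least-squares window span a whole
#' number of motor cycles is `ramp_time * sample_rate / n_cycles` (samples
#' during the ramp divided by noise cycles during the ramp). Symmetric
#' smoothing windows must have odd length, so the value is rounded to the
#' nearest odd integer (ties away from the even value, so 250 rounds to 251).
#'
#' @param ramp_time ramp duration `t0`, s.
#' @param sample_rate sampling frequency, Hz (default 100).
#' @param n_cycles number of motor noise cycles during the ramp.
#' @return An odd integer frame length (>= 3).
#' @examples
#' frame_length(10, 100, 10)  # 101
#' frame_length(10, 100, 7)   # 143
#' @export
frame_length <- function(ramp_time, sample_rate = 100, n_cycles) {
  if (ramp_time <= 0 || sample_rate <= 0 || n_cycles <= 0) {
    stop("ramp_time, sample_rate and n_cycles must all be positive")
  }
  L <- ramp_time * sample_rate / n_cycles
  # nearest odd integer, half-up (round() would tie to even)
  frame <- 2 * floor((L - 1) / 2 + 0.5) + 1
  if (frame < 3) {
    stop("computed frame length ", frame, " is below 3; the smoothing filter ",
         "is inapplicable at this sampling/noise-frequency combination")
  }
  as.integer(frame)
}

#' Savitzky-Golay smoothing of a relaxation trace
#'
#' Local least-squares polynomial smoothing with an odd frame. The default
#' polynomial order 1 makes the filter an unweighted moving linear fit, which
#' reproduces the linear loading ramp exactly while strongly attenuating any
#' periodic component whose period matches the frame. The output has the
#' same length as the input; the terminal windows are handled by the filter's
#' endpoint polynomial fits, so the trace is not shortened.
#'
#' @param trace a `relaxation_trace` data frame.
#' @param frame odd window length in samples.
#' @param poly_order polynomial order (default 1).
#' @return The smoothed `relaxation_trace`.
#' @export
smooth_trace <- function(trace, frame, poly_order = 1) {
  n <- nrow(trace)
  if (frame %% 2 != 1) stop("frame must be odd (got ", frame, ")")
  if (frame <= poly_order) stop("frame must exceed poly_order")
  if (frame > n) stop("frame (", frame, ") exceeds trace length (", n, ")")
  sm <- signal::sgolayfilt(trace$stress_kPa, p = poly_order, n = frame)
  relaxation_trace(trace$time_s, sm, attr(trace, "protocol"))
}

#' Equilibrium modulus from the relaxation tail
#'
#' Estimates the fiber-direction equilibrium modulus `E3 = P(inf)/eps0` by
#' averaging the last `n_tail` stress samples (default 1000, i.e. the last
#' 10 s at 100 Hz) and dividing by the total applied strain.
#'
#' @param trace a `relaxation_trace` data frame.
#' @param total_strain applied strain `eps0` (> 0).
#' @param n_tail number of terminal samples to average.
#' @return Equilibrium modulus, kPa.
#' @export
equilibrium_modulus <- function(trace, total_strain, n_tail = 1000) {
  n <- nrow(trace)
  if (total_strain <= 0) stop("total_strain must be positive")
  if (n < n_tail) {
    stop("trace has ", n, " samples; need at least n_tail = ", n_tail)
  }
  mean(utils::tail(trace$stress_kPa, n_tail)) / total_strain
}

#' Read or write a relaxation/raw trace CSV
#'
#' Traces travel as UTF-8 CSV with a header row; processed traces carry
#' columns `time_s, stress_kPa`, raw traces `time_s, signal_V`.
#'
#' @param path file path.
#' @return `read_trace_csv` returns a data frame.
#' @export
read_trace_csv <- function(path) {
  out <- utils::read.csv(path)
  if ("stress_kPa" %in% names(out)) {
    out <- relaxation_trace(out$time_s, out$stress_kPa)
  }
  out
}

#' @rdname read_trace_csv
#' @param trace data frame to write.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
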