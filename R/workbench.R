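#' Study configuration
#'
#' Bundles everything [run_study()] needs: the global seed (fanned out to
#' per-trace sub-seeds by the generator's counter scheme), the protocol
#' grid, noise switches, the fit configuration, the rates fitted versus
#' merely predicted, and the output directory.
#'
#' @param seed global integer seed.
#' @param rates loading rates generated, 1/s.
#' @param fit_rate the rate whose traces are fitted for the parameter table
#'   (the others serve as independent prediction checks).
#' @param total_strain applied strain.
#' @param hold_time hold duration, s.
#' @param noiseless generate noise-free traces.
#' @param n_cycles motor cycles per ramp assumed by the frame-length rule
#'   (`NULL` = derived from the motor frequency and each ramp time).
#' @param fit fit configuration ([fit_config()]).
#' @param out_dir output directory or `NULL` for no file output.
#' @return An object of class `"study_config"`.
#' @export
study_config <- function(seed = 7L, rates = c(0.0025, 0.005, 0.01, 0.03),
                         fit_rate = 0.01, total_strain = 0.1, hold_time = 100,
                         noiseless = FALSE, n_cycles = NULL,
                         fit = fit_config(), out_dir = NULL) {
  if (!fit_rate %in% rates) stop("fit_rate must be one of the generated rates")
  structure(list(seed = as.integer(seed), rates = rates, fit_rate = fit_rate,
                 total_strain = total_strain, hold_time = hold_time,
                 noiseless = noiseless, n_cycles = n_cycles, fit = fit,
                 out_dir = out_dir),
            class = "study_config")
}

## preprocess one raw trace: calibrate, smooth (frame matched to the motor
## frequency; skipped for noise-free traces, which have no periodic
## component to remove), estimate E3 from the tail
preprocess_trace <- function(raw, n_cycles = NULL) {
  meta <- attr(raw, "meta")
  cal <- attr(raw, "calibration")
  if (is.null(cal)) stop("missing calibration sidecar for raw trace")
  protocol <- attr(raw, "protocol")
  trace <- convert_raw(raw, cal)
  sample_rate <- 1 / diff(trace$time_s[1:2])
  if (is.null(n_cycles)) {
    f_motor <- attr(raw, "noise")$motor_frequency
    if (is.null(f_motor)) f_motor <- meta$motor_frequency_Hz
    if (is.null(f_motor)) stop("cannot derive the smoothing frame: no motor ",
                               "frequency in the trace metadata")
    n_cycles <- max(1, round(f_motor * protocol$ramp_time))
  }
  ns <- attr(raw, "noise")
  noise_free <- !is.null(ns) &&
    identical(ns$motor_amplitude, 0) && identical(ns$sensor_sigma, 0)
  frame <- frame_length(protocol$ramp_time, sample_rate, n_cycles)
  smoothed <- if (!noise_free && frame <= nrow(trace)) {
    smooth_trace(trace, frame)
  } else trace
  E3_hat <- equilibrium_modulus(smoothed, protocol$total_strain)
  list(trace = smoothed, raw_stress = trace, E3 = E3_hat,
       frame = frame, protocol = protocol, meta = meta)
}

#' Run the full synthetic study end to end
#'
#' Generates the study traces, conditions each one (calibration, matched
#' Savitzky-Golay smoothing, tail-average equilibrium modulus), fits
#' `(E1, nu21, tg)` on the traces at the configured fitting rate, checks the
#' fitted parameters against the other rates by r-squared of pure
#' prediction, and runs the prediction layer (rate sweep including the step
#' limit, porosity interpolation, peak-load surface fit). All numeric
#' outputs carry the seed; rerunning with the same configuration reproduces
#' them exactly.
#'
#' @param config a [study_config()].
#' @return A list of class `"study_report"` with elements `parameter_table`
#'   (one row per porosity: estimated and generating values), `fits`,
#'   `prediction_checks` (r-squared at the non-fitted rates), `rate_sweeps`,
#'   `peak_surface`, `seed`, and `log`.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  log <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }
  note("study seed %d (sub-seeds: seed*97 + trace index)", config$seed)
  traces <- generate_study(config$seed, rates = config$rates,
                           total_strain = config$total_strain,
                           hold_time = config$hold_time,
                           noiseless = config$noiseless)
  prepped <- lapply(traces, preprocess_trace, n_cycles = config$n_cycles)

  porosities <- sort(unique(vapply(prepped, function(p) p$meta$porosity,
                                   numeric(1))))
  fits <- list()
  rows <- list()
  checks <- list()
  for (phi in porosities) {
    is_phi <- vapply(prepped, function(p) p$meta$porosity == phi, logical(1))
    fit_idx <- which(is_phi & vapply(prepped, function(p)
      isTRUE(all.equal(p$meta$strain_rate, config$fit_rate)), logical(1)))
    p <- prepped[[fit_idx]]
    fit <- fit_parameters(p$trace, p$protocol, E3 = p$E3,
                          nu31 = 0.24, config = config$fit)
    fits[[as.character(phi)]] <- fit
    note("porosity %.0f%%: E1 = %.3f kPa, nu21 = %.3f, tg = %.2f s, E3 = %.3f kPa (r2 = %.3f)",
         100 * phi, fit$E1, fit$nu21, fit$tg, fit$E3, fit$r2)
    rows[[as.character(phi)]] <- data.frame(
      porosity = phi, E1_kPa = fit$E1, tg_s = fit$tg, nu21 = fit$nu21,
      E3_kPa = fit$E3, nu31 = fit$nu31, r2 = fit$r2,
      E1_true = p$meta$truth$E1_kPa, tg_true = p$meta$truth$tg_s,
      nu21_true = p$meta$truth$nu21, E3_true = p$meta$truth$E3_kPa)

    # pure prediction at the rates that were not fitted
    ec_hat <- engineering_constants(fit$E1, fit$E3, fit$nu21, fit$nu31)
    C_hat <- stiffness_from_engineering(ec_hat)
    sol_hat <- step_response(C_hat,
                             characteristic_roots(1 - C_hat$C12 / C_hat$C11,
                                                  config$fit$n_roots),
                             fit$tg)
    for (i in which(is_phi)) {
      if (i == fit_idx) next
      q <- prepped[[i]]
      pred <- load_intensity(sol_hat, q$protocol, q$trace$time_s)
      checks[[length(checks) + 1]] <- data.frame(
        porosity = phi, rate = q$meta$strain_rate,
        r2 = r_squared(pred, q$trace))
    }
  }
  parameter_table <- do.call(rbind, rows)
  prediction_checks <- do.call(rbind, checks)

  # prediction layer from the fitted anchors
  anchors <- data.frame(porosity = parameter_table$porosity,
                        E1 = parameter_table$E1_kPa,
                        E3 = parameter_table$E3_kPa,
                        nu21 = parameter_table$nu21,
                        tg = parameter_table$tg_s)
  sweep_rates <- c(config$rates, Inf)
  sweeps <- do.call(rbind, lapply(porosities, function(phi) {
    par <- interpolate_porosity(anchors, phi)
    cbind(porosity = phi,
          rate_sweep(par$ec, par$tp, sweep_rates, config$total_strain))
  }))
  grid_phi <- seq(min(porosities), max(porosities), length.out = 5)
  grid <- expand.grid(porosity = grid_phi,
                      rate = c(config$rates, 10 * max(config$rates)))
  grid$peak_kPa <- vapply(seq_len(nrow(grid)), function(i) {
    par <- interpolate_porosity(anchors, grid$porosity[i])
    sweep <- rate_sweep(par$ec, par$tp, grid$rate[i], config$total_strain)
    sweep$peak_kPa
  }, numeric(1))
  surface <- fit_peak_surface(grid)
  note("peak surface RSS = %.4g kPa^2 over %d grid points", surface$rss,
       nrow(grid))

  report <- structure(list(parameter_table = parameter_table,
                           fits = fits,
                           prediction_checks = prediction_checks,
                           rate_sweeps = sweeps,
                           peak_surface = surface,
                           peak_grid = grid,
                           seed = config$seed,
                           log = log),
                      class = "study_report")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(parameter_table,
                     file.path(config$out_dir, "parameter_table.csv"),
                     row.names = FALSE)
    utils::write.csv(sweeps, file.path(config$out_dir, "rate_sweeps.csv"),
                     row.names = FALSE)
    utils::write.csv(prediction_checks,
                     file.path(config$out_dir, "prediction_checks.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(seed = config$seed,
           surface_coefficients = as.list(surface$coefficients),
           surface_rss = surface$rss, log = log),
      file.path(config$out_dir, "study_report.json"),
      auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("Synthetic relaxation study (seed ", x$seed, ")\n\n", sep = "")
  print(x$parameter_table, row.names = FALSE, digits = 4)
  cat("\nPrediction checks (r^2 at non-fitted rates):\n")
  print(x$prediction_checks, row.names = FALSE, digits = 3)
  invisible(x)
}
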