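#' Configuration for the staged least-squares fit
#'
#' Bounds, starting point and staging strategy for estimating
#' `(E1, nu21, tg)` from a processed relaxation trace with `(E3, nu31)` held
#' fixed. When `start` is `NULL` a deterministic data-driven start is used:
#' `E1 = E3/2` (the fiber-direction modulus is typically about twice the
#' in-plane one), `nu21 = 0.7`, and `tg` equal to the time the hold-phase
#' stress takes to fall by 63% of the peak-to-equilibrium drop.
#'
#' @param lower,upper named bounds for `E1` (kPa), `nu21`, `tg` (s).
#' @param start optional named starting vector (`E1`, `nu21`, `tg`).
#' @param staged if `TRUE` (default) two-parameter fits of `(E1, tg)` at held
#'   values of `nu21` precede the full three-parameter refinement.
#' @param nu_profile grid of held `nu21` values scanned in the staged mode;
#'   the best-scoring hold seeds the full fit. The scan makes the search
#'   robust to the shallow `(E1, nu21)` valley of the objective (the load
#'   intensity is only weakly sensitive to `beta = 1 - C12/C11`).
#' @param n_roots number of characteristic roots used in the model series.
#' @param ftol,ptol convergence tolerances passed to
#'   [minpack.lm::nls.lm.control()].
#' @return An object of class `"fit_config"`.
#' @export
fit_config <- function(lower = c(E1 = 0.1, nu21 = 1e-3, tg = 0.1),
                       upper = c(E1 = 100, nu21 = 0.999, tg = 1000),
                       start = NULL, staged = TRUE,
                       nu_profile = seq(0.35, 0.95, by = 0.1), n_roots = 20,
                       ftol = 1e-12, ptol = 1e-12) {
  stopifnot(all(c("E1", "nu21", "tg") %in% names(lower)),
            all(c("E1", "nu21", "tg") %in% names(upper)))
  if (any(!is.finite(lower)) || any(!is.finite(upper))) {
    stop("bounds must be finite")
  }
  if (any(lower[c("E1", "nu21", "tg")] >= upper[c("E1", "nu21", "tg")])) {
    stop("each lower bound must be below its upper bound")
  }
  if (!is.null(start)) {
    if (any(start < lower[names(start)] | start > upper[names(start)])) {
      stop("starting point must lie within the bounds")
    }
  }
  structure(list(lower = lower, upper = upper, start = start, staged = staged,
                 nu_profile = nu_profile, n_roots = n_roots,
                 ftol = ftol, ptol = ptol),
            class = "fit_config")
}

## model load intensity on a time grid for trial parameters; returns NULL
## when the trial point is thermodynamically inadmissible (Delta1 <= 0)
model_load_intensity <- function(E1, nu21, tg, E3, nu31, protocol, times,
                                 n_roots = 20) {
  delta1 <- 1 - nu21 - 2 * nu31^2 * E1 / E3
  if (delta1 <= 1e-8 || E1 <= 0 || tg <= 0 || nu21 <= -1) return(NULL)
  ec <- tryCatch(engineering_constants(E1, E3, nu21, nu31),
                 error = function(e) NULL)
  if (is.null(ec)) return(NULL)
  C <- stiffness_from_engineering(ec)
  roots <- characteristic_roots(1 - C$C12 / C$C11, n_roots)
  sol <- step_response(C, roots, tg)
  load_intensity(sol, protocol, times)$stress_kPa
}

## deterministic data-driven starting point (see fit_config)
default_fit_start <- function(trace, protocol, E3, config) {
  t0 <- protocol$ramp_time
  hold <- trace$time_s >= t0
  P_hold <- trace$stress_kPa[hold]
  t_hold <- trace$time_s[hold]
  P_pk <- max(P_hold)
  P_eq <- mean(utils::tail(trace$stress_kPa, min(nrow(trace), 1000)))
  target <- P_eq + exp(-1) * (P_pk - P_eq)
  below <- which(P_hold <= target)
  tg0 <- if (length(below)) max(t_hold[below[1]] - t0, 1) else
    max(t_hold) - t0
  start <- c(E1 = E3 / 2, nu21 = 0.7, tg = tg0)
  pmin(pmax(start, config$lower + 1e-6), config$upper - 1e-6)
}

#' Estimate (E1, nu21, tg) from a relaxation trace
#'
#' Bounded nonlinear least squares of the analytic ramp-and-hold series
#' against the processed trace, minimizing the sum of squared stress
#' differences over both the loading and hold phases. The equilibrium
#' modulus `E3` and the axial-radial Poisson ratio `nu31` are fixed inputs
#' (from [equilibrium_modulus()] and configuration, respectively). In the
#' staged mode the in-plane Poisson ratio is first held fixed while
#' `(E1, tg)` are fitted — the hold is scanned over a coarse `nu21` grid and
#' the best-scoring hold seeds the full three-parameter refinement. The scan
#' matters because the objective has a long shallow valley: the load
#' intensity depends on `(E1, nu21)` essentially only through the
#' instantaneous modulus `M0` and (weakly) the boundary coefficient
#' `beta = 1 - C12/C11`, so a plain descent can stall far from the global
#' minimum. Trial points violating the admissibility
#' constraint `Delta1 > 0` receive a large graded penalty so the optimizer
#' is steered back into the feasible region.
#'
#' @param trace a `relaxation_trace` data frame covering ramp and hold.
#' @param protocol the [ramp_protocol()] used in the experiment.
#' @param E3 fixed equilibrium modulus, kPa.
#' @param nu31 fixed axial-radial Poisson ratio (default 0.24).
#' @param config a [fit_config()].
#' @return An object of class `"fit_result"`: estimated `E1`, `nu21`, `tg`,
#'   the fixed `E3`, `nu31`, sum of squared differences `ssd` (kPa^2), `r2`,
#'   iteration count, convergence flag and the fitted model trace.
#' @export
fit_parameters <- function(trace, protocol, E3, nu31 = 0.24,
                           config = fit_config()) {
  stopifnot(inherits(protocol, "ramp_protocol"), inherits(config, "fit_config"))
  if (nrow(trace) < 10) stop("trace too short to fit")
  if (max(trace$time_s) < protocol$ramp_time) {
    stop("trace does not cover the loading ramp")
  }
  if (max(trace$time_s) < 2 * protocol$ramp_time) {
    warning("trace has essentially no hold phase; tg is weakly identified")
  }
  times <- trace$time_s
  data_P <- trace$stress_kPa
  penalty_scale <- max(abs(data_P), 1)

  residual <- function(par, fixed) {
    p <- c(par, fixed)
    m <- model_load_intensity(p[["E1"]], p[["nu21"]], p[["tg"]], E3, nu31,
                              protocol, times, config$n_roots)
    if (is.null(m)) {
      viol <- max(0, -(1 - p[["nu21"]] - 2 * nu31^2 * p[["E1"]] / E3))
      return(rep(1e3 * penalty_scale * (1 + viol), length(times)))
    }
    m - data_P
  }

  start <- config$start
  if (is.null(start)) start <- default_fit_start(trace, protocol, E3, config)
  start <- start[c("E1", "nu21", "tg")]

  ctrl <- minpack.lm::nls.lm.control(ftol = config$ftol, ptol = config$ptol,
                                     maxiter = 400)
  run_lm <- function(start_free, fixed) {
    minpack.lm::nls.lm(
      par = start_free,
      lower = config$lower[names(start_free)],
      upper = config$upper[names(start_free)],
      fn = residual, fixed = fixed, control = ctrl)
  }

  n_iter <- 0L
  if (config$staged) {
    # profile the held nu21 over a coarse grid; keep the best 2-parameter fit
    nu_grid <- unique(c(start[["nu21"]], config$nu_profile))
    nu_grid <- nu_grid[nu_grid > config$lower[["nu21"]] &
                         nu_grid < config$upper[["nu21"]]]
    best <- NULL
    for (nu in nu_grid) {
      s1 <- run_lm(start[c("E1", "tg")], c(nu21 = nu))
      n_iter <- n_iter + s1$niter
      if (is.null(best) || s1$deviance < best$dev) {
        best <- list(par = s1$par, nu = nu, dev = s1$deviance)
      }
    }
    start[c("E1", "tg")] <- best$par
    start[["nu21"]] <- best$nu
  }
  fit <- run_lm(start, numeric(0))
  n_iter <- n_iter + fit$niter
  par <- fit$par

  model <- model_load_intensity(par[["E1"]], par[["nu21"]], par[["tg"]],
                                E3, nu31, protocol, times, config$n_roots)
  model_trace <- relaxation_trace(times, model, protocol)
  structure(list(
    E1 = unname(par[["E1"]]), nu21 = unname(par[["nu21"]]),
    tg = unname(par[["tg"]]), E3 = E3, nu31 = nu31,
    ssd = sum((model - data_P)^2),
    r2 = r_squared(model_trace, trace),
    n_iter = n_iter,
    converged = fit$info %in% 1:4,
    info = fit$info, message = fit$message,
    model = model_trace), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Poroelastic parameter fit\n")
  cat(sprintf("  E1 = %.3f kPa, nu21 = %.4f, tg = %.3f s  (fixed E3 = %.3f kPa, nu31 = %.3f)\n",
              x$E1, x$nu21, x$tg, x$E3, x$nu31))
  cat(sprintf("  SSD = %.4g kPa^2, r^2 = %.4f, %d iterations, converged: %s\n",
              x$ssd, x$r2, x$n_iter, x$converged))
  invisible(x)
}

#' Coefficient of determination between model and data traces
#'
#' `r^2 = 1 - SSR/SST` with the total sum of squares taken about the data
#' mean. Values below zero are possible (model worse than the mean) and are
#' returned as such.
#'
#' @param model,data `relaxation_trace` data frames on identical time grids.
#' @return Dimensionless r-squared (<= 1).
#' @export
r_squared <- function(model, data) {
  if (nrow(model) != nrow(data) ||
      any(abs(model$time_s - data$time_s) > 1e-9)) {
    stop("model and data must share the same time grid")
  }
  sst <- sum((data$stress_kPa - mean(data$stress_kPa))^2)
  if (sst == 0) stop("constant data: r^2 undefined (SST = 0)")
  1 - sum((model$stress_kPa - data$stress_kPa)^2) / sst
}
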