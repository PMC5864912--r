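#' Peak load intensity of a ramp-and-hold protocol
#'
#' For the superposition of a monotonically decreasing relaxation kernel the
#' load maximum always occurs at the end of the ramp, so the peak is
#' evaluated analytically at `t = t0` (and equals `M0 * eps0` for a step).
#'
#' @param sol a [step_response()] series solution.
#' @param protocol a [ramp_protocol()].
#' @return Peak load intensity, kPa.
#' @export
peak_load <- function(sol, protocol) {
  if (protocol$step) return(sol$M0 * protocol$total_strain)
  load_intensity(sol, protocol, protocol$ramp_time)$stress_kPa
}

#' Strain-rate sweep of peak and equilibrium load
#'
#' Computes, for each loading rate, the peak load intensity, the equilibrium
#' load `E3 * eps0`, and their ratio. The ratio grows monotonically with
#' rate and is bounded above by the step (isochoric) ratio `M0 / E3`; it
#' tends to 1 in the quasi-static limit.
#'
#' @param ec [engineering_constants()].
#' @param tp [transport_parameters()] with `tg`.
#' @param rates loading rates, 1/s; may include `Inf` for the step limit.
#' @param total_strain applied strain (default 0.1).
#' @param n_roots series terms.
#' @return A data frame with columns `rate`, `peak_kPa`, `equilibrium_kPa`,
#'   `ratio`.
#' @export
rate_sweep <- function(ec, tp, rates, total_strain = 0.1, n_roots = 20) {
  stopifnot(inherits(ec, "engineering_constants"),
            inherits(tp, "transport_parameters"))
  if (any(rates <= 0)) stop("rates must be positive (Inf allowed for step)")
  C <- stiffness_from_engineering(ec)
  roots <- characteristic_roots(1 - C$C12 / C$C11, n_roots)
  sol <- step_response(C, roots, tp$tg)
  eq <- sol$E3_eq * total_strain
  peaks <- vapply(rates, function(r) {
    peak_load(sol, ramp_protocol(r, total_strain))
  }, numeric(1))
  data.frame(rate = rates, peak_kPa = peaks, equilibrium_kPa = eq,
             ratio = peaks / eq)
}

#' Linear porosity interpolation of scaffold parameters
#'
#' Componentwise linear interpolation of `(E1, E3, nu21, tg)` between the
#' porosity anchors; `nu31` is held at its configured constant. Porosities
#' outside the anchor hull are either clamped to the nearest anchor (with a
#' warning, the default) or linearly extrapolated when
#' `extrapolate = TRUE`.
#'
#' @param anchors a data frame with columns `porosity`, `E1`, `E3`, `nu21`,
#'   `tg` (one row per anchor, at least two), or `NULL` for the package's
#'   50%/70% anchor sets.
#' @param phi target porosity (fraction).
#' @param nu31 constant axial-radial Poisson ratio.
#' @param extrapolate allow linear extrapolation outside the hull.
#' @return A list with `ec` ([engineering_constants()]) and `tp`
#'   ([transport_parameters()]) at the requested porosity.
#' @export
interpolate_porosity <- function(anchors = NULL, phi, nu31 = 0.24,
                                 extrapolate = FALSE) {
  if (is.null(anchors)) {
    sets <- study_anchor_sets()
    anchors <- do.call(rbind, lapply(names(sets), function(nm) {
      s <- sets[[nm]]
      data.frame(porosity = as.numeric(nm), E1 = s$ec$E1, E3 = s$ec$E3,
                 nu21 = s$ec$nu21, tg = s$tp$tg)
    }))
  }
  stopifnot(nrow(anchors) >= 2,
            all(c("porosity", "E1", "E3", "nu21", "tg") %in% names(anchors)))
  rng <- range(anchors$porosity)
  if (phi < rng[1] || phi > rng[2]) {
    if (extrapolate) {
      warning("porosity ", phi, " outside anchor hull [", rng[1], ", ",
              rng[2], "]; extrapolating linearly")
    } else {
      warning("porosity ", phi, " outside anchor hull [", rng[1], ", ",
              rng[2], "]; clamping to the nearest anchor")
      phi <- min(max(phi, rng[1]), rng[2])
    }
  }
  interp1 <- function(y) {
    if (extrapolate) {
      # linear fit through the two nearest anchors
      o <- order(abs(anchors$porosity - phi))[1:2]
      slope <- diff(y[o]) / diff(anchors$porosity[o])
      y[o[1]] + slope * (phi - anchors$porosity[o[1]])
    } else {
      stats::approx(anchors$porosity, y, xout = phi, rule = 2)$y
    }
  }
  list(ec = engineering_constants(interp1(anchors$E1), interp1(anchors$E3),
                                  interp1(anchors$nu21), nu31),
       tp = transport_parameters(tg = interp1(anchors$tg), porosity = phi))
}

#' Fit the peak-load surface over porosity and strain rate
#'
#' Nonlinear least squares of the empirical surface
#' `f(x, y) = m x + n + a exp(b y) + c exp(d y)` (x = porosity fraction,
#' y = strain rate) to a grid of computed peak loads. Porosity is taken as a
#' fraction: with percent coordinates the surface coefficients drive the
#' predicted force negative over the physical range.
#'
#' @param peaks a data frame with columns `porosity`, `rate`, `peak_kPa`
#'   spanning at least two porosities and at least three rates.
#' @param start optional named starting coefficients
#'   (`m`, `n`, `a`, `b`, `c`, `d`).
#' @return An object of class `"peak_surface_fit"`: `coefficients`,
#'   `residuals`, `fitted`, and the `predict` closure `f(x, y)`.
#' @export
fit_peak_surface <- function(peaks, start = NULL) {
  stopifnot(all(c("porosity", "rate", "peak_kPa") %in% names(peaks)))
  if (length(unique(peaks$porosity)) < 2 || length(unique(peaks$rate)) < 3) {
    stop("degenerate grid: need at least 2 porosities and 3 rates")
  }
  x <- peaks$porosity; y <- peaks$rate; z <- peaks$peak_kPa
  if (is.null(start)) {
    lin <- stats::coef(stats::lm(z ~ x))
    start <- c(m = unname(lin[2]), n = unname(lin[1]), a = diff(range(z)),
               b = -1 / stats::median(y), c = -0.1, d = 0.01)
  }
  f <- function(p, x, y) {
    p[["m"]] * x + p[["n"]] + p[["a"]] * exp(p[["b"]] * y) +
      p[["c"]] * exp(p[["d"]] * y)
  }
  fit <- minpack.lm::nls.lm(par = start,
                            fn = function(p) f(p, x, y) - z,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  co <- fit$par
  structure(list(coefficients = co,
                 residuals = f(co, x, y) - z,
                 fitted = f(co, x, y),
                 rss = sum((f(co, x, y) - z)^2),
                 predict = function(x, y) f(co, x, y)),
            class = "peak_surface_fit")
}

#' @export
print.peak_surface_fit <- function(x, ...) {
  co <- x$coefficients
  cat("Peak-load surface  f(x, y) = m x + n + a exp(b y) + c exp(d y)\n")
  cat(sprintf("  m = %.4g, n = %.4g, a = %.4g, b = %.4g, c = %.4g, d = %.4g\n",
              co[["m"]], co[["n"]], co[["a"]], co[["b"]], co[["c"]], co[["d"]]))
  cat(sprintf("  RSS = %.4g kPa^2 on %d points\n", x$rss, length(x$residuals)))
  invisible(x)
}
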