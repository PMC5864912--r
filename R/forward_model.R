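#' Ramp-and-hold strain protocol
#'
#' The axial strain rises linearly at rate `strain_rate` until it reaches
#' `total_strain` at `t0 = total_strain/strain_rate`, then is held. A step
#' protocol (instantaneous strain application) is represented exactly by
#' `strain_rate = Inf`, not by a small ramp time.
#'
#' @param strain_rate loading rate, 1/s; `Inf` for a step.
#' @param total_strain final applied strain (dimensionless), e.g. 0.1 for 10%;
#'   zero is allowed and denotes the null protocol (no loading).
#' @param hold_time duration of the hold phase, s.
#' @return An object of class `"ramp_protocol"` with fields `strain_rate`,
#'   `total_strain`, `ramp_time`, `hold_time`, `step` (logical).
#' @export
ramp_protocol <- function(strain_rate, total_strain, hold_time = 100) {
  if (total_strain < 0) stop("total_strain must be non-negative")
  if (strain_rate <= 0) stop("strain_rate must be positive (Inf for a step)")
  if (hold_time < 0) stop("hold_time must be non-negative")
  step <- is.infinite(strain_rate)
  structure(list(strain_rate = strain_rate, total_strain = total_strain,
                 ramp_time = if (step) 0 else total_strain / strain_rate,
                 hold_time = hold_time, step = step),
            class = "ramp_protocol")
}

#' @export
print.ramp_protocol <- function(x, ...) {
  if (x$step) {
    cat(sprintf("Step strain protocol: eps0 = %g, hold %g s\n",
                x$total_strain, x$hold_time))
  } else {
    cat(sprintf("Ramp-and-hold protocol: rate %g /s to eps0 = %g (t0 = %g s), hold %g s\n",
                x$strain_rate, x$total_strain, x$ramp_time, x$hold_time))
  }
  invisible(x)
}

## McMahon expansion start points for the positive zeros of J0
j0_zeros <- function(n) {
  b <- (seq_len(n) - 0.25) * pi
  approx0 <- b + 1 / (8 * b)
  vapply(approx0, function(x0) {
    uniroot(function(x) besselJ(x, 0), c(x0 - 0.5, x0 + 0.5),
            tol = .Machine$double.eps)$root
  }, numeric(1))
}

#' Characteristic Bessel roots of the radial consolidation problem
#'
#' Computes the positive roots `alpha_n` of the characteristic equation
#' `alpha J0(alpha) - beta J1(alpha) = 0` with `beta = 1 - C12/C11`, which
#' arises from the traction-free, free-draining lateral boundary condition.
#' The roots set the relaxation spectrum: the n-th relaxation time is
#' `tg / alpha_n^2`. Exactly one root lies in each interval between
#' consecutive zeros of J0 (for `beta` in `[0, 1)`); each bracketed root is
#' polished by Newton iteration to a residual below 1e-12.
#'
#' @param beta the coefficient `1 - C12/C11`, in `[0, 1)`.
#' @param n_roots number of roots (default 20, matching the point at which
#'   the truncated ramp-response series is numerically converged).
#' @return An object of class `"bessel_roots"` with fields `alpha`
#'   (increasing), `beta`, `n`.
#' @examples
#' characteristic_roots(0, 3)$alpha       # zeros of J0
#' characteristic_roots(0.204, 5)$alpha   # shifted slightly below them
#' @export
characteristic_roots <- function(beta, n_roots = 20) {
  if (!is.numeric(beta) || length(beta) != 1 || beta < 0 || beta >= 1) {
    stop("beta must lie in [0, 1); got ", beta,
         " (check C12/C11 of the stiffness matrix)")
  }
  if (n_roots < 1) stop("n_roots must be at least 1")
  zj <- j0_zeros(n_roots)
  if (beta == 0) {
    # the equation degenerates to alpha J0(alpha) = 0: the zeros of J0
    return(structure(list(alpha = zj, beta = 0, n = n_roots),
                     class = "bessel_roots"))
  }
  f  <- function(x) x * besselJ(x, 0) - beta * besselJ(x, 1)
  fp <- function(x) {
    # d/dx [x J0 - beta J1] with J0' = -J1, J1' = J0 - J1/x
    besselJ(x, 0) - x * besselJ(x, 1) -
      beta * (besselJ(x, 0) - besselJ(x, 1) / x)
  }
  lo <- c(1e-8, zj[-n_roots] + 1e-10)
  alpha <- vapply(seq_len(n_roots), function(i) {
    r <- uniroot(f, c(lo[i], zj[i]), tol = 1e-14, extendInt = "no")$root
    for (it in 1:3) r <- r - f(r) / fp(r)  # Newton polish to machine residual
    r
  }, numeric(1))
  structure(list(alpha = alpha, beta = beta, n = n_roots),
            class = "bessel_roots")
}

#' Step-strain series solution for the load intensity
#'
#' Builds the relaxation-modulus series of the long poroelastic cylinder:
#' after a unit step of axial strain the load intensity is
#' `G(t) = E3 + sum_n B_n exp(-alpha_n^2 t / tg)`, where
#' `E3 = C33 - 2 C13^2/(C11+C12)` is the drained equilibrium modulus and the
#' instantaneous (isochoric) modulus is `M0 = C33 - 2 C13 + (C11+C12)/2`.
#' The modal amplitudes follow from the eigenfunction expansion of the
#' radial consolidation problem:
#' `B_n = (M0 - E3) * 2 (2 - beta) / (alpha_n^2 - 1 + (beta - 1)^2)`,
#' so that `sum_n B_n -> M0 - E3` as the number of roots grows (the
#' convergence is slow, like `1/alpha_n^2`, because the isochoric initial
#' state violates the lateral traction condition; ramp responses converge
#' much faster, like `1/alpha_n^4`).
#'
#' @param C a [stiffness_matrix()].
#' @param roots a [characteristic_roots()] set computed for
#'   `beta = 1 - C12/C11` of the same matrix.
#' @param tg gel diffusion time, s (default 1, i.e. time measured in units
#'   of `tg`).
#' @return An object of class `"series_solution"` with fields `E3_eq`, `M0`
#'   (kPa), `B` (modal amplitudes, kPa), `alpha`, `tau` (relaxation times
#'   `tg/alpha^2`, s), `tg`, `beta`.
#' @export
step_response <- function(C, roots, tg = 1) {
  stopifnot(inherits(C, "stiffness_matrix"), inherits(roots, "bessel_roots"))
  if (tg <= 0) stop("tg must be positive")
  beta <- 1 - C$C12 / C$C11
  if (abs(beta - roots$beta) > 1e-12 * max(1, abs(beta))) {
    stop("root set was computed for beta = ", roots$beta,
         " but the stiffness matrix has beta = ", beta)
  }
  E3 <- equilibrium_E3(C)
  M0 <- instantaneous_modulus(C)
  a2 <- roots$alpha^2
  B  <- (M0 - E3) * 2 * (2 - beta) / (a2 - 1 + (beta - 1)^2)
  structure(list(E3_eq = E3, M0 = M0, B = B, alpha = roots$alpha,
                 tau = tg / a2, tg = tg, beta = beta),
            class = "series_solution")
}

#' @export
print.series_solution <- function(x, ...) {
  cat(sprintf("Poroelastic relaxation series: %d modes, tg = %g s\n",
              length(x$B), x$tg))
  cat(sprintf("  E3(eq) = %.4f kPa, M0(isochoric) = %.4f kPa, sum B_n = %.4f kPa\n",
              x$E3_eq, x$M0, sum(x$B)))
  cat(sprintf("  leading relaxation times: %s s\n",
              paste(signif(utils::head(x$tau, 3), 4), collapse = ", ")))
  invisible(x)
}

#' Load intensity under a ramp-and-hold protocol
#'
#' Evaluates the cross-section-averaged axial stress `P(t)` (kPa) by Duhamel
#' superposition of the step response over the strain history, in closed form
#' (term-wise exponential integrals): during the ramp
#' `P(t) = rate * (E3 t + sum_n B_n tau_n (1 - exp(-t/tau_n)))` and during
#' the hold the same expression with the ramp window shifted. For a step
#' protocol `P(t) = eps0 G(t)`.
#'
#' @param sol a [step_response()] series solution.
#' @param protocol a [ramp_protocol()].
#' @param times non-negative, non-decreasing evaluation times, s.
#' @return A `relaxation_trace` data frame with columns `time_s`,
#'   `stress_kPa`, carrying the protocol as attribute `"protocol"`.
#' @export
load_intensity <- function(sol, protocol, times) {
  stopifnot(inherits(sol, "series_solution"), inherits(protocol, "ramp_protocol"))
  if (length(times) == 0) stop("empty time grid")
  if (any(times < 0)) stop("times must be non-negative")
  if (is.unsorted(times)) stop("times must be non-decreasing")
  eps0 <- protocol$total_strain
  B <- sol$B; tau <- sol$tau; E3 <- sol$E3_eq
  if (protocol$step) {
    decay <- exp(-outer(1 / tau, times))  # modes x times
    P <- eps0 * (E3 + colSums(B * decay))
  } else {
    t0 <- protocol$ramp_time
    rate <- protocol$strain_rate
    tr <- pmin(times, t0)
    # ramp part: integral of G over [0, min(t, t0)] shifted to end at t
    ramp_sum <- colSums(B * tau * (exp(-outer(1 / tau, times - tr)) -
                                     exp(-outer(1 / tau, times))))
    P <- rate * (E3 * tr + ramp_sum)
  }
  relaxation_trace(times, P, protocol)
}

## light constructor for the uniformly-typed trace container
relaxation_trace <- function(time_s, stress_kPa, protocol = NULL) {
  if (any(!is.finite(stress_kPa))) stop("non-finite stress values in trace")
  out <- data.frame(time_s = time_s, stress_kPa = stress_kPa)
  class(out) <- c("relaxation_trace", "data.frame")
  attr(out, "protocol") <- protocol
  out
}

#' Radial displacement, pore pressure and fluid flux fields
#'
#' Reconstructs the interior fields of the relaxing cylinder from the modal
#' expansion. Displacement is reported normalized by the radius
#' (`u_r / a`), pressure in kPa, and the relative fluid (Darcy) flux in
#' units of radii per second. The pore pressure satisfies the free-draining
#' condition `p(r = a, t) = 0` identically, and at drained equilibrium
#' `u_r(r)/a -> -nu31 eps0 r/a`.
#'
#' @param C a [stiffness_matrix()].
#' @param tp [transport_parameters()] with `tg` set (radius only scales the
#'   normalized outputs and is not required).
#' @param protocol a [ramp_protocol()].
#' @param r_grid normalized radii in `[0, 1]`.
#' @param times evaluation times, s.
#' @param n_roots number of series terms.
#' @return A list of class `"radial_fields"` with elements `r_over_a`,
#'   `time_s`, and matrices `u_over_a`, `p_kPa`, `w_over_a` (rows = radii,
#'   columns = times).
#' @export
radial_fields <- function(C, tp, protocol, r_grid, times, n_roots = 20) {
  stopifnot(inherits(C, "stiffness_matrix"),
            inherits(tp, "transport_parameters"),
            inherits(protocol, "ramp_protocol"))
  if (any(r_grid < 0 | r_grid > 1)) stop("r_grid must lie in [0, 1]")
  if (is.null(tp$tg)) stop("transport parameters must carry tg")
  tg <- tp$tg
  beta <- 1 - C$C12 / C$C11
  roots <- characteristic_roots(beta, n_roots)
  al <- roots$alpha
  nu31 <- C$C13 / (C$C11 + C$C12)
  eps0 <- protocol$total_strain

  # per-unit-strain modal displacement amplitudes (u/a), from the
  # eigenfunction expansion of the isochoric initial state
  a_n <- -(0.5 - nu31) * 2 * (2 - beta) /
    (besselJ(al, 1) * (al^2 - 1 + (beta - 1)^2))
  tau <- tg / al^2

  # time factors by Duhamel superposition (modes x times)
  if (protocol$step) {
    eps_t <- rep(eps0, length(times))
    amp <- eps0 * a_n * exp(-outer(1 / tau, times))
  } else {
    t0 <- protocol$ramp_time
    eps_t <- pmin(times, t0) * protocol$strain_rate
    tr <- pmin(times, t0)
    amp <- protocol$strain_rate * a_n * tau *
      (exp(-outer(1 / tau, times - tr)) - exp(-outer(1 / tau, times)))
  }

  J1r <- outer(r_grid, al, function(r, a) besselJ(a * r, 1))  # radii x modes
  J0r <- outer(r_grid, al, function(r, a) besselJ(a * r, 0))
  u <- -nu31 * outer(r_grid, eps_t) + J1r %*% amp
  # p = C11 [L0 u(rho) - L0 u(1)], modal L0 J1(al rho) = al J0(al rho)
  p <- C$C11 * (sweep(J0r, 2, besselJ(al, 0), "-") %*% (al * amp))
  # Darcy flux w_r = -k dp/dr; in radii/s: -(1/(tg C11)) dp/drho with p in kPa
  dJ0 <- -outer(r_grid, al, function(r, a) a * besselJ(a * r, 1))
  w <- -(dJ0 %*% (al * amp)) / tg  # C11 cancels
  structure(list(r_over_a = r_grid, time_s = times,
                 u_over_a = u, p_kPa = p, w_over_a = w),
            class = "radial_fields")
}
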