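#' Grid specification for the finite-difference solver
#'
#' @param n_nodes number of radial intervals (>= 32); the grid is uniform in
#'   `r/a` with nodes `0, h, ..., 1`.
#' @param rtol,atol integration tolerances passed to [deSolve::ode()].
#' @return An object of class `"grid_spec"`.
#' @export
grid_spec <- function(n_nodes = 200, rtol = 1e-8, atol = 1e-10) {
  if (n_nodes < 32) stop("n_nodes must be at least 32")
  if (rtol <= 0 || atol <= 0) stop("tolerances must be positive")
  structure(list(n_nodes = as.integer(n_nodes), rtol = rtol, atol = atol),
            class = "grid_spec")
}

#' Finite-difference solution of the radial consolidation problem
#'
#' Independent method-of-lines solver used to validate the analytic series.
#' The reduced displacement problem for the normalized radial displacement
#' `v = u/a` on `rho = r/a` in `[0, 1]` is
#' `dv/dt = (1/tg) d/drho[(1/rho) d(rho v)/drho] - (deps/dt) rho / 2`,
#' with `v(0) = 0` and the traction-free, free-draining Robin condition
#' `C11 v'(1) + C12 v(1) = -C13 eps(t)`. Space is discretized by
#' conservative second-order central differences with a ghost node carrying
#' the Robin condition; time integration uses the stiff `lsoda` method with
#' a banded (tridiagonal) Jacobian. The load intensity is recovered by
#' trapezoidal quadrature of the cross-section average of the axial total
#' stress `sigma_zz = C13 (eps_rr + eps_phiphi) + C33 eps - p`.
#'
#' A step protocol cannot be represented exactly on the integrator, so it is
#' approximated by a ramp with `t0 = 1e-4 tg` (documented behaviour).
#'
#' @param C a [stiffness_matrix()].
#' @param tp [transport_parameters()] with `tg` set.
#' @param protocol a [ramp_protocol()].
#' @param grid a [grid_spec()].
#' @param times output times, s.
#' @return A list with elements `trace` (a `relaxation_trace` data frame) and
#'   `fields` (list with `r_over_a`, `time_s`, `u_over_a`, `p_kPa` matrices,
#'   rows = radii including the axis, columns = times).
#' @export
solve_radial_consolidation <- function(C, tp, protocol, grid = grid_spec(),
                                       times) {
  stopifnot(inherits(C, "stiffness_matrix"),
            inherits(tp, "transport_parameters"),
            inherits(protocol, "ramp_protocol"),
            inherits(grid, "grid_spec"))
  if (is.null(tp$tg)) stop("transport parameters must carry tg")
  if (length(times) == 0) stop("empty time grid")
  tg <- tp$tg
  eps0 <- protocol$total_strain
  if (eps0 == 0) {  # null protocol: nothing moves
    N <- grid$n_nodes
    z <- matrix(0, N + 1, length(times))
    return(list(trace = relaxation_trace(times, numeric(length(times)),
                                         protocol),
                fields = list(r_over_a = (0:N) / N, time_s = times,
                              u_over_a = z, p_kPa = z)))
  }
  t0 <- if (protocol$step) 1e-4 * tg else protocol$ramp_time
  rate <- eps0 / t0

  N <- grid$n_nodes
  h <- 1 / N
  rho <- (1:N) * h           # interior + boundary nodes (v(0) = 0 eliminated)
  k12 <- C$C12 / C$C11
  k13 <- C$C13 / C$C11

  rhs <- function(t, v, parms) {
    eps <- if (t < t0) rate * t else eps0
    ed  <- if (t < t0) rate else 0
    vfull <- c(0, v)                       # prepend axis value
    vg <- vfull[N] - 2 * h * (k12 * vfull[N + 1] + k13 * eps)  # ghost node
    vp <- c(vfull[3:(N + 1)], vg)
    vm <- vfull[1:N]
    vi <- vfull[2:(N + 1)]
    L <- (vp - 2 * vi + vm) / h^2 + (vp - vm) / (2 * rho * h) - vi / rho^2
    list(L / tg - ed * rho / 2)
  }

  solve_phase <- function(v0, tt) {
    if (length(tt) < 2) return(matrix(v0, nrow = 1))
    # a phase of negligible duration (e.g. a vanishing ramp time) cannot be
    # integrated; the state does not change over it
    if (tt[length(tt)] - tt[1] < 1e-10 * max(tg, 1)) {
      return(matrix(v0, nrow = length(tt), ncol = length(v0), byrow = TRUE))
    }
    sol <- deSolve::ode(v0, tt, rhs, NULL, method = "lsoda",
                        rtol = grid$rtol, atol = grid$atol,
                        jactype = "bandint", bandup = 1, banddown = 1)
    if (attr(sol, "istate")[1] < 0) {
      stop("radial consolidation integration failed (istate = ",
           attr(sol, "istate")[1], ")")
    }
    unname(sol[, -1, drop = FALSE])
  }

  # integrate ramp and hold phases separately so the kink at t0 is exact
  tt <- sort(unique(c(times, 0, t0)))
  pre  <- tt[tt <= t0]
  post <- tt[tt >= t0]
  v_pre <- solve_phase(rep(0, N), pre)
  v_t0  <- v_pre[nrow(v_pre), ]
  v_post <- if (length(post) > 1) solve_phase(v_t0, post) else
    matrix(v_t0, nrow = 1)
  v_all <- rbind(v_pre, v_post[-1, , drop = FALSE])
  keep <- match(times, tt)
  v <- v_all[keep, , drop = FALSE]          # times x N

  eps_t <- pmin(times, t0) * rate
  ed_t  <- ifelse(times < t0, rate, 0)

  # reconstruct fields on the full node set (axis included)
  rho_full <- c(0, rho)
  nt <- length(times)
  u <- rbind(0, t(v))                       # radii x times
  p <- matrix(0, N + 1, nt)
  sigma_zz <- matrix(0, N + 1, nt)
  for (j in seq_len(nt)) {
    vf <- c(0, v[j, ])                      # nodes 0..N
    vg <- vf[N] - 2 * h * (k12 * vf[N + 1] + k13 * eps_t[j])
    vext <- c(vf, vg)                       # nodes 0..N+1 (ghost)
    # L0 v = v' + v/rho by central differences at nodes 1..N;
    # at the axis L'Hopital gives L0 v(0) = 2 v'(0) (one-sided, 2nd order)
    vprime <- (vext[3:(N + 2)] - vext[1:N]) / (2 * h)
    L0 <- c(2 * (2 * vf[2] - 0.5 * vf[3]) / h, vprime + vf[-1] / rho)
    p[, j] <- C$C11 * (L0 - L0[N + 1])
    sigma_zz[, j] <- C$C13 * L0 + C$C33 * eps_t[j] - p[, j]
  }
  # P(t) = 2 * integral_0^1 sigma_zz rho drho (trapezoid)
  wts <- h * c(0.5, rep(1, N - 1), 0.5)
  P <- 2 * colSums(sigma_zz * rho_full * wts)
  list(trace = relaxation_trace(times, P, protocol),
       fields = list(r_over_a = rho_full, time_s = times,
                     u_over_a = u, p_kPa = p))
}
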