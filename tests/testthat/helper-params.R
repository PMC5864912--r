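# Anchor parameter sets for the two scaffold porosities (estimated at 1%/s,
# 10% strain), used as ground truth throughout the suite.
anchor_50 <- function() {
  list(ec = engineering_constants(E1 = 8.49, E3 = 19.19,
                                  nu21 = 0.75, nu31 = 0.24),
       tp = transport_parameters(tg = 40.62, a = 1e-3, porosity = 0.5))
}

anchor_70 <- function() {
  list(ec = engineering_constants(E1 = 5.61, E3 = 11.97,
                                  nu21 = 0.82, nu31 = 0.24),
       tp = transport_parameters(tg = 17.58, a = 1e-3, porosity = 0.7))
}

# Draw an admissible random parameter set (valid compliance, beta in (0,1)).
random_valid_ec <- function() {
  repeat {
    E1 <- runif(1, 2, 15)
    E3 <- runif(1, E1, 30)
    nu31 <- runif(1, 0.1, 0.4)
    nu21_max <- 1 - 2 * nu31^2 * E1 / E3 - 0.05
    if (nu21_max <= 0.15) next
    nu21 <- runif(1, 0.1, min(0.9, nu21_max))
    ec <- tryCatch(engineering_constants(E1, E3, nu21, nu31),
                   error = function(e) NULL)
    if (is.null(ec)) next
    C <- stiffness_from_engineering(ec)
    beta <- 1 - C$C12 / C$C11
    if (beta > 0.01 && beta < 0.99) return(ec)
  }
}

# Independent bisection root finder for the characteristic function,
# scanning for sign changes on a fine grid (oracle for characteristic_roots).
bisect_char_roots <- function(beta, n_roots, upper = 80) {
  f <- function(x) x * besselJ(x, 0) - beta * besselJ(x, 1)
  xs <- seq(1e-6, upper, by = 5e-3)
  fv <- f(xs)
  idx <- which(diff(sign(fv)) != 0)
  roots <- vapply(idx, function(i) {
    lo <- xs[i]; hi <- xs[i + 1]
    for (k in 1:60) {
      mid <- (lo + hi) / 2
      if (sign(f(mid)) == sign(f(lo))) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
  roots[seq_len(n_roots)]
}

# Bare trace builder for filter tests (bypasses the forward model).
relaxation_trace_for_test <- function(time_s, stress_kPa) {
  out <- data.frame(time_s = time_s, stress_kPa = stress_kPa)
  class(out) <- c("relaxation_trace", "data.frame")
  out
}
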