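#' Engineering constants of a transversely isotropic scaffold skeleton
#'
#' Bundles the four elastic constants of the drained solid skeleton: the
#' in-plane Young's modulus `E1` (perpendicular to the fibers), the
#' fiber-direction Young's modulus `E3`, the in-plane Poisson ratio `nu21`
#' and the axial-radial Poisson ratio `nu31` (lateral contraction per unit
#' axial extension). Validation enforces thermodynamic admissibility: the
#' compliance matrix assembled from the constants must be symmetric positive
#' definite, which in particular requires
#' `Delta1 = 1 - nu21 - 2 nu31^2 E1/E3 > 0`.
#'
#' @param E1 in-plane Young's modulus, kPa.
#' @param E3 fiber-direction Young's modulus, kPa.
#' @param nu21 in-plane Poisson's ratio (dimensionless).
#' @param nu31 axial-radial Poisson's ratio (dimensionless).
#' @return An object of class `"engineering_constants"`.
#' @examples
#' ec <- engineering_constants(E1 = 8.49, E3 = 19.19, nu21 = 0.75, nu31 = 0.24)
#' stiffness_from_engineering(ec)
#' @export
engineering_constants <- function(E1, E3, nu21, nu31) {
  stopifnot(is.numeric(E1), is.numeric(E3), is.numeric(nu21), is.numeric(nu31))
  if (E1 <= 0) stop("E1 must be positive (got ", E1, ")")
  if (E3 <= 0) stop("E3 must be positive (got ", E3, ")")
  ec <- structure(list(E1 = E1, E3 = E3, nu21 = nu21, nu31 = nu31),
                  class = "engineering_constants")
  delta1 <- 1 - nu21 - 2 * nu31^2 * E1 / E3
  if (delta1 <= 0) {
    stop("inadmissible constants: Delta1 = 1 - nu21 - 2*nu31^2*E1/E3 = ",
         signif(delta1, 4), " must be positive")
  }
  S <- compliance_matrix(ec)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) {
    stop("inadmissible constants: compliance matrix is not positive definite ",
         "(eigenvalues ", paste(signif(ev, 4), collapse = ", "), ")")
  }
  ec
}

#' @export
print.engineering_constants <- function(x, ...) {
  cat("Transversely isotropic engineering constants\n")
  cat(sprintf("  E1 = %.4g kPa   E3 = %.4g kPa   nu21 = %.4g   nu31 = %.4g\n",
              x$E1, x$E3, x$nu21, x$nu31))
  invisible(x)
}

## 3x3 axisymmetric compliance in (rr, phiphi, zz) ordering.
## S13 couples radial strain to axial stress: eps_rr = -nu31 sigma_zz / E3.
compliance_matrix <- function(ec) {
  with(ec, matrix(c(
     1 / E1,      -nu21 / E1,  -nu31 / E3,
    -nu21 / E1,    1 / E1,     -nu31 / E3,
    -nu31 / E3,   -nu31 / E3,   1 / E3), 3, 3, byrow = TRUE))
}

#' Stiffness matrix from engineering constants
#'
#' Converts engineering constants to the plane-strain-axisymmetric stiffness
#' coefficients `C11, C12, C13, C33` (kPa) relating the elastic stresses
#' `(sigma_rr, sigma_phiphi, sigma_zz)` to the strains
#' `(eps_rr, eps_phiphi, eps_zz)`. The conversion is performed by exact
#' numerical inversion of the transversely isotropic compliance matrix, which
#' guarantees the drained-equilibrium identities
#' `C33 - 2*C13^2/(C11+C12) = E3` and `C13/(C11+C12) = nu31` hold to machine
#' precision.
#'
#' @param ec an [engineering_constants()] object.
#' @return An object of class `"stiffness_matrix"` with fields `C11`, `C12`,
#'   `C13`, `C33` in kPa.
#' @seealso [engineering_from_stiffness()] for the inverse map.
#' @export
stiffness_from_engineering <- function(ec) {
  stopifnot(inherits(ec, "engineering_constants"))
  S <- compliance_matrix(ec)
  C <- solve(S)
  out <- stiffness_matrix(C11 = C[1, 1], C12 = C[1, 2],
                          C13 = C[1, 3], C33 = C[3, 3])
  out
}

#' Construct and validate a stiffness matrix
#'
#' @param C11,C12,C13,C33 stiffness coefficients, kPa.
#' @return An object of class `"stiffness_matrix"`.
#' @export
stiffness_matrix <- function(C11, C12, C13, C33) {
  if (C11 <= abs(C12)) {
    stop("invalid stiffness: C11 > |C12| violated (C11 = ", signif(C11, 4),
         ", C12 = ", signif(C12, 4), ")")
  }
  if (C11 + C12 <= 0) stop("invalid stiffness: C11 + C12 must be positive")
  if (C33 <= 0) stop("invalid stiffness: C33 must be positive")
  if ((C11 + C12) * C33 - 2 * C13^2 <= 0) {
    stop("invalid stiffness: (C11+C12)*C33 - 2*C13^2 must be positive")
  }
  structure(list(C11 = C11, C12 = C12, C13 = C13, C33 = C33),
            class = "stiffness_matrix")
}

#' @export
print.stiffness_matrix <- function(x, ...) {
  cat("Axisymmetric stiffness matrix (kPa)\n")
  cat(sprintf("  C11 = %.4f  C12 = %.4f  C13 = %.4f  C33 = %.4f\n",
              x$C11, x$C12, x$C13, x$C33))
  cat(sprintf("  equilibrium E3 = %.4f kPa, nu31 = %.4f, beta = %.4f\n",
              equilibrium_E3(x), x$C13 / (x$C11 + x$C12),
              1 - x$C12 / x$C11))
  invisible(x)
}

## drained-equilibrium axial modulus C33 - 2 C13^2 / (C11 + C12)
equilibrium_E3 <- function(C) C$C33 - 2 * C$C13^2 / (C$C11 + C$C12)

## instantaneous (isochoric) axial modulus C33 - 2 C13 + (C11 + C12)/2
instantaneous_modulus <- function(C) C$C33 - 2 * C$C13 + (C$C11 + C$C12) / 2

#' Engineering constants from a stiffness matrix
#'
#' Inverse of [stiffness_from_engineering()]: reassembles the full 3x3
#' stiffness, inverts it, and reads the engineering constants off the
#' compliance. Round-trips with the forward map to near machine precision.
#'
#' @param C a [stiffness_matrix()] object.
#' @return An [engineering_constants()] object.
#' @export
engineering_from_stiffness <- function(C) {
  stopifnot(inherits(C, "stiffness_matrix"))
  M <- with(C, matrix(c(C11, C12, C13,
                        C12, C11, C13,
                        C13, C13, C33), 3, 3, byrow = TRUE))
  S <- tryCatch(solve(M), error = function(e)
    stop("singular stiffness matrix: ", conditionMessage(e)))
  engineering_constants(E1   = 1 / S[1, 1],
                        E3   = 1 / S[3, 3],
                        nu21 = -S[1, 2] / S[1, 1],
                        nu31 = -S[1, 3] / S[3, 3])
}

#' Transport parameters of the pore fluid
#'
#' Holds the Darcy permeability `k` (m^4/(N s)), the gel diffusion time
#' `tg` (s), the specimen radius `a` (m) and the porosity (fluid volume
#' fraction). `k`, `tg` and `a` are linked through the stiffness by
#' `tg = a^2 / (k C11)`; porosity is carried as metadata (it drops out of the
#' reduced radial consolidation problem) and as the interpolation coordinate
#' of the prediction layer.
#'
#' @param k Darcy permeability, m^4/(N s), or `NULL`.
#' @param tg gel diffusion time, s, or `NULL`.
#' @param a specimen radius, m, or `NULL`.
#' @param porosity fluid volume fraction in `[0, 1)`, or `NA`.
#' @return An object of class `"transport_parameters"`.
#' @export
transport_parameters <- function(k = NULL, tg = NULL, a = NULL, porosity = NA) {
  if (!is.null(k) && k <= 0) stop("permeability k must be positive")
  if (!is.null(tg) && tg <= 0) stop("gel diffusion time tg must be positive")
  if (!is.null(a) && a <= 0) stop("radius a must be positive")
  if (!is.na(porosity) && (porosity < 0 || porosity >= 1)) {
    stop("porosity must lie in [0, 1)")
  }
  structure(list(k = k, tg = tg, a = a, porosity = porosity),
            class = "transport_parameters")
}

#' Complete transport parameters through the gel-time relation
#'
#' Given exactly two of `{k, tg, a}` plus the radial stiffness `C11`, computes
#' the missing quantity from `tg = a^2 / (k C11)`. `C11` is supplied in kPa
#' and converted to N/m^2 internally, so `k` keeps its SI units.
#'
#' @param tp a [transport_parameters()] object with exactly two of `k`, `tg`,
#'   `a` set.
#' @param C11_kPa radial stiffness coefficient, kPa.
#' @return The completed `transport_parameters` object.
#' @export
gel_time_permeability <- function(tp, C11_kPa) {
  stopifnot(inherits(tp, "transport_parameters"))
  if (C11_kPa <= 0) stop("C11 must be positive")
  C11 <- C11_kPa * 1000  # kPa -> N/m^2
  given <- !vapply(tp[c("k", "tg", "a")], is.null, logical(1))
  if (sum(given) != 2) {
    stop("exactly two of {k, tg, a} must be given (got ", sum(given), ")")
  }
  if (is.null(tp$tg)) tp$tg <- tp$a^2 / (tp$k * C11)
  else if (is.null(tp$k)) tp$k <- tp$a^2 / (tp$tg * C11)
  else tp$a <- sqrt(tp$tg * tp$k * C11)
  tp
}

#' Read or write a scaffold parameter set as JSON
#'
#' The on-disk dialect uses keys `E1_kPa`, `E3_kPa`, `nu21`, `nu31`, `tg_s`,
#' `porosity`, `radius_m`; numbers are written at full precision so a
#' read-write cycle is bit stable.
#'
#' @param path file path.
#' @return `read_scaffold_params` returns a list with elements `ec`
#'   ([engineering_constants()]) and `tp` ([transport_parameters()]).
#' @export
read_scaffold_params <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("E1_kPa", "E3_kPa", "nu21", "nu31", "tg_s")
  miss <- setdiff(need, names(doc))
  if (length(miss)) stop("parameter file missing keys: ",
                         paste(miss, collapse = ", "))
  list(
    ec = engineering_constants(doc$E1_kPa, doc$E3_kPa, doc$nu21, doc$nu31),
    tp = transport_parameters(tg = doc$tg_s,
                              a = if (!is.null(doc$radius_m)) doc$radius_m,
                              porosity = if (!is.null(doc$porosity))
                                doc$porosity else NA)
  )
}

#' @rdname read_scaffold_params
#' @param ec an [engineering_constants()] object.
#' @param tp a [transport_parameters()] object.
#' @export
write_scaffold_params <- function(ec, tp, path) {
  doc <- list(E1_kPa = ec$E1, E3_kPa = ec$E3, nu21 = ec$nu21, nu31 = ec$nu31,
              tg_s = tp$tg, porosity = tp$porosity, radius_m = tp$a)
  doc <- doc[!vapply(doc, is.null, logical(1))]
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
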