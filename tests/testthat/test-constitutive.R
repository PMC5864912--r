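test_that("stiffness conversion reproduces the anchor parameter sets", {
  cases <- list(
    list(set = anchor_50(),
         expect = c(C11 = 23.75, C12 = 18.90, C13 = 10.24, C33 = 24.10)),
    list(set = anchor_70(),
         expect = c(C11 = 23.80, C12 = 20.72, C13 = 10.68, C33 = 17.10))
  )
  for (cs in cases) {
    C <- stiffness_from_engineering(cs$set$ec)
    expect_equal(C$C11, cs$expect[["C11"]], tolerance = 5e-4)
    expect_equal(C$C12, cs$expect[["C12"]], tolerance = 5e-4)
    expect_equal(C$C13, cs$expect[["C13"]], tolerance = 5e-4)
    expect_equal(C$C33, cs$expect[["C33"]], tolerance = 5e-4)
    # drained-equilibrium identities hold to machine precision
    expect_equal(C$C33 - 2 * C$C13^2 / (C$C11 + C$C12), cs$set$ec$E3,
                 tolerance = 1e-12)
    expect_equal(C$C13 / (C$C11 + C$C12), cs$set$ec$nu31, tolerance = 1e-12)
  }
})

test_that("isotropic limit collapses to the Lame closed form", {
  E <- 12; nu <- 0.3
  C <- stiffness_from_engineering(engineering_constants(E, E, nu, nu))
  lam_fac <- E / ((1 + nu) * (1 - 2 * nu))
  expect_equal(C$C11, lam_fac * (1 - nu), tolerance = 1e-12)
  expect_equal(C$C33, lam_fac * (1 - nu), tolerance = 1e-12)
  expect_equal(C$C12, lam_fac * nu, tolerance = 1e-12)
  expect_equal(C$C13, lam_fac * nu, tolerance = 1e-12)
})

test_that("engineering/stiffness maps round-trip on randomized valid inputs", {
  set.seed(41)
  for (i in 1:25) {
    ec <- random_valid_ec()
    C <- stiffness_from_engineering(ec)
    # stiffness inverts the compliance assembled from the constants
    S <- matrix(c(1 / ec$E1, -ec$nu21 / ec$E1, -ec$nu31 / ec$E3,
                  -ec$nu21 / ec$E1, 1 / ec$E1, -ec$nu31 / ec$E3,
                  -ec$nu31 / ec$E3, -ec$nu31 / ec$E3, 1 / ec$E3),
                3, 3, byrow = TRUE)
    M <- matrix(c(C$C11, C$C12, C$C13,
                  C$C12, C$C11, C$C13,
                  C$C13, C$C13, C$C33), 3, 3, byrow = TRUE)
    expect_lt(max(abs(M %*% S - diag(3))), 1e-10)
    back <- engineering_from_stiffness(C)
    expect_equal(back$E1, ec$E1, tolerance = 1e-10)
    expect_equal(back$E3, ec$E3, tolerance = 1e-10)
    expect_equal(back$nu21, ec$nu21, tolerance = 1e-10)
    expect_equal(back$nu31, ec$nu31, tolerance = 1e-10)
    # positive definiteness carried through the inversion
    expect_true(all(eigen(M, symmetric = TRUE, only.values = TRUE)$values > 0))
  }
})

test_that("inadmissible constants are rejected with a named violation", {
  expect_error(engineering_constants(-1, 19, 0.75, 0.24), "E1")
  expect_error(engineering_constants(8.49, -1, 0.75, 0.24), "E3")
  # Delta1 <= 0: nearly incompressible in-plane plus strong coupling
  expect_error(engineering_constants(19, 19, 0.9, 0.4), "Delta1")
  expect_error(stiffness_matrix(10, 11, 3, 20), "C11")
  expect_error(stiffness_matrix(10, 5, 20, 20), "C13|2\\*C13")
})

test_that("gel-time relation completes any missing transport quantity", {
  C11 <- 23.75
  # a^2 scaling: doubling the radius quadruples tg at fixed k
  tp1 <- gel_time_permeability(transport_parameters(k = 1e-12, a = 1e-3), C11)
  tp2 <- gel_time_permeability(transport_parameters(k = 1e-12, a = 2e-3), C11)
  expect_equal(tp2$tg / tp1$tg, 4, tolerance = 1e-12)
  # solve for k, check by re-substitution
  tp3 <- gel_time_permeability(transport_parameters(tg = 40.62, a = 1e-3), C11)
  expect_equal(tp3$a^2 / (tp3$k * C11 * 1000), 40.62, tolerance = 1e-12)
  # k -> infinity drives tg -> 0
  tp4 <- gel_time_permeability(transport_parameters(k = 1e6, a = 1e-3), C11)
  expect_lt(tp4$tg, 1e-12)
  # over- and under-determined inputs
  expect_error(gel_time_permeability(
    transport_parameters(k = 1e-12, tg = 40, a = 1e-3), C11), "exactly two")
  expect_error(gel_time_permeability(transport_parameters(k = 1e-12), C11),
               "exactly two")
})

test_that("scaffold parameter JSON round-trips bit-stable", {
  set <- anchor_50()
  path <- withr::local_tempfile(fileext = ".json")
  write_scaffold_params(set$ec, set$tp, path)
  back <- read_scaffold_params(path)
  expect_identical(back$ec$E1, set$ec$E1)
  expect_identical(back$ec$nu21, set$ec$nu21)
  expect_identical(back$tp$tg, set$tp$tg)
  expect_identical(back$tp$porosity, set$tp$porosity)
  # a second write of the re-read parameters produces identical bytes
  path2 <- withr::local_tempfile(fileext = ".json")
  write_scaffold_params(back$ec, back$tp, path2)
  expect_identical(readLines(path), readLines(path2))
})
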