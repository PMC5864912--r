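test_that("zero-noise traces equal the forward-model output exactly", {
  set <- anchor_50()
  pr <- ramp_protocol(0.01, 0.1, 100)
  raw <- generate_trace(set$ec, set$tp, pr,
                        noise_spec(motor_amplitude = 0, sensor_sigma = 0,
                                   seed = 1))
  tr <- convert_raw(raw, attr(raw, "calibration"))
  C <- stiffness_from_engineering(set$ec)
  sol <- step_response(C, characteristic_roots(1 - C$C12 / C$C11, 20),
                       set$tp$tg)
  expected <- load_intensity(sol, pr, tr$time_s)$stress_kPa
  expect_equal(tr$stress_kPa, expected, tolerance = 1e-12)
  expect_equal(attr(raw, "clean_kPa"), expected, tolerance = 1e-14)
})

test_that("generation is deterministic in the seed", {
  set <- anchor_70()
  pr <- ramp_protocol(0.01, 0.1, 100)
  a <- generate_trace(set$ec, set$tp, pr, noise_spec(seed = 42))
  b <- generate_trace(set$ec, set$tp, pr, noise_spec(seed = 42))
  d <- generate_trace(set$ec, set$tp, pr, noise_spec(seed = 43))
  expect_identical(a$signal_V, b$signal_V)
  expect_false(identical(a$signal_V, d$signal_V))
  # the generator must not disturb the caller's RNG stream
  set.seed(7); before <- rnorm(3)
  set.seed(7); invisible(generate_trace(set$ec, set$tp, pr,
                                        noise_spec(seed = 1)))
  after <- rnorm(3)
  expect_identical(before, after)
})

test_that("noise residual is dominated by the motor line in the periodogram", {
  set <- anchor_50()
  pr <- ramp_protocol(0.01, 0.1, 100)
  raw <- generate_trace(set$ec, set$tp, pr, noise_spec(seed = 6))
  tr <- convert_raw(raw, attr(raw, "calibration"))
  resid <- tr$stress_kPa - attr(raw, "clean_kPa")
  n <- length(resid)
  spec <- Mod(stats::fft(resid))[2:(n %/% 2)]
  freq <- (seq_along(spec)) * 100 / n
  expect_equal(freq[which.max(spec)], 1, tolerance = 0.02)
})

test_that("sensor noise variance matches its specification", {
  set <- anchor_50()
  pr <- ramp_protocol(0.01, 0.1, 100)  # 11001 samples
  sigma <- 0.04
  raw <- generate_trace(set$ec, set$tp, pr,
                        noise_spec(motor_amplitude = 0, sensor_sigma = sigma,
                                   seed = 21))
  tr <- convert_raw(raw, attr(raw, "calibration"))
  resid <- tr$stress_kPa - attr(raw, "clean_kPa")
  expect_equal(stats::var(resid), sigma^2, tolerance = 0.1)
})

test_that("matched smoothing removes >90% of the motor component", {
  set <- anchor_50()
  pr <- ramp_protocol(0.01, 0.1, 100)
  raw <- generate_trace(set$ec, set$tp, pr,
                        noise_spec(sensor_sigma = 0, seed = 17))
  tr <- convert_raw(raw, attr(raw, "calibration"))
  frame <- frame_length(pr$ramp_time, 100, n_cycles = 10)  # 1 Hz motor
  sm <- smooth_trace(tr, frame)
  # isolate the periodic component: compare against the smoothed clean
  # trace so the filter's own bias at the ramp-end kink does not count
  clean <- relaxation_trace_for_test(tr$time_s, attr(raw, "clean_kPa"))
  sm_clean <- smooth_trace(clean, frame)
  motor_before <- tr$stress_kPa - attr(raw, "clean_kPa")
  motor_after <- sm$stress_kPa - sm_clean$stress_kPa
  interior <- seq(frame, nrow(tr) - frame)
  atten <- max(abs(motor_after[interior])) / max(abs(motor_before[interior]))
  expect_lt(atten, 0.1)
})

test_that("motor frequency above Nyquist is refused", {
  set <- anchor_50()
  pr <- ramp_protocol(0.01, 0.1, 10)
  expect_error(generate_trace(set$ec, set$tp, pr,
                              noise_spec(motor_frequency = 60), 100),
               "Nyquist")
})

test_that("the generated study spans the rate-porosity cross with sound tails", {
  tmp <- withr::local_tempdir()
  study <- generate_study(seed = 7, out_dir = tmp)
  expect_length(study, 8)
  metas <- lapply(study, attr, "meta")
  grid <- unique(data.frame(
    phi = vapply(metas, `[[`, numeric(1), "porosity"),
    rate = vapply(metas, `[[`, numeric(1), "strain_rate")))
  expect_identical(nrow(grid), 8L)
  expect_setequal(unique(grid$phi), c(0.5, 0.7))
  expect_setequal(unique(grid$rate), c(0.0025, 0.005, 0.01, 0.03))
  # every tail mean over eps0 recovers the generating E3 within noise
  for (tr_raw in study) {
    meta <- attr(tr_raw, "meta")
    tr <- convert_raw(tr_raw, attr(tr_raw, "calibration"))
    expect_equal(equilibrium_modulus(tr, meta$total_strain),
                 meta$truth$E3_kPa, tolerance = 0.02)
  }
  # files and self-describing sidecars on disk
  expect_length(list.files(tmp, pattern = "\\.csv$"), 8)
  sidecar <- jsonlite::read_json(file.path(tmp, "trace_01.json"),
                                 simplifyVector = TRUE)
  expect_true(all(c("porosity", "strain_rate", "sub_seed", "truth",
                    "calibration") %in% names(sidecar)))
  # study regeneration with the same seed is identical
  study2 <- generate_study(seed = 7)
  expect_identical(study[[3]]$signal_V, study2[[3]]$signal_V)
})
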