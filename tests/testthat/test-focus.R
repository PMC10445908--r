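# Autofocus calibration, PID behavior, focus lock and focus search.

test_that("noiseless calibration recovers the device gain exactly and is valid", {
  g <- him_test_graph(qpd_noise_v = 0)
  foc <- g$logic_module("focus")
  expect_error(foc$calibrate(), "785") # IR laser must be on
  g$device("lasers")$set_ir(TRUE)
  cal <- foc$calibrate()
  expect_lt(cal$precision_nm, 1e-6)
  expect_true(cal$monotonic)
  expect_true(cal$valid)
  expect_equal(cal$slope_v_per_um, g$device("qpd")$gain_v_per_um,
               tolerance = 1e-9)
  expect_equal(nrow(cal$ramp), 21)
  expect_error(foc$calibrate(n_steps = 2), "n_steps")
})

test_that("mean calibration precision matches the injected QPD noise level", {
  # noise_v chosen so the QPD noise is equivalent to 10 nm RMS in z
  precisions <- vapply(1:50, function(s) {
    g <- him_test_graph(seed = s, qpd_noise_v = 0.005)
    foc <- g$logic_module("focus")
    g$device("lasers")$set_ir(TRUE)
    foc$calibrate()$precision_nm
  }, numeric(1))
  # independent oracle: RMS residual of an n-point linear fit to noise of
  # sd sigma has expectation ~ sigma * sqrt((n-2)/n)
  expect_lt(abs(mean(precisions) - 10), 2)
})

test_that("a sign reversal in the ramp invalidates the calibration", {
  z <- seq(49, 51, length.out = 21)
  sig <- 0.5 * (z - 50)
  sig[11] <- sig[9] - 0.01 # injected reversal mid-ramp
  cal <- fit_calibration(z, sig)
  expect_false(cal$monotonic)
  expect_false(cal$valid)
})

test_that("calibration validity rule equals the independent fit oracle", {
  for (case in 1:20) {
    set.seed(case)
    z <- seq(49, 51, length.out = 21)
    noise_sd <- stats::runif(1, 0, 0.03)
    sig <- 0.5 * (z - 50) + stats::rnorm(21, 0, noise_sd)
    cal <- fit_calibration(z, sig)
    # oracle computed from closed-form least squares, not lm
    zc <- z - mean(z); sc <- sig - mean(sig)
    slope <- sum(zc * sc) / sum(zc^2)
    resid <- sig - (mean(sig) + slope * zc)
    prec <- sqrt(mean(resid^2)) / abs(slope) * 1000
    mono <- all(diff(sig) > 0) || all(diff(sig) < 0)
    expect_equal(cal$precision_nm, prec, tolerance = 1e-9)
    expect_identical(cal$valid, mono && prec < 30)
  }
})

test_that("precision is invariant under ramp direction reversal", {
  set.seed(4)
  z <- seq(49, 51, length.out = 21)
  sig <- 0.5 * (z - 50) + stats::rnorm(21, 0, 0.004)
  a <- fit_calibration(z, sig)
  b <- fit_calibration(rev(z), rev(sig))
  expect_equal(a$precision_nm, b$precision_nm, tolerance = 1e-9)
  expect_identical(a$valid, b$valid)
})

test_that("calibration exports to YAML and re-fits identically", {
  g <- him_test_graph(qpd_noise_v = 0.003)
  g$device("lasers")$set_ir(TRUE)
  cal <- g$logic_module("focus")$calibrate()
  path <- withr::local_tempfile(fileext = ".yml")
  calibration_to_yaml(cal, path)
  doc <- yaml::read_yaml(path)
  refit <- fit_calibration(doc$ramp$z_um, doc$ramp$signal_v)
  # YAML serializes doubles at finite precision
  expect_equal(refit$precision_nm, cal$precision_nm, tolerance = 1e-4)
  expect_equal(doc$valid, cal$valid)
})

test_that("PID null input, pure proportional mode, and saturation freeze", {
  p <- pid_params(kp = 2, ki = 1, kd = 0.5)
  st <- pid_state()
  expect_equal(pid_step(p, st, 0, 0.1)$output, 0)

  p2 <- pid_params(kp = 1.7)
  expect_equal(pid_step(p2, pid_state(), 3.5, 0.1)$output, 1.7 * 3.5)

  # hand-simulated trace: kp=0.4, ki=0.1, out_max=1, dt=1
  p3 <- pid_params(kp = 0.4, ki = 0.1, out_min = -1, out_max = 1)
  st <- pid_state()
  errors <- c(2, 2, 2, -1)
  hand_outputs <- c(1.0, # raw 0.8+0.1*2 = 1.0, not saturated, I -> 2
                    1.0, # raw 0.8+0.1*4 = 1.2 saturates -> clamp, I frozen
                    1.0, # same again, I stays 2
                    -0.3) # raw -0.4+0.1*(2-1) = -0.3, I -> 1
  for (i in seq_along(errors)) {
    r <- pid_step(p3, st, errors[i], 1)
    expect_equal(r$output, hand_outputs[i], info = paste("step", i))
    st <- r$state
  }
  expect_equal(st$integral, 1)
})

test_that("lock at equilibrium with no drift and no noise has zero error", {
  g <- him_test_graph(qpd_noise_v = 0)
  foc <- g$logic_module("focus")
  g$device("lasers")$set_ir(TRUE)
  foc$calibrate()
  foc$mark_focus()
  trace <- foc$lock(duration_s = 2)
  expect_equal(max(abs(trace$error_nm)), 0)
})

# independent discrete control-loop oracle: same plant geometry, PID
# re-implemented from its defining equations
oracle_lock <- function(drift_nm_s, duration_s, kp = 0.6, ki = 0.2,
                        dt = 0.1, z0 = 50, surface0 = 50,
                        out_lim = 1000, step_nm = 0) {
  n <- floor(duration_s / dt)
  z <- z0; surface <- surface0 + step_nm / 1000
  integral <- 0; prev_e <- 0
  err <- numeric(n)
  for (i in seq_len(n)) {
    e_nm <- (surface - z) * 1000 # setpoint is zero defocus
    err[i] <- e_nm
    icand <- integral + e_nm * dt
    raw <- kp * e_nm + ki * icand
    if (abs(raw) <= out_lim) integral <- icand else raw <- sign(raw) * out_lim
    z <- z + raw / 1000
    surface <- surface + drift_nm_s * dt / 1000
  }
  err
}

test_that("lock under linear drift stays within the reference oracle's bound", {
  g <- him_test_graph(qpd_noise_v = 0, drift_nm_s = 10)
  foc <- g$logic_module("focus")
  g$device("lasers")$set_ir(TRUE)
  foc$calibrate()
  # calibration rampy motion advanced the clock, so re-zero on the surface
  g$device("piezo")$move_to(g$sample$surface_z_um)
  g$device("piezo")$wait_settled()
  foc$mark_focus()
  trace <- foc$lock(duration_s = 30)
  oracle <- oracle_lock(10, 30)
  tail_idx <- seq(151, 300)
  bound <- max(abs(oracle[tail_idx]))
  expect_lte(max(abs(trace$error_nm[tail_idx])), bound * 1.05 + 0.5)
  # steady-state error must be small thanks to the integral term
  expect_lt(max(abs(trace$error_nm[tail_idx])), 10)
})

test_that("lock recovers from a 500 nm step within the oracle's recovery time", {
  g <- him_test_graph(qpd_noise_v = 0)
  foc <- g$logic_module("focus")
  g$device("lasers")$set_ir(TRUE)
  foc$calibrate()
  foc$mark_focus()
  g$sample$surface_z_um <- g$sample$surface_z_um + 0.5 # step disturbance
  trace <- foc$lock(duration_s = 10)
  oracle <- oracle_lock(0, 10, step_nm = 500)
  in_band <- function(e) {
    idx <- which(abs(e) > 30)
    if (length(idx) == 0) 0L else max(idx)
  }
  t_rec_impl <- in_band(trace$error_nm)
  t_rec_oracle <- in_band(oracle)
  expect_lte(t_rec_impl, t_rec_oracle + 2)
  # and it stays in the band afterwards
  expect_true(all(abs(trace$error_nm[(t_rec_impl + 1):100]) <= 30))
})

test_that("lock never commands the piezo outside travel for any gains", {
  g <- him_test_graph(qpd_noise_v = 0.01)
  foc <- g$logic_module("focus")
  g$device("lasers")$set_ir(TRUE)
  foc$calibrate()
  foc$mark_focus()
  g$sample$drift_nm_s <- 5000 # runaway drift only once locked
  aggressive <- pid_params(kp = 50, ki = 20, kd = 1, out_min = -1e6,
                           out_max = 1e6, period_s = 0.1)
  trace <- foc$lock(duration_s = 10, params = aggressive)
  piezo <- g$device("piezo")
  expect_true(all(trace$z_um >= piezo$travel_um[1]))
  expect_true(all(trace$z_um <= piezo$travel_um[2]))
})

test_that("focus search defines the stack reference below the focal plane", {
  g <- him_test_graph(qpd_noise_v = 0)
  foc <- g$logic_module("focus")
  g$device("lasers")$set_ir(TRUE)
  foc$calibrate()
  foc$mark_focus()
  sp <- foc$find_focus(below_offset_um = 1.5)
  expect_equal(sp$reference_z_um, sp$focal_z_um - 1.5)

  # idempotence: searching again moves the focal plane by < 10 nm
  sp2 <- foc$find_focus(below_offset_um = 1.5)
  expect_lt(abs(sp2$focal_z_um - sp$focal_z_um) * 1000, 10)

  # a 300 nm surface shift is tracked to within 30 nm
  g$sample$surface_z_um <- g$sample$surface_z_um + 0.3
  sp3 <- foc$find_focus(below_offset_um = 1.5)
  expect_lt(abs((sp3$focal_z_um - sp$focal_z_um) - 0.3) * 1000, 30)
})

test_that("lock and focus search refuse to run on an invalid calibration", {
  g <- him_test_graph(qpd_noise_v = 0)
  foc <- g$logic_module("focus")
  expect_error(foc$lock(1), "calibration")
  foc$calibration <- calibration_result(0.5, 0, 45, TRUE,
                                        data.frame(z_um = 0, signal_v = 0))
  expect_false(foc$calibration$valid)
  expect_error(foc$find_focus(), "valid")
})
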