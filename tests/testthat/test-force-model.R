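test_that("vertical amplitude gives exact weight support", {
  # brute-force oracle: average four overlapping half-sines, solve amplitude
  expect_equal(vertical_amplitude(1), oracle_vertical_amplitude(1),
               tolerance = 1e-6)
  expect_equal(vertical_amplitude(1), pi / 8, tolerance = 1e-12)
  expect_equal(vertical_amplitude(0.5), oracle_vertical_amplitude(0.5),
               tolerance = 1e-6)
  expect_equal(vertical_amplitude(0.5), pi / 4, tolerance = 1e-12)
  # stride-mean total vertical force equals gravity: the stance integral of a
  # half-sine is (2/pi) * amplitude * duration, so 4 limbs give exactly g
  for (df in c(0.55, 0.7, 0.85, 0.99)) {
    az <- vertical_amplitude(df, gravity = 1)
    expect_equal(4 * az * (2 / pi) * df, 1, tolerance = 1e-9)
  }
  expect_error(vertical_amplitude(0), "duty_factor")
  expect_error(vertical_amplitude(0.7, gravity = -1), "gravity")
})

test_that("footfall schedule follows the symmetrical-gait convention", {
  expect_equal(footfall_schedule(25),
               c(LH = 0, LF = 0.25, RH = 0.5, RF = 0.75))
  s50 <- footfall_schedule(50)   # trot: diagonal pairs together
  expect_equal(unname((s50["RF"] - s50["LH"]) %% 1), 0)
  expect_equal(unname(s50["LF"]), unname(s50["RH"]))
  s0 <- footfall_schedule(0)     # pace: ipsilateral pairs together
  expect_equal(unname(s0["LH"]), unname(s0["LF"]))
  expect_error(footfall_schedule(100), "\\[0, 100\\)")
  expect_error(footfall_schedule(-1), "\\[0, 100\\)")
})

test_that("limb force profiles satisfy their structural invariants", {
  cfg <- gait_variant("full", duty_factor = 0.7, phase_pct = 37)
  for (limb in c("LH", "LF", "RH", "RF")) {
    fs <- limb_force_series(cfg, limb)
    u <- (fs$time_fraction - fs$onset) %% 1
    swing <- u >= cfg$duty_factor
    expect_true(all(fs$fx[swing] == 0 & fs$fy[swing] == 0 &
                      fs$fz[swing] == 0))
    expect_true(all(fs$fz >= 0))
  }
  # full-sine fore-aft component integrates to zero over stance (no bias)
  base <- gait_config(0.7, 37)
  for (limb in c("LH", "RF")) {
    fs <- limb_force_series(base, limb)
    expect_equal(mean(fs$fx), 0, tolerance = 1e-6)
  }
})

test_that("bias splits fore-aft impulse between girdles and sums to zero", {
  cfg <- gait_variant("bias", duty_factor = 0.7, phase_pct = 25)
  imp <- vapply(all_limb_forces(cfg),
                function(f) unname(net_limb_impulse(f)$components["x"]),
                numeric(1))
  expect_true(all(imp[c("LH", "RH")] > 0))  # hind: net forward
  expect_true(all(imp[c("LF", "RF")] < 0))  # fore: net backward
  expect_lt(abs(sum(imp)), 1e-6)            # balanced to grid tolerance
})

test_that("suspended orientation mirrors the fore-aft force only", {
  up <- gait_config(0.72, 30)
  down <- gait_config(0.72, 30, orientation = "suspended")
  for (limb in c("LH", "LF")) {
    f_up <- limb_force_series(up, limb)
    f_dn <- limb_force_series(down, limb)
    expect_identical(f_dn$fx, -f_up$fx)
    expect_identical(f_dn$fz, f_up$fz)
    expect_identical(f_dn$fy, f_up$fy)
  }
})

test_that("medial forces point toward the midline, opposite per side", {
  # at trot phasing LF and RH share a stance window: equal and opposite fy
  cfg <- gait_variant("full", duty_factor = 0.7, phase_pct = 50)
  lf <- limb_force_series(cfg, "LF")
  rh <- limb_force_series(cfg, "RH")
  expect_equal(lf$onset, rh$onset)
  expect_identical(lf$fy, -rh$fy)
  expect_true(max(abs(lf$fy)) > 0)
})

test_that("CoM velocities fluctuate about the stated means", {
  cfg <- gait_variant("full", duty_factor = 0.68, phase_pct = 20)
  com <- com_velocities(all_limb_forces(cfg), cfg)
  expect_equal(mean(com$vz), 0, tolerance = 1e-9)
  expect_equal(mean(com$vy), 0, tolerance = 1e-9)
  expect_equal(mean(com$vx), com$mean_forward_speed, tolerance = 1e-9)
  expect_true(all(com$vx > 0))
})

test_that("too-small mean forward speed is rejected with advice", {
  cfg <- gait_config(0.65, 25, mean_forward_speed = 1e-5)
  expect_error(com_velocities(all_limb_forces(cfg), cfg),
               "mean_forward_speed")
})

test_that("limb power cancels components before rectification", {
  cfg <- gait_config(0.7, 25)
  forces <- all_limb_forces(cfg)
  com <- com_velocities(forces, cfg)
  p <- limb_power_series(forces$LH, com)
  # zero power outside stance
  u <- (forces$LH$time_fraction - forces$LH$onset) %% 1
  expect_true(all(p[u >= cfg$duty_factor] == 0))
  # signed work over all limbs vanishes over a periodic cycle
  signed <- sum(sapply(forces, function(f)
    mean(limb_power_series(f, com)) * cfg$stride_period))
  positive <- stride_work_cost(cfg)
  expect_lt(abs(signed), 1e-5 * positive)
  # hence positive parts balance negative parts
  negative <- sum(sapply(forces, function(f)
    mean(pmin(limb_power_series(f, com), 0)) * cfg$stride_period))
  expect_equal(positive, -negative, tolerance = 1e-5)
})

test_that("power series demands a common grid", {
  cfg1 <- gait_config(0.7, 25, samples_per_stride = 512)
  cfg2 <- gait_config(0.7, 25, samples_per_stride = 1024)
  com2 <- com_velocities(all_limb_forces(cfg2), cfg2)
  expect_error(limb_power_series(limb_force_series(cfg1, "LH"), com2),
               "common time grid")
})

test_that("stance angle reproduces the quarter-stance construction", {
  expect_equal(stance_angle(0.2), 30, tolerance = 2 / 30)  # within 2 degrees
  expect_equal(stance_angle(0), 0)
  ratios <- c(0.05, 0.1, 0.2, 0.4)
  expect_true(all(diff(stance_angle(ratios)) > 0))
})

test_that("planar cost is invariant under a 50% phase shift", {
  for (p in c(0, 10, 32.5)) {
    expect_equal(stride_work_cost(gait_config(0.66, p)),
                 stride_work_cost(gait_config(0.66, p + 50)),
                 tolerance = 1e-12)
  }
  # and medial forces break the equality
  c25 <- stride_work_cost(gait_variant("full", 0.65, 25))
  c75 <- stride_work_cost(gait_variant("full", 0.65, 75))
  expect_gt(abs(c25 - c75), 1e-6 * c25)
})

test_that("unbiased planar cost is time-reversal symmetric", {
  for (p in c(10, 30)) {
    a <- stride_work_cost(gait_config(0.7, p))
    b <- stride_work_cost(gait_config(0.7, 100 - p))
    expect_equal(a, b, tolerance = 1e-4)
  }
})

test_that("gait_config rejects out-of-domain parameters", {
  expect_error(gait_config(0.5, 25), "duty_factor")
  expect_error(gait_config(1, 25), "duty_factor")
  expect_error(gait_config(0.7, 25, fore_aft_ratio = -0.1), "non-negative")
  expect_error(gait_config(0.7, 25, samples_per_stride = 128), "256")
  expect_equal(gait_config(0.7, 125)$phase_pct, 25)  # circular phase
})
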