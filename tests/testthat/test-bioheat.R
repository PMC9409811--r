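# Transient Pennes solver: closed-form oracles, controller law,
# stability, energy balance.

test_that("source-free insulated equilibrium stays at baseline", {
  tab <- brain_tissue_table(grey_matter = list(omega_b = 0))
  g <- small_grid(spacing = 2, r = 10, z = c(-10, 10),
                  properties = tab)
  pr <- ablation_protocol(mode = "constant_voltage", voltage = 0,
                          duration = 10)
  tf <- run_transient(g, NULL, pr, dt = 0.5, thermal_bc = "insulated")
  for (snap in tf$snapshots)
    expect_equal(max(abs(snap - 37)), 0, tolerance = 1e-9)
})

test_that("uniform perfusion relaxation follows the scalar ODE", {
  # T(t) = 37 + 8 exp(-rho_b c_b omega_b t / (rho c)), within 0.1 C
  g <- small_grid(spacing = 2, r = 10, z = c(-10, 10))
  pr <- ablation_protocol(mode = "constant_voltage", voltage = 0,
                          duration = 20)
  tf <- run_transient(g, NULL, pr, dt = 0.05, initial_temp = 45,
                      thermal_bc = "insulated",
                      store_times = c(2, 5, 10, 15, 20))
  bl <- blood_properties()
  tau <- (1045 * 3700) / (bl$rho_b * bl$c_b * 0.0067)
  for (t in c(2, 5, 10, 15, 20)) {
    got <- tf$snapshots[[as.character(round(t / tf$dt))]][1, 1]
    expect_equal(got, 37 + 8 * exp(-t / tau), tolerance = 0.1 / 45)
  }
})

test_that("insulated-sphere steady state reproduces sigma V^2 / (2k)", {
  # classic RF closed form: tip temperature rise 28.0 C for
  # sigma = 0.28, V_s = 10 V, k = 0.5, within 5%
  tab <- brain_tissue_table(grey_matter = list(k = 0.5, omega_b = 0))
  g <- axisymmetric_grid(r_extent = 103, z_extent = c(-103, 103),
                         spacing = 4,
                         fine_window = list(r = c(0, 6), z = c(-6, 6)),
                         h_fine = 0.1, growth = 1.25, properties = tab)
  el <- electrode_spec(type = "sphere", radius = 1, center = 0)
  sol <- solve_potential(g, el, 10, ground = "sphere",
                         ground_radius = 100)
  Ts <- solve_steady_temperature(g, el, sol, ground = "sphere",
                                 ground_radius = 100)
  rise <- max(Ts, na.rm = TRUE) - 37
  expect_lt(abs(rise - 28) / 28, 0.05)
})

test_that("raising the voltage never cools any cell", {
  g <- small_grid(spacing = 1.5)
  pr <- function(V) ablation_protocol(mode = "constant_voltage",
                                      voltage = V, duration = 20)
  lo <- run_transient(g, electrode_spec(), pr(20), dt = 0.5)
  hi <- run_transient(g, electrode_spec(), pr(30), dt = 0.5)
  for (nm in names(lo$snapshots)) {
    d <- hi$snapshots[[nm]] - lo$snapshots[[nm]]
    expect_gte(min(d, na.rm = TRUE), -1e-9)
  }
})

test_that("implicit scheme is dt-stable; perfusion shrinks the lesion", {
  cfg <- preset_reference()
  g <- build_layered_phantom(cfg$phantom$layers, cfg$phantom$spacing,
                             cfg$phantom$extent,
                             fine_window = cfg$phantom$fine_window,
                             h_fine = 0.35, growth = cfg$phantom$growth)
  el <- electrode_spec()
  pr <- ablation_protocol(mode = "constant_voltage")
  a <- run_transient(g, el, pr, dt = 0.1)
  b <- run_transient(g, el, pr, dt = 0.05)
  expect_lt(abs(as.numeric(isotherm_radius(a, 60)) -
                  as.numeric(isotherm_radius(b, 60))), 0.1)
  # no perfusion: strictly larger 60 C radius at 90 s
  tab0 <- brain_tissue_table(grey_matter = list(omega_b = 0))
  g0 <- g; g0$properties <- tab0
  c0 <- run_transient(g0, el, pr, dt = 0.1)
  expect_gt(as.numeric(isotherm_radius(c0, 60)),
            as.numeric(isotherm_radius(a, 60)))
})

test_that("per-step energy balance closes", {
  g <- small_grid(spacing = 1.5)
  pr <- ablation_protocol(duration = 10)
  tf <- run_transient(g, electrode_spec(), pr, dt = 0.25,
                      energy_log = TRUE)
  e <- tf$energy
  resid <- abs(e[, "added"] - e[, "perfusion"] - e[, "boundary"] -
                 e[, "stored"])
  scale <- pmax(abs(e[, "added"]), abs(e[, "stored"]), 1e-6)
  expect_lt(max(resid / scale), 0.01)
})

test_that("explicit scheme cross-checks implicit and enforces CFL", {
  tab <- brain_tissue_table(grey_matter = list(omega_b = 0))
  g <- small_grid(spacing = 1.5, properties = tab)
  pr <- ablation_protocol(mode = "constant_voltage", voltage = 25,
                          duration = 5)
  expect_error(run_transient(g, electrode_spec(), pr, dt = 5,
                             scheme = "explicit"), "step-size error")
  im <- run_transient(g, electrode_spec(), pr, dt = 0.02)
  ex <- run_transient(g, electrode_spec(), pr, dt = 0.02,
                      scheme = "explicit")
  d <- im$snapshots[["250"]] - ex$snapshots[["250"]]
  expect_lt(max(abs(d), na.rm = TRUE), 0.05)
})

test_that("power controller follows the proportional law and clamps", {
  pr <- ablation_protocol()        # 2-6 W clamp, target 80
  base <- 4.4
  # at setpoint: scale unchanged (factor is exactly 1)
  s <- control_power(80, pr, current_scale = 0.8, base_power = base)
  expect_equal(as.numeric(s), 0.8)
  expect_false(attr(s, "clamped"))
  # far below target, large scale: clamps to the 6 W ceiling exactly
  s <- control_power(37, pr, current_scale = 1.3, base_power = base)
  expect_equal(attr(s, "power"), 6)
  expect_true(attr(s, "clamped"))
  # above target, small scale: clamps to the 2 W floor exactly
  s <- control_power(95, pr, current_scale = 0.46, base_power = base)
  expect_equal(attr(s, "power"), 2)
  expect_true(attr(s, "clamped"))
  # constant-voltage mode never regulates
  pc <- ablation_protocol(mode = "constant_voltage")
  s <- control_power(120, pc, current_scale = 0.2, base_power = base)
  expect_equal(as.numeric(s), 1)
  # setpoint ramp: early in the ramp the setpoint is below target
  expect_lt(rfablate:::protocol_setpoint(pr, 2), 80)
  expect_equal(rfablate:::protocol_setpoint(pr, pr$setpoint_ramp), 80)
})

test_that("time_to_threshold interpolates and signals not-reached", {
  fake <- structure(list(tip_trace = data.frame(
    time = c(0, 1, 2, 3), tip_temp = c(37, 50, 70, 90),
    tissue_max = c(37, 55, 75, 95))),
    class = "temperature_field")
  expect_equal(time_to_threshold(fake, 37), 0)
  expect_equal(time_to_threshold(fake, 80), 2.5)  # linear between 70, 90
  expect_true(is.na(time_to_threshold(fake, 200)))
  expect_equal(time_to_threshold(fake, 95, trace = "tissue_max"), 3)
})
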