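# Shared fixtures. The two reference runs are memoised so the
# acceptance blocks that share a run do not recompute it.

.ref_cache <- new.env(parent = emptyenv())

# published-simulation emulation: constant 34 V, insulated electrode
ref_lesion_run <- function() {
  if (is.null(.ref_cache$lesion))
    .ref_cache$lesion <- run_pipeline(preset_reference())
  .ref_cache$lesion
}

# generator emulation: temperature-controlled, thermocouple-sensed
ref_protocol_run <- function() {
  if (is.null(.ref_cache$protocol))
    .ref_cache$protocol <-
      run_pipeline(preset_reference(mode = "temperature_controlled"))
  .ref_cache$protocol
}

# concentric-spheres validation solve (a = 1 mm, b = 100 mm, 30 V,
# sigma = 0.28): graded grid, fine near the electrode
sphere_oracle_solve <- function(voltage = 30, h_fine = 0.1) {
  g <- axisymmetric_grid(
    r_extent = 103, z_extent = c(-103, 103), spacing = 4,
    fine_window = list(r = c(0, 6), z = c(-6, 6)), h_fine = h_fine,
    growth = 1.25,
    properties = brain_tissue_table())
  el <- electrode_spec(type = "sphere", radius = 1, center = 0)
  list(grid = g, electrode = el,
       sol = solve_potential(g, el, voltage, ground = "sphere",
                             ground_radius = 100))
}

# closed forms for the concentric-spheres geometry (mm in, SI out)
cf_phi <- function(r_mm, V = 30, a = 1, b = 100) {
  V * a * (b - r_mm) / (r_mm * (b - a))
}
cf_power <- function(V = 30, sigma = 0.28, a = 1e-3, b = 0.1) {
  4 * pi * sigma * V^2 * a * b / (b - a)
}
cf_q <- function(r_mm, V = 30, sigma = 0.28, a = 1e-3, b = 0.1) {
  r <- r_mm * 1e-3
  sigma * V^2 * a^2 * b^2 / ((b - a)^2 * r^4)
}

# small uniform grey-matter grid for cheap solver tests
small_grid <- function(spacing = 1, r = 30, z = c(-30, 30), ...) {
  axisymmetric_grid(r_extent = r, z_extent = z, spacing = spacing, ...)
}
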