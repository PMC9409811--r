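# Electro-quasistatic solver: closed-form validation, maximum
# principle, energy bookkeeping, grid convergence.

test_that("zero excitation gives a null field", {
  g <- small_grid(spacing = 1.5)
  sol <- solve_potential(g, electrode_spec(), 0)
  expect_true(all(sol$phi[sol$type == 0L] == 0))
  expect_true(all(sol$q_src == 0))
  expect_equal(sol$power_total, 0)
  expect_true(is.na(sol$impedance))
})

test_that("uniform axial drop reproduces |E| and q by hand arithmetic", {
  # 10 V across a 10 mm homogeneous white-matter column:
  # |E| = 1000 V/m, q = 0.27 * 1000^2 = 2.7e5 W/m^3
  g <- axisymmetric_grid(r_extent = 5, z_extent = c(0, 10),
                         spacing = 0.5, labels = 2L)
  sol <- solve_potential(g, NULL, 10, ground = "plates")
  expect_lt(max(abs(sol$e_mag - 1000)) / 1000, 1e-6)
  expect_lt(max(abs(sol$q_src - 2.7e5)) / 2.7e5, 1e-6)
  vol <- cell_volumes(g) * 1e-9
  expect_equal(sum(sol$q_src * vol), sol$power_total,
               tolerance = 1e-10)
})

test_that("concentric spheres match the closed form", {
  o <- sphere_oracle_solve()
  sol <- o$sol; g <- o$grid
  # power: 4 pi sigma V^2 a b / (b - a) = 3.20 W, within 2%
  expect_lt(abs(sol$power_total - cf_power()) / cf_power(), 0.02)
  # power/impedance identity to 1e-9 relative
  expect_equal(sol$power_total,
               sol$applied_voltage^2 / sol$impedance,
               tolerance = 1e-9)
  # potential at r ~ 2 mm on the equator, within 2%
  j <- which.min(abs(g$zc))
  i <- which.min(abs(g$rc - 2))
  rr <- sqrt(g$rc[i]^2 + g$zc[j]^2)
  expect_lt(abs(sol$phi[i, j] - cf_phi(rr)) / cf_phi(rr), 0.02)
  # q(r) ~ r^-4, within 3% at r = 2-5 mm
  for (rt in c(2, 3, 4, 5)) {
    i <- which.min(abs(g$rc - rt))
    rr <- sqrt(g$rc[i]^2 + g$zc[j]^2)
    expect_lt(abs(sol$q_src[i, j] - cf_q(rr)) / cf_q(rr), 0.03)
  }
  # discrete maximum principle and non-negative heating
  expect_true(all(sol$q_src >= 0))
  ph <- sol$phi[!is.na(sol$phi)]
  expect_gte(min(ph), 0)
  expect_lte(max(ph), 30)
})

test_that("energy bookkeeping: boundary flux times V equals integral of q", {
  g <- small_grid(spacing = 0.5)
  sol <- solve_potential(g, electrode_spec(), 34)
  vol <- cell_volumes(g) * 1e-9
  q_int <- sum(sol$q_src * vol)
  expect_lt(abs(q_int - sol$applied_voltage * sol$current) /
              q_int, 0.01)
  expect_equal(q_int, sol$power_total, tolerance = 1e-10)
})

test_that("maximum principle and q >= 0 hold for heterogeneous media", {
  set.seed(11)
  for (rep in 1:4) {
    sig <- stats::runif(3, 0.05, 1.5)
    tab <- brain_tissue_table(grey_matter = list(sigma = sig[1]),
                              white_matter = list(sigma = sig[2]),
                              hippocampus = list(sigma = sig[3]))
    ph <- build_layered_phantom(
      list(list(label = 1L, region = list(type = "all")),
           list(label = 2L, region = list(type = "slab",
                                          z = c(-30, stats::runif(1, -10, 5)))),
           list(label = 3L, region = list(type = "sphere",
                                          center = stats::runif(1, -8, 0),
                                          radius = stats::runif(1, 3, 8)))),
      spacing = 1, extent = list(r = 30, z = c(-30, 30)),
      properties = tab)
    V <- stats::runif(1, 5, 40)
    sol <- solve_potential(ph, electrode_spec(), V)
    ph_vals <- sol$phi[!is.na(sol$phi)]
    expect_gte(min(ph_vals), -1e-9 * V)
    expect_lte(max(ph_vals), V * (1 + 1e-9))
    expect_true(all(sol$q_src >= 0))
  }
})

test_that("refining the grid converges toward the closed form", {
  # small concentric-sphere twin (a = 2 mm, b = 20 mm) at three
  # uniform spacings; the L2 potential error over mid-field cells must
  # drop by at least a factor 2 per quarter refinement (stairstepped
  # Dirichlet boundaries are first order)
  err <- vapply(c(1, 0.5, 0.25), function(h) {
    g <- axisymmetric_grid(r_extent = 22, z_extent = c(-22, 22),
                           spacing = h)
    el <- electrode_spec(type = "sphere", radius = 2, center = 0)
    sol <- solve_potential(g, el, 30, ground = "sphere",
                           ground_radius = 20, min_clearance = 2)
    R <- matrix(g$rc, length(g$rc), length(g$zc))
    Z <- matrix(g$zc, length(g$rc), length(g$zc), byrow = TRUE)
    rr <- sqrt(R^2 + Z^2)
    mid <- rr > 5 & rr < 15 & !is.na(sol$phi)
    cf <- 30 * 2 * (20 - rr) / (rr * (20 - 2))
    sqrt(mean((sol$phi[mid] - cf[mid])^2))
  }, numeric(1))
  expect_lt(err[2], err[1])
  expect_lt(err[3], err[1] / 2)
})

test_that("geometry and consistency errors are reported", {
  g <- small_grid(spacing = 1.5)
  expect_error(solve_potential(g, electrode_spec(tip_position = -28),
                               30), "geometry error")
  sol <- solve_potential(g, electrode_spec(), 30)
  g2 <- small_grid(spacing = 1.5, r = 20, z = c(-20, 20))
  expect_error(heat_source(sol, g2), "consistency error")
  expect_identical(heat_source(sol, g), sol$q_src)
})
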