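# Lesion model: planning formula, isotherm extraction, composition,
# rasterization.

test_that("planning volume formula matches hand arithmetic", {
  expect_equal(lesion_volume_eq1(0, 5), 0)
  # r = 1, n = 1: 0.5*3.14 + 3.14*3 = 10.99
  expect_equal(lesion_volume_eq1(1, 1), 10.99)
  # r = 5.4, n = 5: 0.5*3.14*5.4^3 + 3.14*5.4^2*15
  expect_equal(lesion_volume_eq1(5.4, 5),
               0.5 * 3.14 * 5.4^3 + 3.14 * 5.4^2 * 15,
               tolerance = 1e-12)
  expect_equal(lesion_volume_eq1(5.4, 5), 1620.65448)
  expect_error(lesion_volume_eq1(-1, 2), "parameter error")
  expect_error(lesion_volume_eq1(2, 1.5), "parameter error")
})

test_that("planning volume is strictly increasing in r and n", {
  rs <- seq(0.5, 8, by = 0.5)
  expect_true(all(diff(lesion_volume_eq1(rs, 3)) > 0))
  ns <- 0:10
  expect_true(all(diff(lesion_volume_eq1(4.2, ns)) > 0))
  # geometric solid volume too, and it exceeds the planning value
  # (2/3 vs 1/2 hemisphere coefficient, exact vs truncated pi)
  expect_true(all(lesion_geometric_volume(rs, 3) >
                    lesion_volume_eq1(rs, 3)))
})

test_that("isotherm radius inverts a synthetic radial field", {
  # T(r) = 37 + 43 exp(-r^2 / (2 s^2)), s = 4 mm:
  # the 60 C contour sits at s * sqrt(2 log(43/23)) = 4.4753 mm
  g <- axisymmetric_grid(r_extent = 20, z_extent = c(-20, 20),
                         spacing = 0.1)
  R <- matrix(g$rc, length(g$rc), length(g$zc))
  Z <- matrix(g$zc, length(g$rc), length(g$zc), byrow = TRUE)
  Tmat <- 37 + 43 * exp(-(R^2 + Z^2) / (2 * 16))
  r <- isotherm_radius(Tmat, 60, grid = g)
  expect_lt(abs(as.numeric(r) - 4 * sqrt(2 * log(43 / 23))), 0.05)
  # axisymmetric consistency: flipping the z axis changes nothing
  r_flip <- isotherm_radius(Tmat[, rev(seq_len(ncol(Tmat)))], 60,
                            grid = g)
  expect_equal(as.numeric(r), as.numeric(r_flip))
})

test_that("cold fields yield no lesion; bad thresholds error", {
  g <- axisymmetric_grid(r_extent = 10, z_extent = c(-10, 10),
                         spacing = 1)
  Tmat <- matrix(37, length(g$rc), length(g$zc))
  r <- isotherm_radius(Tmat, 60, grid = g)
  expect_equal(as.numeric(r), 0)
  expect_false(attr(r, "reached"))
  expect_error(isotherm_radius(Tmat, 30, grid = g), "parameter error")
})

test_that("plan composition is additive over trajectories", {
  plan1 <- trajectory_plan(c(0, 0, 40), c(0, 0, 0), 4L)
  e1 <- compose_plan(plan1, 5)
  expect_equal(e1$v_total, e1$v_eq1)
  expect_equal(e1$v_eq1, lesion_volume_eq1(5, 4))

  off <- rbind(c(0, 0, 40), c(15, 0, 40), c(30, 0, 40))
  tgt <- rbind(c(0, 0, 0), c(15, 0, 0), c(30, 0, 0))
  plan3 <- trajectory_plan(off, tgt, c(4L, 4L, 4L))
  e3 <- compose_plan(plan3, 5)
  expect_equal(e3$v_total, 3 * e1$v_total)

  expect_error(compose_plan(plan3, c(5, 5)), "consistency error")
})

test_that("rasterized solids converge to the geometric volume", {
  plan <- trajectory_plan(c(0, 0, 40), c(0, 0, 0), 2L)
  est <- compose_plan(plan, 5.4)
  m <- rasterize_lesion(est, plan, voxel_size = 0.2)
  v_vox <- sum(m$mask) * 0.2^3
  v_geo <- lesion_geometric_volume(5.4, 2)
  expect_lt(abs(v_vox - v_geo) / v_geo, 0.01)

  # two disjoint identical solids: exactly double the voxel count
  plan2 <- trajectory_plan(rbind(c(0, 0, 40), c(20, 0, 40)),
                           rbind(c(0, 0, 0), c(20, 0, 0)),
                           c(2L, 2L))
  m2 <- rasterize_lesion(compose_plan(plan2, 5.4), plan2,
                         voxel_size = 0.2)
  expect_equal(sum(m2$mask), 2 * sum(m$mask))

  # zero radius: empty volume; coarse voxels: degenerate warning
  m0 <- rasterize_lesion(compose_plan(plan, 0), plan, voxel_size = 1)
  expect_equal(sum(m0$mask), 0)
  expect_warning(rasterize_lesion(est, plan, voxel_size = 6),
                 "degenerate raster")
})

test_that("rasterization error stays inside a linear-in-h envelope", {
  # voxel-center counting has a surface error of order the voxel size;
  # it oscillates with lattice alignment, so assert the linear envelope
  # err <= 0.2 * h rather than monotone decay
  plan <- trajectory_plan(c(0, 0, 40), c(0, 0, 0), 3L)
  for (r in c(3, 4.5)) {
    est <- compose_plan(plan, r)
    v_geo <- lesion_geometric_volume(r, 3)
    for (h in c(1, 0.5, 0.25)) {
      err <- abs(sum(rasterize_lesion(est, plan, voxel_size = h)$mask) *
                   h^3 - v_geo) / v_geo
      expect_lt(err, 0.2 * h)
    }
  }
})
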