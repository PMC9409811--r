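# Synthetic phantom generator: label geometry, volume conservation,
# property lookup, determinism.

test_that("label volumes are conserved and regions paint in order", {
  ph <- build_layered_phantom(
    list(list(label = 2L, region = list(type = "all")),
         list(label = 1L, region = list(type = "slab", z = c(0, 30)))),
    spacing = 1, extent = list(r = 30, z = c(-30, 30)))
  vol <- cell_volumes(ph)
  # exact conservation: sum over labels equals the domain volume
  expect_equal(sum(vol[ph$labels == 1L]) + sum(vol[ph$labels == 2L]),
               pi * 30^2 * 60, tolerance = 1e-12)
  # later region overwrote the upper half
  expect_true(all(ph$labels[, ph$zc > 0] == 1L))
  expect_true(all(ph$labels[, ph$zc < 0] == 2L))
})

test_that("uniform grey phantom exposes the 100 kHz conductivity", {
  ph <- build_layered_phantom(
    list(list(label = 1L, region = list(type = "all"))),
    spacing = 2, extent = list(r = 20, z = c(-20, 20)))
  expect_true(all(ph$labels == 1L))
  sig <- rfablate:::property_field(ph, "sigma")
  expect_equal(unique(as.vector(sig)), 0.28)
})

test_that("degenerate one-cell grid takes the last region's label", {
  ph <- build_layered_phantom(
    list(list(label = 1L, region = list(type = "all")),
         list(label = 2L, region = list(type = "all"))),
    spacing = 200, extent = list(r = 50, z = c(-50, 50)))
  expect_identical(dim(ph$labels), c(1L, 1L))
  expect_identical(as.vector(ph$labels), 2L)
})

test_that("rasterized hippocampus sphere matches the analytic volume", {
  ph <- build_layered_phantom(
    list(list(label = 2L, region = list(type = "all")),
         list(label = 3L, region = list(type = "sphere", center = 0,
                                        radius = 10))),
    spacing = 0.5, extent = list(r = 30, z = c(-30, 30)))
  v <- sum(cell_volumes(ph)[ph$labels == 3L])
  expect_lt(abs(v - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.02)
  # same in cartesian mode
  ph3 <- build_layered_phantom(
    list(list(label = 2L, region = list(type = "all")),
         list(label = 3L, region = list(type = "sphere",
                                        center = c(0, 0, 0),
                                        radius = 10))),
    spacing = 0.5, extent = c(-15, 15), mode = "cartesian-3d")
  v3 <- sum(ph3$labels == 3L) * cell_volumes(ph3)
  expect_lt(abs(v3 - 4188.79) / 4188.79, 0.02)
})

test_that("phantom generation is deterministic and validates input", {
  spec <- list(list(label = 1L, region = list(type = "all")),
               list(label = 3L, region = list(type = "sphere",
                                              center = 5, radius = 8)))
  a <- build_layered_phantom(spec, 1, list(r = 25, z = c(-25, 25)))
  b <- build_layered_phantom(spec, 1, list(r = 25, z = c(-25, 25)))
  expect_identical(a$labels, b$labels)

  expect_error(build_layered_phantom(
    list(list(label = 99L, region = list(type = "all"))),
    1, list(r = 25, z = c(-25, 25))), "configuration error")
  expect_error(build_layered_phantom(
    list(list(label = 1L, region = list(type = "sphere", center = 0,
                                        radius = 100))),
    1, list(r = 25, z = c(-25, 25))), "geometry error")
  expect_error(build_layered_phantom(spec, -1,
                                     list(r = 25, z = c(-25, 25))),
               "spacing")
})

test_that("tissue table rejects unphysical values and unknown labels", {
  expect_error(tissue_properties("x", sigma = -1, k = 0.5, rho = 1000,
                                 c = 3600), "sigma")
  expect_error(brain_tissue_table(grey_matter = list(k = -2)), "k must")
  expect_error(brain_tissue_table(bogus_tissue = list(k = 1)),
               "unknown tissue label")
  tab <- brain_tissue_table(white_matter = list(sigma = 0.3))
  expect_equal(tab$sigma[tab$label_name == "white_matter"], 0.3)
  expect_equal(tab$sigma[tab$label_name == "grey_matter"], 0.28)
})
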