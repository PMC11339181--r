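test_that("Darcy-Forchheimer pressure drop evaluates the layer law", {
  expect_identical(pressure_drop(66.8, 170, 0), 0)
  expect_equal(pressure_drop(66.8, 170, 0.1), 8.38)
  expect_identical(pressure_drop(0, 0, 0.5), 0)
  expect_error(pressure_drop(66.8, 170, -0.1), "non-negative")
  expect_error(pressure_drop(-1, 170, 0.1), "non-negative")
})

test_that("pressure drop is strictly increasing in l_c, q_c and v", {
  v <- c(0.05, 0.1, 0.2, 0.4)
  for (lc in c(5, 50, 150)) {
    for (qc in c(100, 300)) {
      expect_true(all(diff(pressure_drop(lc, qc, v)) > 0))
      expect_lt(pressure_drop(lc, qc, 0.2), pressure_drop(lc + 1, qc, 0.2))
      expect_lt(pressure_drop(lc, qc, 0.2), pressure_drop(lc, qc + 1, 0.2))
    }
  }
})

test_that("HR coefficient fitting is the exact left inverse of the layer law", {
  v <- c(0.05, 0.1, 0.2, 0.4)
  cf <- fit_hr_coefficients(v, pressure_drop(100, 200, v))
  expect_equal(unname(cf["l_c"]), 100, tolerance = 1e-9)
  expect_equal(unname(cf["q_c"]), 200, tolerance = 1e-9)
  expect_identical(fit_hr_coefficients(v, rep(0, 4)), c(l_c = 0, q_c = 0))
  expect_error(fit_hr_coefficients(c(0.1, 0.2), c(1, 2)), "3 samples")
  expect_error(fit_hr_coefficients(rep(0.1, 4), rep(1, 4)), "identical")
})

test_that("the measured scenario table has the full 16-scenario structure", {
  hr <- hr_scenarios()
  expect_identical(nrow(hr), 16L)
  counts <- table(hr$device, hr$deployment)
  expect_identical(unname(counts["PED", "nominal"]), 4L)
  expect_identical(unname(counts["PED", "oversized"]), 4L)
  expect_identical(unname(counts["P64", "nominal"]), 3L)
  expect_identical(unname(counts["P64", "oversized"]), 5L)
  expect_equal(hr$l_c[hr$scenario_id == 1], 66.8)
  expect_equal(hr$q_c[hr$scenario_id == 1], 170)
  expect_true(all(hr$wire_count[hr$device == "PED"] == 48))
  expect_true(all(hr$wire_count[hr$device == "P64"] == 64))
  # oversizing opens the braid: much smaller linear resistance
  expect_lt(max(hr$l_c[hr$deployment == "oversized"]),
            min(hr$l_c[hr$deployment == "nominal"]))
})

test_that("stent-to-porous rasterization is deterministic and area-consistent", {
  grid <- fix_tube_grid()
  h <- grid$h
  rr <- expand.grid(y = seq(-1.5, 1.5, h / 2), z = seq(-1.5, 1.5, h / 2))
  rr <- rr[rr$y^2 + rr$z^2 <= 1.6^2, ]
  pts <- cbind(5, rr$y, rr$z)
  p1 <- map_stent_to_porous_voxels(pts, grid, 66.8, 170, t_layer = h)
  p2 <- map_stent_to_porous_voxels(pts, grid, 66.8, 170, t_layer = h)
  expect_identical(p1$voxels, p2$voxels)
  # one-voxel disc across the lumen: count ~ pi r^2 h / h^3
  expect_equal(length(p1$voxels), pi * 1.5^2 / h^2, tolerance = 0.1 * pi * 1.5^2 / h^2)
  expect_equal(p1$alpha, 66.8 / (h * 1e-3))
  expect_equal(p1$beta, 170 / (h * 1e-3))
  expect_error(map_stent_to_porous_voxels(pts, grid, 66.8, 170, t_layer = 0),
               "positive")
  far <- cbind(100, rr$y, rr$z)
  expect_error(map_stent_to_porous_voxels(far, grid, 66.8, 170), "fluid region")
})
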