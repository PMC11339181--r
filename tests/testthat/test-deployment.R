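test_that("braid construction validates inputs and scales with wire count", {
  expect_error(build_braid(7, 4, 20, 75), "even")
  expect_error(build_braid(6, 4, 20, 75), "at least 8")
  expect_error(build_braid(48, 4, 20, 95), "braid_angle")
  n48 <- build_braid(48, 4, 20, 75)
  n64 <- build_braid(64, 4, 20, 75)
  expect_gt(nrow(n64$pos), nrow(n48$pos))
  # regular diamond braid: interior nodes have 4 surface-spring neighbours
  deg <- tabulate(as.vector(n48$springs), nbins = nrow(n48$pos))
  interior <- n48$row > 0 & n48$row < n48$n_z - 1
  expect_true(all(deg[interior] == 4))
  expect_true(all(n48$l0 > 0))
})

test_that("free-space deployment recovers the nominal device dimensions", {
  net <- build_braid(48, 4, 10, 75)
  st <- deploy(net, vessel = NULL)
  expect_equal(st$deployed_length, 10, tolerance = 0.01)
  expect_equal(mean(st$diameter_profile), 4, tolerance = 0.01)
})

test_that("nominal deployment matches the vessel, oversizing elongates", {
  net <- build_braid(48, 4, 10, 75)
  st <- deploy(net, vessel = list(diameter = 4, length = 30))
  expect_equal(st$deployed_length, 10, tolerance = 0.02)
  expect_equal(mean(st$diameter_profile), 4, tolerance = 0.02)
  net5 <- build_braid(64, 5, 10, 75)
  st5 <- deploy(net5, vessel = list(diameter = 4, length = 40))
  expect_equal(mean(st5$diameter_profile), 4, tolerance = 0.02)
  expect_gt(st5$deployed_length, 10)      # foreshortening reciprocity
  # contact: no node outside the lumen beyond tolerance
  r <- sqrt(st5$node_positions[, 2]^2 + st5$node_positions[, 3]^2)
  expect_lt(max(r), 2 + 1e-6)
})

test_that("deployment rejects incompatible vessels", {
  net <- build_braid(48, 4, 10, 75)
  expect_error(deploy(net, vessel = list(diameter = 1.5, length = 30)), "narrow")
  expect_error(deploy(net, vessel = list(diameter = 7, length = 30)), "wide")
})

test_that("elastic energy is non-increasing during free relaxation", {
  net <- build_braid(48, 4, 10, 75)
  st <- deploy(net, vessel = NULL)
  e <- st$energy
  expect_true(all(diff(e) <= 1e-9 * max(e, 1e-12)))
})

test_that("stiffness calibration inverts the tensile forward model", {
  net <- fix_small_braid()
  e <- c(0.5, 1, 2, 3, 4)
  td <- simulate_tensile(net, e, k_s = 2, k_r = 0.1)
  expect_true(all(diff(td$force_n) > 0))
  cal <- calibrate_stiffness(net, td)
  expect_equal(unname(cal["k_s"]), 2, tolerance = 0.01)
  expect_equal(unname(cal["k_r"]), 0.1, tolerance = 0.01)
})

test_that("calibration tolerates measurement noise", {
  net <- fix_small_braid()
  e <- c(0.5, 1, 2, 3, 4)
  td <- simulate_tensile(net, e, k_s = 2, k_r = 0.1)
  set.seed(42)
  td$force_n <- td$force_n * (1 + rnorm(length(e), sd = 0.05))
  cal <- calibrate_stiffness(net, td)
  expect_equal(unname(cal["k_s"]), 2, tolerance = 0.1)
  expect_equal(unname(cal["k_r"]), 0.1, tolerance = 0.1)
})

test_that("calibration rejects degenerate sample sets", {
  net <- fix_small_braid()
  expect_error(calibrate_stiffness(net, cbind(c(1, 2), c(0.1, 0.2))), "3")
  expect_error(calibrate_stiffness(net, cbind(c(1, 2, 3), c(0, 0, 0))),
               "degenerate")
})

test_that("metallic surface area follows wire count and deployment state", {
  st48 <- deploy(build_braid(48, 4, 10, 75), vessel = list(diameter = 4, length = 30))
  st64 <- deploy(build_braid(64, 4, 10, 75), vessel = list(diameter = 4, length = 30))
  sto <- deploy(build_braid(64, 5, 10, 75), vessel = list(diameter = 4, length = 40))
  expect_identical(metallic_surface_area(st48, wire_diameter = 0), 0)
  msa48 <- metallic_surface_area(st48)
  msa64 <- metallic_surface_area(st64)
  msao <- metallic_surface_area(sto)
  expect_gt(msa64, msa48)               # more wires cover more surface
  expect_lt(msao, msa64)                # oversizing opens the braid
  expect_true(msa48 > 0 && msa64 <= 1)
})
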