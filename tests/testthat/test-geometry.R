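test_that("sidewall generator validates its parameters", {
  expect_error(make_sidewall_aneurysm(4, 8, 9, 40), "neck_diameter")
  expect_error(make_sidewall_aneurysm(-4, 8, 4, 40), "positive")
  expect_error(make_sidewall_aneurysm(4, 8, 4, 0), "positive")
  expect_error(make_sidewall_aneurysm(4, 0, 2, 40), "neck_diameter")
  expect_error(make_sidewall_aneurysm(4, 8, 0, 40), "neck_diameter")
  expect_error(make_sidewall_aneurysm(4, 8, 4, 40, bend_radius = 5), "bend_radius")
})

test_that("sidewall geometry is closed, labeled, and carries the neck plane", {
  g <- fix_sidewall()
  expect_true(check_watertight(g))
  labs <- vapply(g$openings, `[[`, "", "label")
  expect_identical(sum(labs == "inlet"), 1L)
  expect_true(any(grepl("^outlet", labs)))
  expect_true(all(vapply(g$openings, `[[`, 0, "diameter") > 0))
  pl <- g$metadata$ostium_plane
  expect_equal(sqrt(sum(pl$normal^2)), 1, tolerance = 1e-12)
  # normal points from the parent lumen into the sac
  expect_gt(sum((g$metadata$sac_center - pl$point) * pl$normal), 0)
})

test_that("degenerate no-sac case gives a plain straight tube", {
  g <- make_sidewall_aneurysm(4, 0, 0, 40)
  expect_true(check_watertight(g))
  expect_null(g$metadata$ostium_plane)
  expect_length(g$openings, 2)
})

# area of a disc of radius rho intersected with the centred strip |y| <= w
disc_strip_overlap <- function(rho, w) {
  if (w <= 0) return(0)
  if (w >= rho) return(pi * rho^2)
  2 * (w * sqrt(rho^2 - w^2) + rho^2 * asin(w / rho))
}

test_that("voxelized sac volume matches the analytic sphere-cylinder union", {
  g <- fix_sidewall()
  grid <- voxelize(g, 0.2)
  sac <- detect_ostium_plane(g, grid)
  # the sac mask counts voxels inside the sphere, above the neck plane and
  # outside the parent cylinder: integrate sphere sections minus their
  # overlap with the cylinder's strip cross-section over height z
  r_s <- 4; r_p <- 2
  zc <- g$metadata$sac_center[3]
  f <- function(z) {
    rho2 <- r_s^2 - (z - zc)^2
    if (rho2 <= 0) return(0)
    w <- sqrt(max(r_p^2 - z^2, 0))
    pi * rho2 - disc_strip_overlap(sqrt(rho2), w)
  }
  vol_ana <- integrate(Vectorize(f), 0, zc + r_s, subdivisions = 400)$value
  vol_vox <- length(sac$mask) * 0.2^3
  expect_equal(vol_vox, vol_ana, tolerance = 0.05)
})

test_that("opening extensions scale with the local diameter and preserve area", {
  g <- make_bifurcation(4, 3, 2, trunk_length = 8, branch_length = 6)
  gx <- extend_openings(g, 5)
  for (k in seq_along(g$openings)) {
    shift <- sqrt(sum((gx$openings[[k]]$centroid - g$openings[[k]]$centroid)^2))
    expect_equal(shift, 5 * g$openings[[k]]$diameter, tolerance = 1e-9)
    expect_identical(gx$openings[[k]]$label, g$openings[[k]]$label)
  }
  # identity at zero diameters
  expect_identical(extend_openings(g, 0), g)
  # cross-sectional area of each opening unchanged (within one voxel layer)
  grid <- voxelize(extend_openings(fix_sidewall(), 2), 0.25)
  for (k in seq_len(nrow(grid$openings))) {
    n_cap <- sum(grid$labels == grid$openings$code[k])
    a_true <- pi * (grid$openings$diameter[k] / 2)^2 / 0.25^2
    expect_lt(abs(n_cap - a_true) / a_true, 0.2)
  }
})

test_that("voxelization converges to the analytic volume and is deterministic", {
  sph <- stentflow:::tessellate_sphere(c(0, 0, 0), 2, 64, 32)
  g <- structure(list(vertices = sph$vertices, triangles = sph$triangles,
                      component = rep(1L, nrow(sph$triangles)),
                      openings = list(), metadata = list()),
                 class = "surface_geometry")
  v_true <- 4 / 3 * pi * 8
  errs <- vapply(c(0.4, 0.2, 0.1), function(h) {
    v <- sum(voxelize(g, h)$labels != 0L) * h^3
    abs(v - v_true) / v_true
  }, 0)
  expect_lt(errs[3], 0.05)          # 5% at h = 0.1 on a 2-mm-radius sphere
  expect_true(all(diff(errs) < 0))  # first-order shrinkage with h
  g2 <- fix_sidewall()
  expect_identical(voxelize(g2, 0.4)$labels, voxelize(g2, 0.4)$labels)
  expect_error(voxelize(g2, 0), "positive")
})

test_that("too-coarse voxelization is rejected with a diagnostic", {
  g <- make_bifurcation(3, 1.2, 1.2, trunk_length = 8, branch_length = 8)
  expect_error(voxelize(g, 1.2), "coarse|connectivity")
})

test_that("curved parents voxelize and keep their openings", {
  g <- make_sidewall_aneurysm(4, 8, 4, 30, bend_radius = 30)
  expect_true(check_watertight(g))
  grid <- voxelize(g, 0.3)
  expect_gt(sum(grid$labels == 1L), 0)
  expect_identical(nrow(grid$openings), 2L)
})
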