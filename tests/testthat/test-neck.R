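test_that("parametric geometries pass their analytic neck plane through", {
  g <- fix_sidewall()
  grid <- voxelize(g, 0.3)
  sac <- detect_ostium_plane(g, grid)
  expect_true(sac$analytic)
  expect_identical(sac$plane, g$metadata$ostium_plane)
  expect_gt(length(sac$mask), 0)
})

test_that("geometric fallback recovers the neck plane of a sphere-on-tube", {
  for (dims in list(c(4, 8, 3), c(3, 6, 2.5))) {
    g <- make_sidewall_aneurysm(dims[1], dims[2], dims[3], 30)
    grid <- voxelize(g, 0.25)
    g_blank <- g; g_blank$metadata <- list()
    sac <- detect_ostium_plane(g_blank, grid)
    expect_false(sac$analytic)
    pl <- g$metadata$ostium_plane
    angle <- acos(min(1, abs(sum(sac$plane$normal * pl$normal)))) * 180 / pi
    offset <- abs(sum((sac$plane$point - pl$point) * pl$normal))
    expect_lt(angle, 5)
    expect_lt(offset, grid$h)           # within one voxel
  }
})

test_that("neck detection refuses a sac-free vessel", {
  g <- make_sidewall_aneurysm(4, 0, 0, 20)
  grid <- voxelize(g, 0.3)
  g$metadata <- list()
  expect_error(detect_ostium_plane(g, grid), "no sac")
})

test_that("STAV averages speed over sac voxels and instants", {
  g <- fix_sidewall()
  grid <- voxelize(g, 0.4)
  sac <- detect_ostium_plane(g, grid)
  lin <- which(grid$labels != 0L)
  n <- length(lin)
  mk_flow <- function(u_list) {
    structure(list(u = u_list, lin = lin, cycle_avg_speed = NULL),
              class = "flow_field")
  }
  u1 <- matrix(1 / sqrt(3), n, 3)       # uniform |u| = 1
  expect_equal(stav(mk_flow(list(u1)), sac), 1, tolerance = 1e-12)
  u0 <- matrix(0, n, 3)
  expect_equal(stav(mk_flow(list(u0, 2 * u1)), sac), 1, tolerance = 1e-12)
  # brute-force oracle on a random field, and invariance to instant order
  set.seed(42)
  us <- replicate(3, matrix(rnorm(n * 3), n, 3), simplify = FALSE)
  idx <- match(sac$mask, lin)
  brute <- mean(sapply(us, function(m) mean(sqrt(rowSums(m[idx, ]^2)))))
  expect_equal(stav(mk_flow(us), sac), brute, tolerance = 1e-12)
  expect_equal(stav(mk_flow(rev(us)), sac), brute, tolerance = 1e-12)
  empty <- sac; empty$mask <- integer(0)
  expect_error(stav(mk_flow(us), empty), "empty")
})

test_that("AMVR is the relative STAV reduction", {
  expect_equal(amvr(0.10, 0.04), 0.6)
  expect_identical(amvr(0.2, 0.2), 0)
  expect_identical(amvr(0.10, 0), 1)
  expect_error(amvr(0, 0.1), "positive")
  expect_warning(a <- amvr(0.1, 0.12), "negative")
  expect_lt(a, 0)
})
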