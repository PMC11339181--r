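test_that("Murray's law splits flow by the cube of the diameter", {
  expect_equal(murray_outlet_split(c(2, 2)), c(0.5, 0.5))
  expect_equal(murray_outlet_split(c(1, 2)), c(1, 8) / 9)
  expect_identical(murray_outlet_split(3), 1)
  expect_error(murray_outlet_split(numeric(0)), "no outlet")
  expect_error(murray_outlet_split(c(2, -1)), "positive")
})

test_that("area-based inlet velocity follows the flow power law", {
  expect_equal(inlet_mean_velocity_from_area(10, a = 0.3, b = 1), 0.3)
  q1 <- inlet_mean_velocity_from_area(10, a = 1, b = 1.5) * 10
  q2 <- inlet_mean_velocity_from_area(20, a = 1, b = 1.5) * 20
  expect_equal(q2 / q1, 2^1.5)
  expect_error(inlet_mean_velocity_from_area(0), "positive")
  # documented stand-in: ~0.25 m/s on a 4-mm inlet
  expect_equal(inlet_mean_velocity_from_area(pi * 4), 0.25, tolerance = 0.01)
})

test_that("lattice unit conversion respects the stability window", {
  un <- lbm_units(0.1, fluid_props(), u_peak = 0.03)
  expect_gte(un$tau, 0.55); expect_lte(un$tau, 1.2)
  # reference-resolution time step is of order 1e-4 s
  expect_gt(un$dt, 1e-5); expect_lt(un$dt, 1e-3)
  expect_error(lbm_units(0.1, fluid_props(), u_peak = 0.5), "infeasible")
})

test_that("the shipped inflow waveform has unit cycle mean and ~1.8x peak", {
  wf <- waveform_spec(v_mean = 0.25)
  tg <- seq(0, 1, length.out = 2001)[-2001]
  expect_equal(mean(wf$w(tg)), 1, tolerance = 1e-6)
  expect_equal(wf$w_max, 1.8, tolerance = 0.05)
  expect_equal(wf$w(0.3), wf$w(1.3))    # periodic
})

test_that("steady tube flow reproduces the Poiseuille parabola", {
  grid <- fix_tube_grid()
  v <- 0.01
  fl <- run_steady(grid, v_mean = v)
  expect_true(fl$converged)
  ctr <- voxel_centers(grid, fl$lin)
  mid <- abs(ctr[, 1] - 5) < grid$h / 2 * 1.01
  r <- sqrt(ctr[mid, 2]^2 + ctr[mid, 3]^2)
  u_ana <- 2 * v * (1 - (r / 1.5)^2)
  err <- abs(fl$u[[1]][mid, 1] - u_ana) / (2 * v)
  expect_lt(max(err), 0.02)
  expect_equal(max(fl$u[[1]][mid, 1]), 2 * v, tolerance = 0.02)
  expect_lt(mass_conservation_error(fl), 0.01)
  expect_identical(length(fl$u), 1L)
})

test_that("zero inflow produces a zero field", {
  grid <- fix_tube_grid()
  fl <- run_steady(grid, v_mean = 0)
  expect_identical(max(abs(fl$u[[1]])), 0)
})

test_that("outlet fluxes realize the Murray fractions on a bifurcation", {
  g <- extend_openings(make_bifurcation(4, 3, 2.4, trunk_length = 10,
                                        branch_length = 8), 2)
  grid <- voxelize(g, 0.2)
  fl <- run_steady(grid, v_mean = 0.01)
  fr <- fl$fluxes[2:3] / sum(fl$fluxes[2:3])
  target <- murray_outlet_split(c(3, 2.4))
  expect_lt(max(abs(fr - target)), 0.02)
  expect_lt(mass_conservation_error(fl), 0.01)
})

test_that("pulsatile flow exports 50 instants and conserves mass throughout", {
  grid <- voxelize(make_sidewall_aneurysm(4, 0, 0, 8), 0.25)
  wf <- waveform_spec(v_mean = 0.004, period = 16)
  fl <- run_pulsatile(grid, wf = wf, warmup_cycles = 1)
  expect_identical(length(fl$u), 50L)
  expect_true(all(mass_conservation_error(fl) < 0.01))
  # inlet flux tracks the waveform over the cycle
  q_in <- -fl$fluxes[, 1]
  expect_equal(max(q_in) / mean(q_in), wf$w_max, tolerance = 0.1)
})

test_that("the cycle-mean of low-Womersley pulsatile flow is quasi-steady", {
  g <- make_sidewall_aneurysm(3, 5, 2.5, 16)
  gx <- extend_openings(g, 2)
  grid <- voxelize(gx, 0.25)
  sac <- detect_ostium_plane(g, grid)
  wf <- waveform_spec(v_mean = 0.006, period = 8)
  fp <- run_pulsatile(grid, wf = wf, warmup_cycles = 2)
  fs <- run_steady(grid, v_mean = 0.006)
  expect_equal(stav(fp, sac), stav(fs, sac), tolerance = 0.1)
})

test_that("sac velocity is grid-converged at the working resolutions", {
  g <- make_sidewall_aneurysm(3, 5, 2.5, 16)
  gx <- extend_openings(g, 2)
  stav_at <- function(h) {
    grid <- voxelize(gx, h)
    stav(run_steady(grid, v_mean = 0.005), detect_ostium_plane(g, grid))
  }
  s2 <- stav_at(0.2)
  s1 <- stav_at(0.1)
  expect_lt(abs(s1 - s2) / s1, 0.05)
})
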