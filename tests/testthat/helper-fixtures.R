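# Shared fixtures, built once per test session and cached.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# reference sidewall aneurysm (parent 4 mm, sac 8 mm, neck 4 mm)
fix_sidewall <- function() fixture("sidewall", function() {
  make_sidewall_aneurysm(4, 8, 4, 30)
})

# straight tube for Poiseuille-type checks
fix_tube_grid <- function() fixture("tube_grid", function() {
  voxelize(make_sidewall_aneurysm(3, 0, 0, 10), 0.2)
})

# small braid for calibration tests
fix_small_braid <- function() fixture("small_braid", function() {
  build_braid(16, 4, 8, 60)
})

# fast-mode study across all 16 scenarios on the reference geometry;
# this is the package's scaled-down analogue of the full simulation study
fix_study <- function() fixture("study", function() {
  run_study(list(G1 = fix_sidewall()), scenarios = hr_scenarios(),
            config = study_fast_config(), progress = FALSE)
})

# steady solve on the study grid with a zero-resistance porous layer,
# plus the matching pretreatment STAV (for the zero-resistance identity)
fix_zero_resistance <- function() fixture("zero_res", function() {
  g <- fix_sidewall()
  gx <- extend_openings(g, 3)
  grid <- voxelize(gx, 0.3)
  sac <- detect_ostium_plane(g, grid)
  pre <- run_steady(grid, NULL, v_mean = 0.005)
  stent <- stentflow:::deploy_for_geometry(g)
  por0 <- map_stent_to_porous_voxels(stent, grid, 0, 0)
  fl0 <- run_steady(grid, por0, v_mean = 0.005, init = pre)
  list(stav_pre = stav(pre, sac), stav_zero = stav(fl0, sac),
       pre = pre, grid = grid, sac = sac)
})
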