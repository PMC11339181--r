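#' Fast-mode study configuration
#'
#' Desk-scale defaults for study-sized batches of simulations: coarse
#' resolution, shortened opening extensions, steady cycle-mean inflow at a
#' reduced (creeping-flow) velocity that keeps the lattice operating point
#' inside the stable relaxation window at this resolution. The AMVR endpoint
#' is a velocity ratio and is governed by the resistance of the porous
#' layer, which this regime preserves.
#'
#' @param h voxel spacing, mm.
#' @param n_extend opening extension length in local diameters.
#' @param v_mean steady mean inlet velocity, m/s.
#' @param conv_tol steady-state residual tolerance.
#' @param max_steps iteration cap per solve.
#' @return a named list of settings consumed by [run_study()].
#' @export
study_fast_config <- function(h = 0.3, n_extend = 3, v_mean = 0.005,
                              conv_tol = 1e-6, max_steps = 40000L) {
  list(h = h, n_extend = n_extend, v_mean = v_mean, conv_tol = conv_tol,
       max_steps = max_steps)
}

#' Run the deployment-scenario simulation study
#'
#' For each geometry: voxelizes the vessel, runs one pretreatment flow
#' simulation, deploys a braided stent across the neck, converts it to a
#' porous layer, and re-runs the flow once per hydrodynamic-resistance
#' scenario; AMVR is computed against the pretreatment STAV. Posttreatment
#' solves warm-start from the previous converged field.
#'
#' @param geometries a named list of [surface_geometry] objects (names become
#'   geometry ids), or a single geometry.
#' @param scenarios an [hr_scenarios] table.
#' @param config settings list, see [study_fast_config()].
#' @param fluid a [fluid_props].
#' @param progress print per-run progress.
#' @return a `data.frame` of class `study_result`: one row per
#'   (geometry, scenario) plus one pretreatment row per geometry, with
#'   columns `geometry_id, scenario_id, device, wire_count, deployment,
#'   l_c, q_c, stav_pre, stav_fd, amvr, mass_err`.
#' @export
run_study <- function(geometries, scenarios = hr_scenarios(),
                      config = study_fast_config(), fluid = fluid_props(),
                      progress = interactive()) {
  if (inherits(geometries, "surface_geometry")) geometries <- list(G1 = geometries)
  if (is.null(names(geometries))) names(geometries) <- paste0("G", seq_along(geometries))
  rows <- list()
  for (gid in names(geometries)) {
    g <- geometries[[gid]]
    gext <- extend_openings(g, config$n_extend)
    grid <- voxelize(gext, config$h)
    sac <- detect_ostium_plane(g, grid)
    if (progress) message(gid, ": ", sum(grid$labels == 1L), " fluid voxels, ",
                          length(sac$mask), " sac voxels")
    pre <- run_steady(grid, NULL, fluid, v_mean = config$v_mean,
                      conv_tol = config$conv_tol, max_steps = config$max_steps)
    stav_pre <- stav(pre, sac)
    rows[[length(rows) + 1]] <- data.frame(
      geometry_id = gid, scenario_id = NA_integer_, device = NA_character_,
      wire_count = NA_integer_, deployment = "pretreatment", l_c = 0, q_c = 0,
      stav_pre = stav_pre, stav_fd = stav_pre, amvr = 0,
      mass_err = max(mass_conservation_error(pre)))
    # one representative deployment per geometry; scenario differences enter
    # through the measured (l_c, q_c) of the homogeneous layer
    stent <- deploy_for_geometry(g)
    prev <- pre
    for (si in seq_len(nrow(scenarios))) {
      sc <- scenarios[si, ]
      porous <- map_stent_to_porous_voxels(stent, grid, sc$l_c, sc$q_c)
      flow <- run_steady(grid, porous, fluid, v_mean = config$v_mean,
                         conv_tol = config$conv_tol,
                         max_steps = config$max_steps, init = prev)
      stav_fd <- stav(flow, sac)
      a <- amvr(stav_pre, stav_fd)
      if (progress) message(sprintf("  scenario %d (%s %s, l_c=%.1f): AMVR = %.3f",
                                    sc$scenario_id, sc$device, sc$deployment,
                                    sc$l_c, a))
      rows[[length(rows) + 1]] <- data.frame(
        geometry_id = gid, scenario_id = sc$scenario_id, device = sc$device,
        wire_count = sc$wire_count, deployment = sc$deployment,
        l_c = sc$l_c, q_c = sc$q_c, stav_pre = stav_pre, stav_fd = stav_fd,
        amvr = a, mass_err = max(mass_conservation_error(flow)))
      prev <- flow
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("study_result", "data.frame")
  out
}

# braid sized to span the neck with a comfortable landing zone
deploy_for_geometry <- function(g, n_wires = 48) {
  meta <- g$metadata
  land <- min(meta$parent_length * 0.8,
              (meta$neck_diameter %||% 4) + 10)
  net <- build_braid(n_wires, meta$parent_diameter, land)
  deploy(net, vessel = list(diameter = meta$parent_diameter,
                            length = meta$parent_length))
}

#' Summarize a study: power-law fit, group statistics, endpoint rates
#'
#' @param results a [run_study()] result.
#' @param threshold AMVR endpoint threshold (fraction).
#' @return list with `power_law` ([fit_power_law()] on the posttreatment
#'   runs), `groups` ([group_stats()]) and `endpoint`
#'   ([threshold_classification()]).
#' @export
study_report <- function(results, threshold = 0.35) {
  post <- results[results$deployment %in% c("nominal", "oversized"), ]
  list(power_law = fit_power_law(post$l_c, post$amvr),
       groups = group_stats(post),
       endpoint = threshold_classification(post, threshold))
}
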