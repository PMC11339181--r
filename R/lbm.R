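#' Blood fluid properties
#'
#' @param density fluid density (kg/m^3); default 1055 (whole blood).
#' @param viscosity dynamic viscosity (Pa s); default 3.4e-3 (Newtonian blood).
#' @return object of class `fluid_props`.
#' @export
fluid_props <- function(density = 1055, viscosity = 3.4e-3) {
  if (density <= 0 || viscosity <= 0) stop("density and viscosity must be positive")
  structure(list(density = density, viscosity = viscosity), class = "fluid_props")
}

#' Murray's-law outflow split
#'
#' Physiological outflow partitioning: each outlet receives flow in
#' proportion to the cube of its diameter.
#'
#' @param outlet_diameters outlet diameters (mm), all positive.
#' @return flow fractions summing to 1.
#' @examples
#' murray_outlet_split(c(1, 2))  # 1/9, 8/9
#' @export
murray_outlet_split <- function(outlet_diameters) {
  if (length(outlet_diameters) == 0) stop("no outlet diameters given")
  if (any(outlet_diameters <= 0)) stop("diameters must be positive")
  d3 <- outlet_diameters^3
  d3 / sum(d3)
}

#' Area-based mean inlet velocity
#'
#' Scales the inlet flow rate with the inlet cross-sectional area through the
#' power law `Q = a * A^b` and returns the mean velocity `Q/A`. The default
#' coefficients are a documented stand-in calibrated so that a 4-mm circular
#' inlet receives ~0.25 m/s; they are configurable.
#'
#' @param area inlet area in mm^2 (positive).
#' @param a flow-rate coefficient (SI; m^3/s at A = 1 m^2).
#' @param b area exponent.
#' @return mean inlet velocity (m/s).
#' @export
inlet_mean_velocity_from_area <- function(area, a = 3267, b = 1.84) {
  if (area <= 0) stop("inlet area must be positive")
  A <- area * 1e-6                      # mm^2 -> m^2
  (a * A^b) / A
}

#' Normalized periodic inflow waveform
#'
#' A carotid-like pulsatile waveform with unit cycle mean: the shipped
#' fixture is a 3-harmonic truncated Fourier series with a systolic peak of
#' about 1.8x the mean, sampled over one unit cycle and renormalized
#' numerically so its cycle mean is 1 within 1e-6. Any two-column CSV
#' (`t_frac`, `w`) over one cycle can be substituted.
#'
#' @param v_mean target cycle-mean inlet velocity (m/s).
#' @param period cycle period T in seconds (default 1).
#' @param file optional waveform CSV; default the packaged fixture.
#' @return object of class `waveform_spec` with fields `period`, `v_mean`,
#'   `w` (vectorized periodic function of time in seconds) and `w_max`.
#' @export
waveform_spec <- function(v_mean, period = 1, file = NULL) {
  if (v_mean <= 0 || period <= 0) stop("v_mean and period must be positive")
  if (is.null(file)) {
    file <- system.file("extdata", "ica_waveform.csv", package = "stentflow",
                        mustWork = TRUE)
  }
  tab <- read.csv(file)
  if (!all(c("t_frac", "w") %in% names(tab))) stop("waveform CSV needs t_frac, w")
  tf <- tab$t_frac; w <- tab$w
  w <- w / mean(w)                      # enforce unit cycle mean
  wfun <- function(t) {
    x <- (t / period) %% 1
    approx(c(tf, 1), c(w, w[1]), xout = x, rule = 2)$y
  }
  structure(list(period = period, v_mean = v_mean, w = wfun, w_max = max(w),
                 samples = data.frame(t_frac = tf, w = w)),
            class = "waveform_spec")
}

#' Lattice unit conversion
#'
#' Chooses the physical time step for a given spacing so that the peak
#' lattice velocity stays below the Mach limit while the BGK relaxation time
#' remains inside the stable window. The largest admissible time step is
#' taken (largest tau), clamped to `tau_max`; if the Mach limit forces tau
#' below `tau_min` the operating point is infeasible at this resolution.
#'
#' @param h voxel spacing (mm).
#' @param fluid a [fluid_props].
#' @param u_peak expected peak physical velocity (m/s).
#' @param tau_min,tau_max admissible BGK relaxation-time window.
#' @param mach_limit maximum lattice Mach number (|u|_lb / c_s).
#' @return list with `h_m`, `dt` (s), `tau`, `nu_lb`, `u_scale` (m/s per
#'   lattice unit), `mach_limit`.
#' @export
lbm_units <- function(h, fluid = fluid_props(), u_peak,
                      tau_min = 0.55, tau_max = 1.2, mach_limit = 0.1) {
  if (h <= 0 || u_peak <= 0) stop("h and u_peak must be positive")
  h_m <- h * 1e-3
  nu <- fluid$viscosity / fluid$density
  u_lb_max <- mach_limit / sqrt(3)
  dt <- u_lb_max * h_m / u_peak         # largest dt allowed by the Mach limit
  tau <- 0.5 + 3 * nu * dt / h_m^2
  if (tau > tau_max) {                  # viscosity-limited: shrink dt
    dt <- (tau_max - 0.5) / 3 * h_m^2 / nu
    tau <- tau_max
  }
  if (tau < tau_min - 1e-9) {
    stop(sprintf(paste0("infeasible lattice operating point: tau = %.3f < %.2f ",
                        "at h = %g mm, u_peak = %g m/s; refine the resolution ",
                        "or lower the inflow velocity"), tau, tau_min, h, u_peak))
  }
  list(h_m = h_m, dt = dt, tau = tau, nu_lb = (tau - 0.5) / 3,
       u_scale = h_m / dt, mach_limit = mach_limit)
}

# ---- node assembly -------------------------------------------------------

# D3Q19 stencil (must match the C++ kernel)
d3q19_e <- function() {
  cbind(c(0, 1,-1, 0, 0, 0, 0, 1,-1, 1,-1, 1,-1, 1,-1, 0, 0, 0, 0),
        c(0, 0, 0, 1,-1, 0, 0, 1,-1,-1, 1, 0, 0, 0, 0, 1,-1, 1,-1),
        c(0, 0, 0, 0, 0, 1,-1, 0, 0, 0, 0, 1,-1,-1, 1, 1,-1,-1, 1))
}

build_lbm_nodes <- function(grid, porous = NULL) {
  dims <- dim(grid$labels)
  lin <- which(grid$labels != 0L)
  n <- length(lin)
  ids <- integer(prod(dims)); ids[lin] <- seq_len(n)
  ijk <- arrayInd(lin, dims)
  e <- d3q19_e()
  neigh <- matrix(-1L, n, 19)
  for (q in 1:19) {
    i2 <- ijk[, 1] - e[q, 1]; j2 <- ijk[, 2] - e[q, 2]; k2 <- ijk[, 3] - e[q, 3]
    ok <- i2 >= 1 & i2 <= dims[1] & j2 >= 1 & j2 <= dims[2] & k2 >= 1 & k2 <= dims[3]
    lin2 <- i2[ok] + dims[1] * (j2[ok] - 1) + dims[1] * dims[2] * (k2[ok] - 1)
    val <- ids[lin2]
    col <- rep(-1L, n); col[ok] <- val - 1L   # -1 where neighbor is solid
    neigh[, q] <- col
  }
  node_type <- integer(n)                      # 0 interior
  labs <- grid$labels[lin]
  node_type[labs == 2L] <- 2L                  # inlet
  if (!is.null(grid$openings)) {
    outs <- grid$openings[grid$openings$label != "inlet", , drop = FALSE]
    if (nrow(outs) > 0) {
      smallest <- outs$code[which.min(outs$diameter)]
      for (code in outs$code) {
        node_type[labs == code] <- if (code == smallest) 4L else 3L
      }
    }
  }
  # interior reference neighbor of each boundary-cap node: the most
  # inward-pointing lattice direction with a plain-fluid neighbor
  bc_ref <- rep(-1L, n)
  opp1 <- c(1L, 3L,2L, 5L,4L, 7L,6L, 9L,8L, 11L,10L, 13L,12L, 15L,14L,
            17L,16L, 19L,18L)
  if (!is.null(grid$openings)) {
    for (k in seq_len(nrow(grid$openings))) {
      op <- grid$openings[k, ]
      sel <- which(labs == op$code)
      if (length(sel) == 0) next
      score <- as.vector(e %*% (-c(op$nx, op$ny, op$nz)))
      for (q in order(score, decreasing = TRUE)[1:6]) {
        cand <- neigh[sel, opp1[q]]       # neighbor at x + e_q (inward-most)
        ok <- bc_ref[sel] < 0L & cand >= 0L
        ok[ok] <- labs[cand[ok] + 1L] == 1L
        bc_ref[sel][ok] <- cand[ok]
      }
    }
  }
  alpha <- numeric(n); beta <- numeric(n)
  if (!is.null(porous)) {
    pid <- ids[porous$voxels]
    pid <- pid[pid > 0]
    interior <- node_type[pid] == 0L           # caps keep their BC role
    pid <- pid[interior]
    node_type[pid] <- 1L
    alpha[pid] <- porous$alpha
    beta[pid] <- porous$beta
  }
  centers <- voxel_centers(grid, lin)
  # sub-voxel wall positions for interpolated bounce-back
  link_frac <- NULL
  if (!is.null(grid$mesh)) {
    e_int <- e; storage.mode(e_int) <- "integer"
    link_frac <- cpp_link_fractions(grid$mesh$vertices, grid$mesh$triangles - 1L,
                                    grid$origin, grid$h, dims, centers, neigh,
                                    e_int)
  }
  list(lin = lin, n = n, ids = ids, neigh = neigh, node_type = node_type,
       bc_ref = bc_ref, alpha = alpha, beta = beta, link_frac = link_frac,
       centers = centers, labs = labs, dims = dims)
}

# parabolic cap profile carrying volume flux v_mean * pi R^2, pointing inward
cap_profile <- function(centers, sel, opening, v_mean, h) {
  nrm <- c(opening$nx, opening$ny, opening$nz)
  ctr <- c(opening$cx, opening$cy, opening$cz)
  rel <- sweep(centers[sel, , drop = FALSE], 2, ctr, "-")
  s <- rel %*% nrm
  lat2 <- pmax(0, rowSums(rel^2) - s^2)
  R <- opening$diameter / 2
  p <- pmax(0, 1 - lat2 / R^2)
  if (mean(p) <= 0) p <- rep(1, length(p))
  # normalize the discrete profile so the volume flux equals v_mean times the
  # true cap area (the voxelized cap area differs from pi R^2 at O(h))
  area_fac <- (pi * R^2) / (length(p) * h^2)
  outer(as.vector(v_mean * p / mean(p) * area_fac), -nrm)
}

assemble_bc <- function(nodes, grid, v_mean, outlet_fractions) {
  u_bc <- matrix(0, nodes$n, 3)
  ops <- grid$openings
  inlet <- ops[ops$label == "inlet", ]
  sel_in <- which(nodes$labs == inlet$code)
  u_bc[sel_in, ] <- cap_profile(nodes$centers, sel_in, inlet, v_mean, grid$h)
  Q_in <- v_mean * pi * (inlet$diameter / 2)^2     # m/s * mm^2
  outs <- ops[ops$label != "inlet", , drop = FALSE]
  if (nrow(outs) > 1) {
    if (is.null(outlet_fractions)) outlet_fractions <- murray_outlet_split(outs$diameter)
    if (length(outlet_fractions) != nrow(outs)) {
      stop("outlet_fractions must match the number of outlets")
    }
    outlet_fractions <- outlet_fractions / sum(outlet_fractions)
    smallest <- which.min(outs$diameter)
    for (k in seq_len(nrow(outs))) {
      if (k == smallest) next                  # pressure outlet absorbs the rest
      sel <- which(nodes$labs == outs$code[k])
      v_k <- outlet_fractions[k] * Q_in / (pi * (outs$diameter[k] / 2)^2)
      prof <- cap_profile(nodes$centers, sel, outs[k, ], v_k, grid$h)
      u_bc[sel, ] <- -prof                     # outflow: along outward normal
    }
  }
  u_bc
}

# signed outward mass-equivalent flux (m^3/s at reference density) through
# each opening: a discrete surface integral of rho*u over the full lumen
# cross-section two voxels inside the cap (density weighting removes the
# weak-compressibility bias of the lattice scheme)
opening_fluxes <- function(u_phys, nodes, grid, rho = NULL) {
  ops <- grid$openings
  vapply(seq_len(nrow(ops)), function(k) {
    sel <- flux_plane_nodes(nodes, grid, k)
    nrm <- c(ops$nx[k], ops$ny[k], ops$nz[k])
    un <- as.vector(u_phys[sel, , drop = FALSE] %*% nrm)
    if (!is.null(rho)) un <- un * rho[sel]
    sum(un) * (grid$h * 1e-3)^2
  }, 0)
}

# controller wiring for velocity-imposed (Murray) outlets: group ids per
# node, target fractions, and interior measurement planes (group 0 = inlet)
build_flux_control <- function(nodes, grid, outlet_fractions) {
  empty <- list(group = integer(nodes$n), frac = numeric(0),
                plane_idx = integer(0), plane_group = integer(0),
                plane_nrm = matrix(0, 0, 3))
  ops <- grid$openings
  if (is.null(ops)) return(empty)
  outs <- ops[ops$label != "inlet", , drop = FALSE]
  if (nrow(outs) < 2) return(empty)
  if (is.null(outlet_fractions)) outlet_fractions <- murray_outlet_split(outs$diameter)
  outlet_fractions <- outlet_fractions / sum(outlet_fractions)
  smallest <- which.min(outs$diameter)
  group <- integer(nodes$n)
  frac <- numeric(0)
  plane_idx <- integer(0); plane_group <- integer(0); plane_nrm <- NULL
  k_in <- which(ops$label == "inlet")
  sel0 <- flux_plane_nodes(nodes, grid, k_in)
  plane_idx <- c(plane_idx, sel0 - 1L)
  plane_group <- c(plane_group, rep(0L, length(sel0)))
  plane_nrm <- matrix(rep(c(ops$nx[k_in], ops$ny[k_in], ops$nz[k_in]),
                          each = length(sel0)), ncol = 3)
  gid <- 0L
  for (k in seq_len(nrow(outs))) {
    if (k == smallest) next
    gid <- gid + 1L
    frac <- c(frac, outlet_fractions[k])
    group[nodes$labs == outs$code[k]] <- gid
    kk <- which(ops$code == outs$code[k])
    sel <- flux_plane_nodes(nodes, grid, kk)
    plane_idx <- c(plane_idx, sel - 1L)
    plane_group <- c(plane_group, rep(gid, length(sel)))
    plane_nrm <- rbind(plane_nrm, matrix(rep(c(ops$nx[kk], ops$ny[kk], ops$nz[kk]),
                                             each = length(sel)), ncol = 3))
  }
  list(group = group, frac = frac, plane_idx = plane_idx,
       plane_group = plane_group, plane_nrm = plane_nrm)
}

flux_plane_nodes <- function(nodes, grid, k) {
  op <- grid$openings[k, ]
  nrm <- c(op$nx, op$ny, op$nz)
  rel <- sweep(nodes$centers, 2, c(op$cx, op$cy, op$cz), "-")
  s <- as.vector(rel %*% nrm)
  lat2 <- rowSums(rel^2) - s^2
  which(s >= -2.6 * grid$h & s < -1.6 * grid$h &
          lat2 <= (op$diameter / 2 + 2 * grid$h)^2)
}

# ---- solvers -------------------------------------------------------------

#' Steady-state flow solve
#'
#' Runs the D3Q19 lattice-Boltzmann solver with constant inflow until the
#' velocity field is stationary: a parabolic inlet profile at the prescribed
#' mean velocity, Murray's-law flux-controlled outlets with the
#' smallest-diameter outlet held at the 0 Pa reference pressure, rigid
#' no-slip walls (halfway bounce-back), and the Darcy-Forchheimer body force
#' in porous voxels.
#'
#' @param grid a [voxel_grid].
#' @param porous optional [map_stent_to_porous_voxels()] layer.
#' @param fluid a [fluid_props].
#' @param v_mean mean inlet velocity (m/s).
#' @param outlet_fractions optional outflow fractions (default Murray's law).
#' @param conv_tol per-step relative velocity residual for convergence.
#' @param max_steps iteration cap.
#' @param init optional previous [flow_field] on the same grid used as the
#'   initial condition (warm start).
#' @param tau_min,tau_max,mach_limit see [lbm_units()].
#' @param verbose print residuals.
#' @return a `flow_field`: physical velocities (m/s) at the fluid nodes, the
#'   cycle/ensemble average speed, per-opening fluxes and solver diagnostics.
#' @export
run_steady <- function(grid, porous = NULL, fluid = fluid_props(), v_mean,
                       outlet_fractions = NULL, conv_tol = 1e-6,
                       max_steps = 60000L, init = NULL,
                       tau_min = 0.55, tau_max = 1.2, mach_limit = 0.1,
                       verbose = FALSE) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (v_mean < 0) stop("v_mean must be non-negative")
  if (v_mean == 0) {
    nodes <- build_lbm_nodes(grid, porous)
    u0 <- matrix(0, nodes$n, 3)
    return(new_flow_field(list(u0), 0, nodes, grid, fluxes = matrix(0, 1, nrow(grid$openings)),
                          dt = NA, tau = NA, steps = 0, converged = TRUE))
  }
  nodes <- build_lbm_nodes(grid, porous)
  u_bc_phys <- assemble_bc(nodes, grid, v_mean, outlet_fractions)
  un <- lbm_units(grid$h, fluid, u_peak = 1.35 * max(sqrt(rowSums(u_bc_phys^2))),
                  tau_min = tau_min, tau_max = tau_max, mach_limit = mach_limit)
  u_bc <- u_bc_phys / un$u_scale
  alpha_lat <- nodes$alpha * un$dt / fluid$density
  beta_lat <- nodes$beta * un$h_m / fluid$density
  ramp <- pmin(1, seq_len(max_steps) / 600)
  u_init <- if (!is.null(init)) init$u[[length(init$u)]] / un$u_scale else NULL
  ctrl <- build_flux_control(nodes, grid, outlet_fractions)
  res <- cpp_lbm_run(nodes$neigh, nodes$node_type, u_bc, nodes$bc_ref,
                     alpha_lat, beta_lat,
                     un$tau, as.integer(max_steps), ramp, integer(0),
                     50L, conv_tol, mach_limit, u_init, nodes$link_frac,
                     ctrl$group, ctrl$frac, ctrl$plane_idx, ctrl$plane_group,
                     ctrl$plane_nrm, as.integer(verbose))
  if (res$unstable) {
    stop(sprintf(paste0("lattice instability (max lattice velocity %.3g at step %d): ",
                        "refine the resolution or reduce the inflow velocity"),
                 res$max_u_lattice, res$steps))
  }
  if (!res$converged) {
    warning(sprintf("steady solve not converged after %d steps (residual %.3g)",
                    res$steps, res$residual))
  }
  u_phys <- res$u * un$u_scale
  fx <- matrix(opening_fluxes(u_phys, nodes, grid, rho = res$rho), nrow = 1)
  new_flow_field(list(u_phys), times = 0, nodes = nodes, grid = grid,
                 fluxes = fx, dt = un$dt, tau = un$tau, steps = res$steps,
                 converged = res$converged, rho = res$rho,
                 u_scale = un$u_scale, rho0 = fluid$density)
}

#' Pulsatile flow solve over one cardiac cycle
#'
#' As [run_steady()], but with the inlet (and flux-controlled outlets) scaled
#' by a periodic waveform. The simulation runs `warmup_cycles` precursor
#' cycles and then one export cycle from which `n_export` equally spaced
#' velocity snapshots are taken.
#'
#' @inheritParams run_steady
#' @param wf a [waveform_spec].
#' @param n_export number of snapshots over the export cycle (default 50).
#' @param warmup_cycles precursor cycles before the export cycle (default 2).
#' @return a `flow_field` with `n_export` instants, their fluxes and the
#'   cycle-averaged speed field.
#' @export
run_pulsatile <- function(grid, porous = NULL, fluid = fluid_props(), wf,
                          outlet_fractions = NULL, n_export = 50L,
                          warmup_cycles = 2L, tau_min = 0.55, tau_max = 1.2,
                          mach_limit = 0.1, verbose = FALSE) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(wf, "waveform_spec"))
  nodes <- build_lbm_nodes(grid, porous)
  u_bc_phys <- assemble_bc(nodes, grid, wf$v_mean, outlet_fractions)
  un <- lbm_units(grid$h, fluid,
                  u_peak = 1.35 * wf$w_max * max(sqrt(rowSums(u_bc_phys^2))),
                  tau_min = tau_min, tau_max = tau_max, mach_limit = mach_limit)
  spc <- as.integer(ceiling(wf$period / un$dt))
  un$dt <- wf$period / spc                     # integer steps per cycle
  un$u_scale <- un$h_m / un$dt
  un$tau <- 0.5 + 3 * (fluid$viscosity / fluid$density) * un$dt / un$h_m^2
  u_bc <- u_bc_phys / un$u_scale
  alpha_lat <- nodes$alpha * un$dt / fluid$density
  beta_lat <- nodes$beta * un$h_m / fluid$density
  n_steps <- (warmup_cycles + 1L) * spc
  tgrid <- (seq_len(n_steps) - 1) * un$dt
  scale <- wf$w(tgrid) * pmin(1, seq_len(n_steps) / min(300, spc %/% 4))
  exp_steps <- warmup_cycles * spc +
    unique(floor(seq(0, spc - 1, length.out = n_export)))
  ctrl <- build_flux_control(nodes, grid, outlet_fractions)
  res <- cpp_lbm_run(nodes$neigh, nodes$node_type, u_bc, nodes$bc_ref,
                     alpha_lat, beta_lat,
                     un$tau, n_steps, scale, as.integer(exp_steps),
                     0L, 0, mach_limit, NULL, nodes$link_frac,
                     ctrl$group, ctrl$frac, ctrl$plane_idx, ctrl$plane_group,
                     ctrl$plane_nrm, as.integer(verbose))
  if (res$unstable) {
    stop(sprintf(paste0("lattice instability (max lattice velocity %.3g at step %d): ",
                        "refine the resolution or reduce the inflow velocity"),
                 res$max_u_lattice, res$steps))
  }
  u_list <- lapply(res$exports, function(m) m[, 1:3] * un$u_scale)
  rho_list <- lapply(res$exports, function(m) m[, 4])
  fx <- t(vapply(seq_along(u_list), function(i) {
    opening_fluxes(u_list[[i]], nodes, grid, rho = rho_list[[i]])
  }, numeric(nrow(grid$openings))))
  new_flow_field(u_list, times = (exp_steps - warmup_cycles * spc) * un$dt,
                 nodes = nodes, grid = grid, fluxes = fx, dt = un$dt,
                 tau = un$tau, steps = res$steps, converged = TRUE,
                 rho = res$rho, u_scale = un$u_scale, rho0 = fluid$density)
}

#' Static pressure field of a flow solution
#'
#' Relative pressure in Pa at every node, from the lattice density:
#' `p = c_s^2 (rho - 1)` in lattice units, scaled to physical units. The
#' reference 0 Pa is the smallest-diameter outlet.
#'
#' @param flow a `flow_field` from [run_steady()] or [run_pulsatile()].
#' @return numeric vector of pressures (Pa), one per node (final instant).
#' @export
pressure_field <- function(flow) {
  stopifnot(inherits(flow, "flow_field"))
  if (is.null(flow$rho)) stop("flow field carries no density information")
  (flow$rho - 1) / 3 * flow$rho0 * flow$u_scale^2
}

new_flow_field <- function(u_list, times, nodes, grid, fluxes, dt, tau, steps,
                           converged, rho = NULL, u_scale = NA, rho0 = 1055) {
  speed <- Reduce(`+`, lapply(u_list, function(m) sqrt(rowSums(m^2)))) / length(u_list)
  ops <- grid$openings
  colnames(fluxes) <- ops$label
  structure(list(u = u_list, times = times, lin = nodes$lin,
                 node_type = nodes$node_type, dims = nodes$dims, h = grid$h,
                 origin = grid$origin, cycle_avg_speed = speed, fluxes = fluxes,
                 rho = rho, dt = dt, tau = tau, steps = steps,
                 converged = converged, u_scale = u_scale, rho0 = rho0),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat("<flow_field> ", length(x$u), " instant(s), ", length(x$lin),
      " nodes @ h = ", x$h, " mm\n  dt = ", signif(x$dt, 3), " s, tau = ",
      signif(x$tau, 4), ", steps = ", x$steps,
      if (isTRUE(x$converged)) " (converged)" else "", "\n", sep = "")
  cat("  mean speed ", signif(mean(x$cycle_avg_speed), 4), " m/s; fluxes (m^3/s): ",
      paste(signif(colMeans(x$fluxes), 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Mass-conservation error of a flow field
#'
#' Relative inlet/outlet flux imbalance `|Q_in - sum(Q_out)| / Q_in` per
#' exported instant.
#'
#' @param flow a `flow_field`.
#' @return numeric vector, one value per instant.
#' @export
mass_conservation_error <- function(flow) {
  fx <- flow$fluxes
  q_in <- -fx[, 1]                      # inlet flux is inward (negative outward)
  q_out <- rowSums(fx[, -1, drop = FALSE])
  abs(q_in - q_out) / pmax(abs(q_in), .Machine$double.eps)
}
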