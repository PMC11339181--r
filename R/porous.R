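#' Darcy-Forchheimer pressure drop across a flow-diverter layer
#'
#' Evaluates the layer pressure drop \deqn{\Delta p = l_c v + q_c v^2,} the
#' hydrodynamic-resistance (HR) characteristic of a deployed braided
#' flow diverter. `l_c` is the linear and `q_c` the quadratic resistance
#' coefficient; `v` is the (superficial) velocity normal to the layer.
#'
#' @param l_c linear resistance coefficient (kg/m^2/s), `>= 0`.
#' @param q_c quadratic resistance coefficient (kg/m^3), `>= 0`.
#' @param v velocity across the layer (m/s), `>= 0`; vectorized.
#' @return pressure drop in Pa, same length as `v`.
#' @examples
#' pressure_drop(66.8, 170, 0.1)  # 8.38 Pa
#' @seealso [fit_hr_coefficients()], [hr_scenarios()]
#' @export
pressure_drop <- function(l_c, q_c, v) {
  stopifnot(is.numeric(l_c), is.numeric(q_c), is.numeric(v))
  if (l_c < 0 || q_c < 0) stop("resistance coefficients must be non-negative")
  if (any(v < 0)) stop("velocity must be non-negative (take the magnitude first)")
  l_c * v + q_c * v^2
}

#' Fit hydrodynamic-resistance coefficients from pressure-drop samples
#'
#' Least-squares fit of the no-intercept model `dp = l_c*v + q_c*v^2` to
#' measured (velocity, pressure-drop) pairs, as produced by a bench
#' HR measurement of a deployed device. Negative fitted coefficients are
#' clipped to zero with a warning (the physical model admits only
#' non-negative resistances).
#'
#' @param v velocities (m/s), at least 3 distinct positive values.
#' @param dp pressure drops (Pa), same length as `v`.
#' @return named numeric vector `c(l_c = , q_c = )`.
#' @examples
#' v <- c(0.05, 0.1, 0.2, 0.4)
#' fit_hr_coefficients(v, pressure_drop(100, 200, v))
#' @export
fit_hr_coefficients <- function(v, dp) {
  if (length(v) != length(dp)) stop("v and dp must have equal length")
  if (length(v) < 3) stop("at least 3 samples are required")
  if (length(unique(v)) < 2 || all(v == v[1])) stop("velocities must not be all identical")
  if (any(v <= 0)) stop("velocities must be positive")
  if (all(dp == 0)) return(c(l_c = 0, q_c = 0))
  fit <- lm(dp ~ 0 + v + I(v^2))
  cf <- unname(coef(fit))
  if (any(cf < 0)) {
    warning("negative fitted resistance coefficient clipped to 0")
    cf <- pmax(cf, 0)
  }
  c(l_c = cf[1], q_c = cf[2])
}

#' Measured hydrodynamic-resistance scenarios
#'
#' The 16 bench-measured deployment scenarios shipped with the package:
#' two braided flow-diverter designs (48-wire PED, 64-wire P64), each
#' deployed nominally (device diameter equal to the 4-mm host tube) or
#' oversized (device 1 mm larger than the host tube), with the measured
#' linear (`l_c`, kg/m^2/s) and quadratic (`q_c`, kg/m^3) Darcy-Forchheimer
#' coefficients. Oversizing opens the braid and sharply lowers `l_c`.
#'
#' @param file optional path to an alternative scenario CSV with the same
#'   columns (`scenario_id, device, wire_count, deployment, l_c, q_c`).
#' @return a `data.frame` of class `hr_scenarios`, one row per scenario.
#' @examples
#' hr <- hr_scenarios()
#' aggregate(l_c ~ device + deployment, hr, mean)
#' @export
hr_scenarios <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "hr_scenarios.csv", package = "stentflow",
                        mustWork = TRUE)
  }
  x <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("scenario_id", "device", "wire_count", "deployment", "l_c", "q_c")
  if (!all(need %in% names(x))) {
    stop("scenario file must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(x$scenario_id)) stop("duplicate scenario ids")
  if (any(x$l_c < 0) || any(x$q_c < 0)) stop("resistance coefficients must be >= 0")
  if (!all(x$deployment %in% c("nominal", "oversized"))) {
    stop("deployment must be 'nominal' or 'oversized'")
  }
  class(x) <- c("hr_scenarios", "data.frame")
  x
}

#' Map a deployed stent surface into a porous voxel layer
#'
#' Rasterizes the deployed stent into the fluid voxels of a grid and dilates
#' the rasterized shell to a prescribed layer thickness. The areal HR law
#' (pressure drop across the layer) is converted to volumetric
#' Darcy-Forchheimer coefficients `alpha = l_c / t_layer` (kg/m^3/s) and
#' `beta = q_c / t_layer` (kg/m^4), so that integrating the body force
#' `f = -(alpha u + beta |u| u)` across the layer thickness recovers
#' `dp = l_c v + q_c v^2`.
#'
#' @param stent a [stent_surface] (deployed spring network) or an `n x 3`
#'   matrix of surface points in mm.
#' @param grid a [voxel_grid].
#' @param l_c,q_c hydrodynamic-resistance coefficients (SI, see
#'   [pressure_drop()]).
#' @param t_layer porous layer thickness in mm; default one voxel.
#' @return an object of class `porous_layer`: integer voxel indices (into the
#'   grid's fluid nodes), `alpha`, `beta` (SI volumetric coefficients) and
#'   `t_layer`.
#' @export
map_stent_to_porous_voxels <- function(stent, grid, l_c, q_c, t_layer = grid$h) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (t_layer <= 0) stop("t_layer must be positive")
  pts <- if (inherits(stent, "stent_surface")) stent$node_positions else as.matrix(stent)
  if (ncol(pts) != 3) stop("stent points must be n x 3")
  h <- grid$h
  # voxel indices (0-based) of each surface point, then dilate to t_layer
  idx <- floor(sweep(pts, 2, grid$origin, "-") / h)
  r_vox <- max(0L, as.integer(ceiling(t_layer / h / 2 - 0.5)))
  dim3 <- dim(grid$labels)
  lin <- porous_rasterize(idx, dim3, r_vox)
  # restrict to fluid-like voxels (fluid label only; caps keep their BC role)
  keep <- grid$labels[lin] == 1L
  lin <- lin[keep]
  if (length(lin) == 0) stop("stent does not intersect the fluid region of the grid")
  structure(list(
    voxels = sort(lin), t_layer = t_layer,
    l_c = l_c, q_c = q_c,
    alpha = l_c / (t_layer * 1e-3), beta = q_c / (t_layer * 1e-3)
  ), class = "porous_layer")
}

# linear (1-based) voxel indices touched by points idx (0-based), dilated by
# r_vox voxels in each direction, clipped to the grid box
porous_rasterize <- function(idx, dim3, r_vox) {
  offs <- expand.grid(dx = -r_vox:r_vox, dy = -r_vox:r_vox, dz = -r_vox:r_vox)
  out <- integer(0)
  for (k in seq_len(nrow(offs))) {
    i <- idx[, 1] + offs$dx[k]; j <- idx[, 2] + offs$dy[k]; l <- idx[, 3] + offs$dz[k]
    ok <- i >= 0 & i < dim3[1] & j >= 0 & j < dim3[2] & l >= 0 & l < dim3[3]
    out <- c(out, 1L + i[ok] + dim3[1] * (j[ok] + dim3[2] * l[ok]))
  }
  unique(out)
}

#' @export
print.porous_layer <- function(x, ...) {
  cat("<porous_layer> ", length(x$voxels), " voxels, t_layer = ", x$t_layer,
      " mm\n  l_c = ", x$l_c, " kg/m2s, q_c = ", x$q_c, " kg/m3 (alpha = ",
      signif(x$alpha, 4), ", beta = ", signif(x$beta, 4), " SI)\n", sep = "")
  invisible(x)
}
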