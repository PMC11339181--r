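#' Detect the ostium plane and build the sac region
#'
#' Separates the aneurysm sac from the parent lumen by the ostium (neck)
#' plane. For parametric geometries the stored analytic neck plane is used
#' directly. Otherwise a geometric fallback estimates the parent centerline
#' and radius (iterative principal-axis fit with radial trimming), takes the
#' bulge voxels off the parent lumen, and places the plane perpendicular to
#' the parent-to-sac direction at the minimal-area cross-section of the
#' bulge funnel.
#'
#' @param g the [surface_geometry] the grid was voxelized from (may be
#'   `NULL` when `grid` carries the geometry metadata).
#' @param grid a [voxel_grid].
#' @return object of class `sac_region`: `plane` (point + unit normal, mm;
#'   normal points from the parent lumen into the sac), `mask` (1-based
#'   linear voxel indices of the sac), `analytic` flag.
#' @export
detect_ostium_plane <- function(g = NULL, grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  meta <- if (!is.null(g)) g$metadata else grid$meta
  lin <- which(grid$labels != 0L)
  ctr <- voxel_centers(grid, lin)
  if (!is.null(meta$ostium_plane)) {
    pl <- meta$ostium_plane
    s <- sweep(ctr, 2, pl$point, "-") %*% pl$normal
    off_axis <- radial_distance(ctr, meta$centerline) > meta$parent_radius
    mask <- lin[s > 0 & off_axis]
    return(structure(list(plane = pl, mask = mask, analytic = TRUE),
                     class = "sac_region"))
  }
  fallback_ostium(grid, lin, ctr)
}

radial_distance <- function(pts, centerline) {
  if (nrow(centerline) == 2 ||
      max(abs(diff(centerline[, 2]))) + max(abs(diff(centerline[, 3]))) < 1e-9) {
    # straight axis
    p0 <- centerline[1, ]; d <- centerline[nrow(centerline), ] - p0
    d <- d / sqrt(sum(d^2))
    rel <- sweep(pts, 2, p0, "-")
    s <- rel %*% d
    sqrt(pmax(0, rowSums(rel^2) - s^2))
  } else {
    # curved axis: distance to the polyline, chunked to bound memory
    out <- numeric(nrow(pts))
    idx <- split(seq_len(nrow(pts)), ceiling(seq_len(nrow(pts)) / 20000))
    for (ii in idx) {
      d2 <- outer(rowSums(pts[ii, , drop = FALSE]^2), rowSums(centerline^2), "+") -
        2 * pts[ii, , drop = FALSE] %*% t(centerline)
      out[ii] <- sqrt(pmax(0, apply(d2, 1, min)))
    }
    out
  }
}

# geometric neck detection for grids without analytic metadata, assuming a
# near-spherical sac on a near-cylindrical parent (the package's synthetic
# family): fit the parent cylinder and the sac sphere, then solve for the
# neck circle where the two primitives intersect
fallback_ostium <- function(grid, lin, ctr) {
  # 1. parent axis and radius: principal axis of the fluid cloud, refined by
  #    trimming voxels far from the axis (the sac) and refitting
  keep <- rep(TRUE, nrow(ctr))
  axis_dir <- NULL; axis_pt <- NULL; r_hat <- NULL; rad <- NULL
  for (it in 1:4) {
    pc <- prcomp(ctr[keep, , drop = FALSE])
    axis_dir <- pc$rotation[, 1]
    axis_pt <- colMeans(ctr[keep, , drop = FALSE])
    rel <- sweep(ctr, 2, axis_pt, "-")
    s <- rel %*% axis_dir
    rad <- sqrt(pmax(0, rowSums(rel^2) - s^2))
    r_hat <- unname(stats::quantile(rad[keep], 0.8))
    keep <- rad < 1.3 * r_hat
  }
  h <- grid$h
  wall_all <- has_solid_neighbor(grid, lin)
  fit_sphere <- function(P) {
    coefs <- qr.solve(cbind(2 * P, 1), rowSums(P^2))
    # wall-voxel centres sit about half a voxel inside the surface
    list(c = coefs[1:3], R = sqrt(coefs[4] + sum(coefs[1:3]^2)) + h / 2)
  }
  # 2. rough sac sphere from the bulge's wall voxels (q0.8 of radii in a
  #    filled cylinder sits at sqrt(0.8) R: debias before thresholding)
  sac_sel <- rad > 1.05 * r_hat / sqrt(0.8)
  if (sum(sac_sel) < 20) stop("no sac detectable off the parent lumen")
  wall <- sac_sel & wall_all
  if (sum(wall) < 12) wall <- sac_sel
  sph <- fit_sphere(ctr[wall, , drop = FALSE])
  # 3. re-fit the parent axis on fluid clearly outside the sac sphere, and
  #    the parent radius from that region's wall voxels
  d_sph <- sqrt(rowSums(sweep(ctr, 2, sph$c, "-")^2))
  parent <- d_sph > sph$R + h
  if (sum(parent) < 100) stop("no sac detectable off the parent lumen")
  pc <- prcomp(ctr[parent, , drop = FALSE])
  axis_dir <- pc$rotation[, 1]
  axis_pt <- colMeans(ctr[parent, , drop = FALSE])
  rel <- sweep(ctr, 2, axis_pt, "-")
  s_all <- as.vector(rel %*% axis_dir)
  rad <- sqrt(pmax(0, rowSums(rel^2) - s_all^2))
  pw <- parent & wall_all
  r_p <- mean(rad[pw]) + h / 2
  # 4. re-fit the sac sphere with the refined parent radius
  wall2 <- rad > 1.05 * r_p & wall_all & d_sph < sph$R + 2 * h
  if (sum(wall2) >= 12) sph <- fit_sphere(ctr[wall2, , drop = FALSE])
  # 5. neck circle radius from the cylinder-sphere pair, neck plane through
  #    it perpendicular to the axis-to-sphere-centre direction
  s_c <- sum((sph$c - axis_pt) * axis_dir)
  foot <- axis_pt + s_c * axis_dir
  t_c <- sqrt(sum((sph$c - foot)^2))
  nrm <- (sph$c - foot) / t_c
  fr <- function(r_n) sqrt(pmax(r_p^2 - r_n^2, 0)) +
    sqrt(pmax(sph$R^2 - r_n^2, 0)) - t_c
  r_max <- min(r_p, sph$R) * 0.999999
  r_n <- if (fr(r_max) > 0) r_max else stats::uniroot(fr, c(1e-6, r_max))$root
  t0 <- sqrt(max(r_p^2 - r_n^2, 0))
  plane <- list(point = as.numeric(foot + t0 * nrm), normal = as.numeric(nrm))
  s <- sweep(ctr, 2, plane$point, "-") %*% nrm
  mask <- lin[s > 0 & rad > r_p]
  structure(list(plane = plane, mask = mask, analytic = FALSE,
                 parent_radius_est = r_p, sac_center_est = sph$c,
                 sac_radius_est = sph$R),
            class = "sac_region")
}

# voxels (among lin) with at least one solid 6-neighbor
has_solid_neighbor <- function(grid, lin) {
  dims <- dim(grid$labels)
  ijk <- arrayInd(lin, dims)
  out <- rep(FALSE, length(lin))
  for (d in 1:3) for (s in c(-1L, 1L)) {
    ijk2 <- ijk
    ijk2[, d] <- ijk2[, d] + s
    inside <- ijk2[, d] >= 1 & ijk2[, d] <= dims[d]
    lin2 <- ijk2[, 1] + dims[1] * (ijk2[, 2] - 1) + dims[1] * dims[2] * (ijk2[, 3] - 1)
    hit <- !inside
    hit[inside] <- grid$labels[lin2[inside]] == 0L
    out <- out | hit
  }
  out
}

#' @export
print.sac_region <- function(x, ...) {
  cat("<sac_region> ", length(x$mask), " voxels; plane point (",
      paste(signif(x$plane$point, 4), collapse = ", "), "), normal (",
      paste(signif(x$plane$normal, 3), collapse = ", "), ")",
      if (x$analytic) " [analytic]" else " [detected]", "\n", sep = "")
  invisible(x)
}

#' Space- and time-averaged velocity in the sac
#'
#' Mean of the velocity magnitude over the sac voxels and over all exported
#' instants of the flow field.
#'
#' @param flow a `flow_field` (see [run_steady()], [run_pulsatile()]).
#' @param sac a [detect_ostium_plane()] result.
#' @return STAV in m/s.
#' @export
stav <- function(flow, sac) {
  stopifnot(inherits(flow, "flow_field"), inherits(sac, "sac_region"))
  if (length(sac$mask) == 0) stop("empty sac mask")
  if (length(flow$u) < 1) stop("flow field has no exported instants")
  node_idx <- match(sac$mask, flow$lin)
  node_idx <- node_idx[!is.na(node_idx)]
  if (length(node_idx) == 0) stop("sac mask does not overlap the flow-field nodes")
  mean(vapply(flow$u, function(m) {
    mean(sqrt(rowSums(m[node_idx, , drop = FALSE]^2)))
  }, 0))
}

#' Aneurysmal mean velocity reduction
#'
#' `AMVR = (STAV_pre - STAV_FD) / STAV_pre`: the fraction by which flow
#' diversion reduces the mean intra-aneurysmal velocity. Negative values
#' (treated velocity above pretreatment) are flagged with a warning.
#'
#' @param stav_pre pretreatment STAV (m/s, positive).
#' @param stav_fd posttreatment STAV (m/s, non-negative).
#' @return AMVR as a dimensionless fraction (<= 1).
#' @examples
#' amvr(0.10, 0.04)  # 0.6
#' @export
amvr <- function(stav_pre, stav_fd) {
  if (stav_pre <= 0) stop("stav_pre must be positive")
  if (stav_fd < 0) stop("stav_fd must be non-negative")
  out <- (stav_pre - stav_fd) / stav_pre
  if (out < 0) warning("negative AMVR: treated velocity exceeds pretreatment")
  out
}
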