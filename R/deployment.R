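#' Build a braided flow-diverter spring network
#'
#' Constructs the diamond-braid node lattice of a self-expanding braided
#' stent: `n_wires/2` left-handed and `n_wires/2` right-handed helical wires
#' whose crossings form the nodes. Surface springs connect crossing
#' neighbours along the wires (they carry the length contraction of the
#' braid); a radial spring at every node pulls towards the nominal radius
#' (self-expansion). Rest lengths equal the nominal-state distances, so the
#' free equilibrium is exactly the nominal device.
#'
#' @param n_wires even wire count >= 8 (48 for the PED-class device, 64 for
#'   the P64-class device).
#' @param diameter nominal (labelled) device diameter, mm.
#' @param length nominal device length, mm.
#' @param braid_angle wire angle from the device axis in the nominal state,
#'   degrees (0, 90); braided flow diverters are typically 70-80 degrees.
#' @param k_s,k_r surface and radial spring stiffness (N/mm); see
#'   [calibrate_stiffness()].
#' @param wire_diameter single wire diameter, mm (default 0.030).
#' @return object of class `spring_network`.
#' @export
build_braid <- function(n_wires, diameter, length, braid_angle = 75,
                        k_s = 1, k_r = 0.05, wire_diameter = 0.030) {
  if (n_wires %% 2 != 0) stop("n_wires must be even (half left-, half right-handed)")
  if (n_wires < 8) stop("n_wires must be at least 8")
  if (diameter <= 0 || length <= 0) stop("diameter and length must be positive")
  if (braid_angle <= 0 || braid_angle >= 90) stop("braid_angle must be in (0, 90)")
  if (k_s <= 0 || k_r <= 0) stop("stiffnesses must be positive")
  n_c <- n_wires / 2
  r0 <- diameter / 2
  dz <- (pi * diameter / n_c) / (2 * tan(braid_angle * pi / 180))
  n_z <- max(3L, round(length / dz) + 1L)
  dz <- length / (n_z - 1)              # hit the nominal length exactly
  row <- rep(seq_len(n_z) - 1L, each = n_c)
  col <- rep(seq_len(n_c) - 1L, times = n_z)
  theta <- (2 * pi / n_c) * (col + (row %% 2) / 2)
  pos <- cbind(row * dz, r0 * cos(theta), r0 * sin(theta))
  nid <- function(i, j) j * n_c + (i %% n_c) + 1L   # col i, row j -> node id
  sp <- vector("list", n_z - 1)
  for (j in 0:(n_z - 2)) {
    i <- 0:(n_c - 1)
    if (j %% 2 == 0) {
      sp[[j + 1]] <- rbind(cbind(nid(i, j), nid(i, j + 1)),
                           cbind(nid(i, j), nid(i - 1, j + 1)))
    } else {
      sp[[j + 1]] <- rbind(cbind(nid(i, j), nid(i + 1, j + 1)),
                           cbind(nid(i, j), nid(i, j + 1)))
    }
  }
  springs <- do.call(rbind, sp)
  l0 <- sqrt(rowSums((pos[springs[, 1], ] - pos[springs[, 2], ])^2))
  structure(list(pos = pos, springs = springs, l0 = l0, k_s = k_s, k_r = k_r,
                 n_wires = n_wires, n_c = n_c, n_z = n_z, row = row, col = col,
                 nominal_diameter = diameter, nominal_length = length,
                 braid_angle = braid_angle, wire_diameter = wire_diameter,
                 damping = NULL),
            class = "spring_network")
}

#' @export
print.spring_network <- function(x, ...) {
  cat("<spring_network> ", x$n_wires, "-wire braid, ", nrow(x$pos), " nodes, ",
      nrow(x$springs), " surface springs\n  nominal ", x$nominal_diameter,
      " x ", x$nominal_length, " mm, braid angle ", x$braid_angle,
      " deg, k_s = ", x$k_s, ", k_r = ", x$k_r, " N/mm\n", sep = "")
  invisible(x)
}

relax_network <- function(pos, net, k_s = net$k_s, k_r = net$k_r,
                          r_target = net$nominal_diameter / 2,
                          axis = list(type = 0L, params = c(0, 0, 0, 1, 0, 0)),
                          r_wall = -1, r_sheath = -1,
                          constrained = integer(nrow(pos)),
                          tol = 1e-4, max_iter = 50000L, energy_stride = 0L) {
  dt0 <- 0.25 / sqrt(4 * k_s + k_r)     # stable step for the stiffest mode, m = 1
  cpp_spring_relax(pos, net$springs - 1L, net$l0, k_s, k_r,
                   rep(r_target, length.out = nrow(pos)),
                   axis$type, axis$params, r_wall, r_sheath,
                   as.integer(constrained), dt0, tol,
                   as.integer(max_iter), as.integer(energy_stride))
}

#' Simulate a tensile (force-response) test of the braid
#'
#' Grips both end rings, displaces the distal grip axially by each requested
#' elongation, relaxes the free nodes to equilibrium and reads the axial
#' grip force. This is the forward model inverted by
#' [calibrate_stiffness()].
#'
#' @param net a [build_braid()] network.
#' @param elongations axial grip displacements, mm.
#' @param k_s,k_r stiffnesses to simulate with (default the network's).
#' @return data.frame with `elongation_mm` and `force_n`.
#' @export
simulate_tensile <- function(net, elongations, k_s = net$k_s, k_r = net$k_r) {
  stopifnot(inherits(net, "spring_network"))
  grip <- ifelse(net$row == 0 | net$row == net$n_z - 1, 2L, 0L)
  distal <- net$row == net$n_z - 1
  force <- vapply(elongations, function(e) {
    pos <- net$pos
    pos[, 1] <- pos[, 1] * (1 + e / net$nominal_length)   # affine initial guess
    pos[distal, 1] <- net$nominal_length + e
    pos[net$row == 0, 1] <- 0
    res <- relax_network(pos, net, k_s = k_s, k_r = k_r, constrained = grip,
                         tol = 1e-6)
    -sum(res$force[distal, 1])          # reaction force at the distal grip
  }, 0)
  data.frame(elongation_mm = elongations, force_n = force)
}

#' Calibrate spring stiffness from tensile force-response data
#'
#' Recovers the surface and radial stiffness pair `(k_s, k_r)` that makes
#' the simulated tensile force-elongation curve of the braid fit measured
#' samples in the least-squares sense. The equilibrium shape depends only on
#' the ratio `k_r/k_s` while forces scale linearly with `k_s`, so the fit is
#' a 1-D search over the log ratio with the scale solved in closed form.
#'
#' @param net a [build_braid()] network (geometry only; its stored
#'   stiffnesses are ignored).
#' @param samples data.frame/matrix with columns (elongation mm, force N);
#'   at least 3 rows with positive elongations.
#' @param ratio_bounds search interval for `k_r/k_s`.
#' @return named vector `c(k_s = , k_r = )`.
#' @export
calibrate_stiffness <- function(net, samples, ratio_bounds = c(1e-3, 10)) {
  stopifnot(inherits(net, "spring_network"))
  samples <- as.matrix(samples)
  if (nrow(samples) < 3) stop("at least 3 tensile samples are required")
  e <- samples[, 1]; f <- samples[, 2]
  if (any(e <= 0)) stop("elongations must be positive")
  if (all(f == 0)) stop("degenerate samples: all forces are zero")
  shape <- function(log_rho) {
    g <- simulate_tensile(net, e, k_s = 1, k_r = exp(log_rho))$force_n
    ks <- sum(g * f) / sum(g * g)
    list(ks = ks, rss = sum((ks * g - f)^2))
  }
  opt <- optimize(function(lr) shape(lr)$rss, log(ratio_bounds), tol = 1e-5)
  best <- shape(opt$minimum)
  rho <- exp(opt$minimum)
  c(k_s = best$ks, k_r = best$ks * rho)
}

# resolve a deployment target into wall radius + centerline axis
as_vessel_spec <- function(vessel) {
  if (is.list(vessel) && !is.null(vessel$diameter) && !inherits(vessel, "surface_geometry") &&
      !inherits(vessel, "voxel_grid")) {
    return(list(r_wall = vessel$diameter / 2,
                axis = list(type = 0L, params = c(0, 0, 0, 1, 0, 0)),
                length = vessel$length %||% Inf))
  }
  meta <- if (inherits(vessel, "voxel_grid")) vessel$meta else vessel$metadata
  if (is.null(meta$parent_diameter)) stop("cannot derive a vessel lumen from this object")
  if (!is.null(meta$bend_radius)) {
    axis <- list(type = 1L, params = c(0, meta$bend_radius, 0, meta$bend_radius))
  } else {
    axis <- list(type = 0L, params = c(0, 0, 0, 1, 0, 0))
  }
  list(r_wall = meta$parent_diameter / 2, axis = axis,
       length = meta$parent_length %||% Inf)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deploy a braided stent into a vessel
#'
#' Simulates the release of the device from its delivery catheter: the braid
#' starts radially compressed in a 1-mm virtual sheath (axially elongated
#' according to the braid kinematics), is released band by band from the
#' distal end, and each released band self-expands against the vessel wall
#' (hard projection contact) under damped spring relaxation until the
#' maximum per-step node displacement falls below `tol`.
#'
#' @param net a [build_braid()] network.
#' @param vessel deployment target: a tube spec `list(diameter =, length =)`,
#'   a [surface_geometry] or a [voxel_grid] with parent-vessel metadata, or
#'   `NULL` for free-space deployment.
#' @param release_position axial position (mm along the vessel centerline)
#'   of the deployed stent centre; default mid-vessel.
#' @param sheath_diameter delivery-sheath inner diameter, mm.
#' @param tol equilibrium tolerance: max node displacement per step, mm.
#' @param band_iters relaxation iterations after each band release.
#' @param max_iter iteration cap for the final relaxation.
#' @return object of class `stent_surface`: deployed `node_positions` (mm),
#'   `wires` (ordered node indices per wire), `deployed_length` (mm),
#'   `diameter_profile` (per braid row), the energy trace of the final
#'   relaxation and the generating network.
#' @export
deploy <- function(net, vessel = NULL, release_position = NULL,
                   sheath_diameter = 1, tol = 1e-4, band_iters = 40L,
                   max_iter = 100000L) {
  stopifnot(inherits(net, "spring_network"))
  free_space <- is.null(vessel)
  if (free_space) {
    vs <- list(r_wall = -1, axis = list(type = 0L, params = c(0, 0, 0, 1, 0, 0)),
               length = Inf)
  } else {
    vs <- as_vessel_spec(vessel)
    d_lumen <- 2 * vs$r_wall
    if (d_lumen < 0.5 * net$nominal_diameter) {
      stop("vessel too narrow: lumen below half the nominal device diameter")
    }
    if (d_lumen > 1.5 * net$nominal_diameter) {
      stop("vessel too wide: lumen above 1.5x the nominal device diameter")
    }
  }
  r0 <- net$nominal_diameter / 2
  r_sheath <- sheath_diameter / 2
  # braid kinematics: axial row spacing at a given radius, wire length fixed
  l0_seg <- mean(net$l0)
  dz0 <- net$nominal_length / (net$n_z - 1)
  dz_at <- function(r) {
    chord <- 2 * r * sin(pi / (2 * net$n_c))   # half-cell circumferential chord
    sqrt(max(l0_seg^2 - chord^2, (0.2 * dz0)^2))
  }
  dz_s <- dz_at(r_sheath)
  r_dep <- if (vs$r_wall > 0) min(vs$r_wall, r0) else r0
  dz_dep <- dz_at(r_dep)
  len_dep <- (net$n_z - 1) * dz_dep
  if (is.null(release_position)) {
    release_position <- if (is.finite(vs$length)) vs$length / 2 else len_dep / 2
  }
  s_front <- release_position + len_dep / 2   # distal end of the landing zone
  theta <- (2 * pi / net$n_c) * (net$col + (net$row %% 2) / 2)

  # distal-to-proximal release, one braid-cell band at a time: the sheathed
  # part slides distally through the catheter (as in a clinical unsheathing),
  # each released band expands at the release front and is relaxed locally
  n_nodes <- nrow(net$pos)
  constrained <- rep(1L, n_nodes)
  pos_cyl <- cbind(numeric(n_nodes), r_sheath * cos(theta),
                   r_sheath * sin(theta))
  for (j in (net$n_z - 1):0) {
    constrained[net$row == j] <- 0L
    rel <- net$row >= j                        # released rows
    pos_cyl[rel, 1] <- s_front - (net$n_z - 1 - net$row[rel]) * dz_dep
    s_bound <- s_front - (net$n_z - 1 - j) * dz_dep
    if (j > 0) {                               # sheathed rows trail the front
      sh <- net$row < j
      pos_cyl[sh, 1] <- s_bound - (j - net$row[sh]) * dz_s
      pos_cyl[sh, 2] <- r_sheath * cos(theta[sh])
      pos_cyl[sh, 3] <- r_sheath * sin(theta[sh])
    }
    newly <- net$row == j
    pos_cyl[newly, 2] <- r_dep * cos(theta[newly])
    pos_cyl[newly, 3] <- r_dep * sin(theta[newly])
    pos <- axis_embed(pos_cyl, vs$axis)
    res <- relax_network(pos, net, r_target = r0, axis = vs$axis,
                         r_wall = vs$r_wall, r_sheath = r_sheath,
                         constrained = constrained, tol = tol,
                         max_iter = band_iters)
    # back to cylinder coordinates for the next band's kinematic placement
    pos_cyl <- cyl_from_world(res$pos, vs$axis)
  }
  # the braid's coupled (radius, axial-spacing) mode is energetically almost
  # flat: reset it to the kinematic deployed state so the final relaxation
  # only has the stiff modes left to equilibrate
  row_s <- tapply(pos_cyl[, 1], net$row, mean)
  span <- max(row_s) - min(row_s)
  mid <- mean(range(row_s))
  if (span > 0) pos_cyl[, 1] <- mid + (pos_cyl[, 1] - mid) * (len_dep / span)
  r_now <- sqrt(pos_cyl[, 2]^2 + pos_cyl[, 3]^2)
  fac <- ifelse(r_now > 1e-9, r_dep / r_now, 1)
  pos_cyl[, 2] <- pos_cyl[, 2] * fac
  pos_cyl[, 3] <- pos_cyl[, 3] * fac
  pos <- axis_embed(pos_cyl, vs$axis)
  res <- relax_network(pos, net, r_target = r0, axis = vs$axis,
                       r_wall = vs$r_wall, r_sheath = -1,
                       constrained = integer(nrow(pos)), tol = tol,
                       max_iter = max_iter, energy_stride = 10L)
  if (!res$converged) {
    stop(sprintf("deployment relaxation did not converge: max displacement %.3g mm/step after %d iterations",
                 res$max_disp, res$iterations))
  }
  pos <- res$pos
  sr <- axis_coords(pos, vs$axis)
  prof <- tapply(sr$r, net$row, mean) * 2
  row_s <- tapply(sr$s, net$row, mean)   # robust against end-row tilt
  wires <- braid_wires(net)
  structure(list(node_positions = pos, wires = wires,
                 deployed_length = unname(max(row_s) - min(row_s)),
                 diameter_profile = as.numeric(prof),
                 energy = res$energy, iterations = res$iterations,
                 network = net, axis = vs$axis, r_wall = vs$r_wall),
            class = "stent_surface")
}

# cylinder coordinates -> world coordinates on the given axis
axis_embed <- function(pos_cyl, axis) {
  if (axis$type == 0L) {
    p0 <- axis$params[1:3]; d <- axis$params[4:6]
    # build an orthonormal frame (d, b1, b2)
    b1 <- if (abs(d[3]) < 0.9) c(-d[2], d[1], 0) else c(0, -d[3], d[2])
    b1 <- b1 / sqrt(sum(b1^2)); b2 <- c(d[2]*b1[3]-d[3]*b1[2], d[3]*b1[1]-d[1]*b1[3],
                                        d[1]*b1[2]-d[2]*b1[1])
    sweep(outer(pos_cyl[, 1], d) + outer(pos_cyl[, 2], b1) + outer(pos_cyl[, 3], b2),
          2, p0, "+")
  } else {
    Rb <- axis$params[4]; cen <- axis$params[1:3]
    phi <- pos_cyl[, 1] / Rb
    foot <- cbind(cen[1] + Rb * sin(phi), cen[2] - Rb * cos(phi), cen[3])
    rad_in <- cbind(sin(phi), -cos(phi), 0)   # outward in-plane unit vector
    foot + pos_cyl[, 2] * rad_in + outer(pos_cyl[, 3], c(0, 0, 1))
  }
}

# world coordinates -> cylinder frame coordinates (inverse of axis_embed)
cyl_from_world <- function(pos, axis) {
  if (axis$type == 0L) {
    p0 <- axis$params[1:3]; d <- axis$params[4:6]
    b1 <- if (abs(d[3]) < 0.9) c(-d[2], d[1], 0) else c(0, -d[3], d[2])
    b1 <- b1 / sqrt(sum(b1^2))
    b2 <- c(d[2]*b1[3]-d[3]*b1[2], d[3]*b1[1]-d[1]*b1[3], d[1]*b1[2]-d[2]*b1[1])
    rel <- sweep(pos, 2, p0, "-")
    cbind(rel %*% d, rel %*% b1, rel %*% b2)
  } else {
    cen <- axis$params[1:3]; Rb <- axis$params[4]
    px <- pos[, 1] - cen[1]; py <- pos[, 2] - cen[2]
    rho <- sqrt(px^2 + py^2)
    phi <- atan2(px, -py)
    cbind(Rb * phi, rho - Rb, pos[, 3] - cen[3])
  }
}

axis_coords <- function(pos, axis) {
  if (axis$type == 0L) {
    p0 <- axis$params[1:3]; d <- axis$params[4:6]
    rel <- sweep(pos, 2, p0, "-")
    s <- as.numeric(rel %*% d)
    r <- sqrt(pmax(0, rowSums(rel^2) - s^2))
  } else {
    cen <- axis$params[1:3]; Rb <- axis$params[4]
    px <- pos[, 1] - cen[1]; py <- pos[, 2] - cen[2]
    rho <- sqrt(px^2 + py^2)
    s <- Rb * atan2(px, -py)
    r <- sqrt((rho - Rb)^2 + (pos[, 3] - cen[3])^2)
  }
  list(s = s, r = r)
}

# ordered node indices of each wire (n_c left- plus n_c right-handed helices)
braid_wires <- function(net) {
  nid <- function(i, j) j * net$n_c + (i %% net$n_c) + 1L
  wires <- vector("list", net$n_wires)
  for (w in 0:(net$n_c - 1)) {
    right <- integer(net$n_z); left <- integer(net$n_z)
    ir <- w; il <- w
    for (j in 0:(net$n_z - 1)) {
      right[j + 1] <- nid(ir, j); left[j + 1] <- nid(il, j)
      if (j %% 2 == 1) ir <- ir + 1L else il <- il - 1L
    }
    wires[[w + 1]] <- right
    wires[[net$n_c + w + 1]] <- left
  }
  wires
}

#' @export
print.stent_surface <- function(x, ...) {
  cat("<stent_surface> ", nrow(x$node_positions), " nodes, deployed length ",
      signif(x$deployed_length, 4), " mm (nominal ",
      x$network$nominal_length, " mm)\n  diameter ",
      signif(min(x$diameter_profile), 3), "-", signif(max(x$diameter_profile), 3),
      " mm\n", sep = "")
  invisible(x)
}

#' Metallic surface area fraction of a deployed stent
#'
#' Fraction of the lateral stent surface covered by wire metal, computed
#' from the braid geometry: per braid row the local diameter and local wire
#' angle give the single-hand coverage `f = (n_wires/2) d_w / (pi D cos
#' beta)`, and the two crossing wire families combine as `MSA = 1 - (1 -
#' f)^2`, capped at 1. Oversizing (elongation) opens the braid angle and
#' lowers the MSA; higher wire counts raise it.
#'
#' @param stent a [deploy()]ed stent surface.
#' @param wire_diameter wire diameter, mm (default the device's).
#' @return MSA fraction in `[0, 1]`.
#' @export
metallic_surface_area <- function(stent, wire_diameter = stent$network$wire_diameter) {
  stopifnot(inherits(stent, "stent_surface"))
  if (wire_diameter < 0) stop("wire_diameter must be non-negative")
  if (wire_diameter == 0) return(0)
  net <- stent$network
  sc <- axis_coords(stent$node_positions, stent$axis)
  sp <- net$springs
  dz <- abs(sc$s[sp[, 1]] - sc$s[sp[, 2]])
  chord <- sqrt(pmax(0, rowSums((stent$node_positions[sp[, 1], ] -
                                   stent$node_positions[sp[, 2], ])^2) - dz^2))
  cos_beta <- dz / sqrt(dz^2 + chord^2)         # beta = wire angle from axis
  d_loc <- (sc$r[sp[, 1]] + sc$r[sp[, 2]])      # = 2 * mean radius
  w_area <- pi * d_loc * dz                     # local lateral area weight
  f_hand <- (net$n_wires / 2) * wire_diameter / (pi * d_loc * pmax(cos_beta, 1e-9))
  msa_loc <- pmin(1, 1 - (1 - pmin(f_hand, 1))^2)
  min(1, sum(msa_loc * w_area) / sum(w_area))
}
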