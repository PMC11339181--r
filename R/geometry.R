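#' Parametric sidewall aneurysm geometry
#'
#' Builds an idealized sidewall aneurysm: a spherical sac attached over a
#' circular neck to a straight (or gently curved) parent vessel. The lumen is
#' the union of two closed triangulated components (capped parent tube and
#' sac sphere), which keeps the surface watertight by construction. The
#' analytic ostium plane (the plane of the neck circle, normal pointing from
#' the parent lumen into the sac) is stored in the metadata.
#'
#' With `sac_diameter = 0` (and `neck_diameter = 0`) a plain straight tube is
#' returned; this degenerate case is used for Poiseuille-type solver checks.
#'
#' @param parent_diameter parent vessel diameter (mm), typically 2-6 mm.
#' @param sac_diameter sac (sphere) diameter (mm); 0 disables the sac.
#' @param neck_diameter neck (ostium) diameter (mm); must satisfy
#'   `0 < neck_diameter <= sac_diameter` and `neck_diameter <= parent_diameter`.
#' @param parent_length parent vessel length (mm).
#' @param bend_radius optional centerline bend radius (mm) for a curved
#'   parent; `NULL` gives a straight vessel.
#' @param n_seg circumferential tessellation segments.
#' @return object of class `surface_geometry` with fields `vertices` (mm),
#'   `triangles` (1-based vertex triples), `component` (per-triangle closed
#'   component id), `openings` (inlet/outlet caps: label, centroid, outward
#'   normal, diameter) and `metadata`.
#' @examples
#' g <- make_sidewall_aneurysm(4, 8, 4, 40)
#' g$metadata$ostium_plane
#' @export
make_sidewall_aneurysm <- function(parent_diameter, sac_diameter, neck_diameter,
                                   parent_length, bend_radius = NULL, n_seg = 48) {
  if (parent_diameter <= 0 || parent_length <= 0) {
    stop("parent_diameter and parent_length must be positive")
  }
  if (sac_diameter < 0 || neck_diameter < 0) stop("dimensions must be non-negative")
  has_sac <- sac_diameter > 0
  if (has_sac) {
    if (neck_diameter <= 0) stop("neck_diameter must be positive when a sac is present")
    if (neck_diameter > sac_diameter) {
      stop("neck_diameter must not exceed sac_diameter")
    }
    if (neck_diameter > parent_diameter) {
      stop("neck_diameter must not exceed parent_diameter (neck must fit on the vessel)")
    }
  } else if (neck_diameter > 0) {
    stop("neck_diameter must be 0 when sac_diameter is 0")
  }
  if (!is.null(bend_radius)) {
    if (bend_radius <= 0) stop("bend_radius must be positive")
    if (parent_length / bend_radius > pi) {
      stop("bend_radius too small: the centerline would exceed a half circle")
    }
  }

  r_p <- parent_diameter / 2
  n_ax <- max(8L, ceiling(parent_length / (parent_diameter / 6)))
  s <- seq(0, parent_length, length.out = n_ax + 1)
  if (is.null(bend_radius)) {
    centers <- cbind(s, 0, 0)
    tangents <- matrix(rep(c(1, 0, 0), each = n_ax + 1), ncol = 3)
  } else {
    phi <- s / bend_radius
    centers <- cbind(bend_radius * sin(phi), bend_radius * (1 - cos(phi)), 0)
    tangents <- cbind(cos(phi), sin(phi), 0)
  }
  tube <- tessellate_tube(centers, tangents, r_p, n_seg)
  verts <- tube$vertices; tris <- tube$triangles
  comp <- rep(1L, nrow(tris))

  mid <- (n_ax %/% 2) + 1L
  meta <- list(generator = "sidewall", parent_diameter = parent_diameter,
               sac_diameter = sac_diameter, neck_diameter = neck_diameter,
               parent_length = parent_length, bend_radius = bend_radius,
               parent_radius = r_p, centerline = centers, tangents = tangents)
  if (has_sac) {
    r_s <- sac_diameter / 2; r_n <- neck_diameter / 2
    t0 <- sqrt(r_p^2 - r_n^2)          # neck-plane offset from the centerline
    up <- c(0, 0, 1)                   # sac direction, out of the bend plane
    plane_pt <- centers[mid, ] + t0 * up
    sac_center <- plane_pt + sqrt(r_s^2 - r_n^2) * up
    sph <- tessellate_sphere(sac_center, r_s, n_seg, max(12L, n_seg %/% 2))
    tris <- rbind(tris, sph$triangles + nrow(verts))
    verts <- rbind(verts, sph$vertices)
    comp <- c(comp, rep(2L, nrow(sph$triangles)))
    meta$sac_center <- sac_center
    meta$sac_radius <- r_s
    meta$ostium_plane <- list(point = plane_pt, normal = up)
  }

  openings <- list(
    list(label = "inlet", centroid = centers[1, ], normal = -tangents[1, ],
         diameter = parent_diameter),
    list(label = "outlet_1", centroid = centers[n_ax + 1, ],
         normal = tangents[n_ax + 1, ], diameter = parent_diameter)
  )
  new_surface_geometry(verts, tris, comp, openings, meta)
}

#' Parametric bifurcation (Y) vessel
#'
#' A trunk vessel splitting into two straight daughter branches; used mainly
#' to exercise multi-outlet boundary conditions (Murray outflow splitting).
#'
#' @param d_in trunk diameter (mm).
#' @param d_out1,d_out2 daughter branch diameters (mm).
#' @param trunk_length,branch_length segment lengths (mm).
#' @param half_angle half opening angle between the branches (degrees).
#' @return a `surface_geometry` with one inlet and two outlets.
#' @export
make_bifurcation <- function(d_in, d_out1, d_out2, trunk_length = 15,
                             branch_length = 12, half_angle = 30, n_seg = 40) {
  if (min(d_in, d_out1, d_out2, trunk_length, branch_length) <= 0) {
    stop("all dimensions must be positive")
  }
  a <- half_angle * pi / 180
  mk_tube <- function(p0, dir, len, r) {
    n_ax <- max(6L, ceiling(len / (2 * r / 6)))
    s <- seq(0, len, length.out = n_ax + 1)
    centers <- sweep(outer(s, dir), 2, p0, "+")
    tangents <- matrix(rep(dir, each = n_ax + 1), ncol = 3)
    tessellate_tube(centers, tangents, r, n_seg)
  }
  trunk <- mk_tube(c(-trunk_length, 0, 0), c(1, 0, 0), trunk_length + d_in / 2, d_in / 2)
  b1 <- mk_tube(c(-d_in / 2, 0, 0), c(cos(a), sin(a), 0), branch_length + d_in / 2, d_out1 / 2)
  b2 <- mk_tube(c(-d_in / 2, 0, 0), c(cos(a), -sin(a), 0), branch_length + d_in / 2, d_out2 / 2)
  verts <- trunk$vertices; tris <- trunk$triangles; comp <- rep(1L, nrow(tris))
  for (part in list(b1, b2)) {
    comp <- c(comp, rep(max(comp) + 1L, nrow(part$triangles)))
    tris <- rbind(tris, part$triangles + nrow(verts))
    verts <- rbind(verts, part$vertices)
  }
  end1 <- c(-d_in / 2, 0, 0) + (branch_length + d_in / 2) * c(cos(a), sin(a), 0)
  end2 <- c(-d_in / 2, 0, 0) + (branch_length + d_in / 2) * c(cos(a), -sin(a), 0)
  openings <- list(
    list(label = "inlet", centroid = c(-trunk_length, 0, 0), normal = c(-1, 0, 0),
         diameter = d_in),
    list(label = "outlet_1", centroid = end1, normal = c(cos(a), sin(a), 0),
         diameter = d_out1),
    list(label = "outlet_2", centroid = end2, normal = c(cos(a), -sin(a), 0),
         diameter = d_out2)
  )
  new_surface_geometry(verts, tris, comp, openings,
                       list(generator = "bifurcation", parent_diameter = d_in))
}

new_surface_geometry <- function(vertices, triangles, component, openings, metadata) {
  labs <- vapply(openings, `[[`, "", "label")
  if (length(openings)) {
    if (sum(labs == "inlet") != 1) stop("exactly one inlet opening is required")
    if (!any(grepl("^outlet", labs))) stop("at least one outlet opening is required")
    if (any(vapply(openings, `[[`, 0, "diameter") <= 0)) {
      stop("all opening diameters must be positive")
    }
  }
  structure(list(vertices = vertices, triangles = triangles,
                 component = component, openings = openings,
                 metadata = metadata),
            class = "surface_geometry")
}

# closed tube along a polyline centerline: rings + two cap fans
tessellate_tube <- function(centers, tangents, radius, n_seg) {
  n_r <- nrow(centers)
  theta <- seq(0, 2 * pi, length.out = n_seg + 1)[-(n_seg + 1)]
  up <- c(0, 0, 1)
  verts <- matrix(0, n_r * n_seg + 2, 3)
  for (j in seq_len(n_r)) {
    tj <- tangents[j, ]
    w <- c(tj[2], -tj[1], 0)           # in-plane normal (tangent x up)
    w <- w / sqrt(sum(w^2))
    ring <- radius * (outer(cos(theta), up) + outer(sin(theta), w))
    verts[(j - 1) * n_seg + seq_len(n_seg), ] <- sweep(ring, 2, centers[j, ], "+")
  }
  i_c0 <- n_r * n_seg + 1L; i_c1 <- n_r * n_seg + 2L
  verts[i_c0, ] <- centers[1, ]; verts[i_c1, ] <- centers[n_r, ]
  tris <- matrix(0L, 0, 3)
  side <- vector("list", n_r - 1)
  for (j in seq_len(n_r - 1)) {
    a <- (j - 1) * n_seg + seq_len(n_seg)
    b <- j * n_seg + seq_len(n_seg)
    a2 <- c(a[-1], a[1]); b2 <- c(b[-1], b[1])
    side[[j]] <- rbind(cbind(a, b, a2), cbind(a2, b, b2))
  }
  tris <- do.call(rbind, side)
  ring0 <- seq_len(n_seg); ring1 <- (n_r - 1) * n_seg + seq_len(n_seg)
  cap0 <- cbind(i_c0, c(ring0[-1], ring0[1]), ring0)
  cap1 <- cbind(i_c1, ring1, c(ring1[-1], ring1[1]))
  list(vertices = verts, triangles = rbind(tris, cap0, cap1))
}

# closed UV sphere, poles along +-z
tessellate_sphere <- function(center, radius, n_seg, n_lat) {
  phi <- seq(0, pi, length.out = n_lat + 1)[2:n_lat]
  theta <- seq(0, 2 * pi, length.out = n_seg + 1)[-(n_seg + 1)]
  verts <- matrix(0, (n_lat - 1) * n_seg + 2, 3)
  for (j in seq_along(phi)) {
    ring <- cbind(radius * sin(phi[j]) * cos(theta),
                  radius * sin(phi[j]) * sin(theta),
                  radius * cos(phi[j]))
    verts[(j - 1) * n_seg + seq_len(n_seg), ] <- sweep(ring, 2, center, "+")
  }
  i_top <- (n_lat - 1) * n_seg + 1L; i_bot <- (n_lat - 1) * n_seg + 2L
  verts[i_top, ] <- center + c(0, 0, radius)
  verts[i_bot, ] <- center - c(0, 0, radius)
  tris <- vector("list", n_lat)
  ring1 <- seq_len(n_seg)
  tris[[1]] <- cbind(i_top, ring1, c(ring1[-1], ring1[1]))
  for (j in seq_len(n_lat - 2)) {
    a <- (j - 1) * n_seg + seq_len(n_seg)
    b <- j * n_seg + seq_len(n_seg)
    a2 <- c(a[-1], a[1]); b2 <- c(b[-1], b[1])
    tris[[j + 1]] <- rbind(cbind(a, a2, b), cbind(a2, b2, b))
  }
  ringN <- (n_lat - 2) * n_seg + seq_len(n_seg)
  tris[[n_lat]] <- cbind(i_bot, c(ringN[-1], ringN[1]), ringN)
  list(vertices = verts, triangles = do.call(rbind, tris))
}

#' Extend vessel openings along their outward normals
#'
#' Extrudes every labeled opening by `n_diameters` local diameters so that
#' inlet/outlet boundary conditions act far from the region of interest. The
#' extrusion is added as an additional closed tube component that overlaps
#' the existing lumen slightly (the voxelizer classifies the union), and the
#' opening centroid moves to the new end cap; labels and diameters are
#' preserved.
#'
#' @param g a [surface_geometry].
#' @param n_diameters extrusion length in units of the local opening
#'   diameter (default 5).
#' @return the extended `surface_geometry`.
#' @export
extend_openings <- function(g, n_diameters = 5) {
  stopifnot(inherits(g, "surface_geometry"))
  if (n_diameters < 0) stop("n_diameters must be non-negative")
  if (n_diameters == 0) return(g)
  if (length(g$openings) == 0) stop("geometry has no labeled openings")
  verts <- g$vertices; tris <- g$triangles; comp <- g$component
  openings <- g$openings
  for (k in seq_along(openings)) {
    op <- openings[[k]]
    if (is.null(op$label) || is.null(op$diameter)) stop("unlabeled opening")
    len <- n_diameters * op$diameter
    overlap <- min(op$diameter / 2, 1)
    nrm <- op$normal / sqrt(sum(op$normal^2))
    p0 <- op$centroid - overlap * nrm
    n_ax <- max(4L, ceiling((len + overlap) / (op$diameter / 2)))
    s <- seq(0, len + overlap, length.out = n_ax + 1)
    centers <- sweep(outer(s, nrm), 2, p0, "+")
    tangents <- matrix(rep(nrm, each = n_ax + 1), ncol = 3)
    ext <- tessellate_tube(centers, tangents, op$diameter / 2, n_seg = 40L)
    comp <- c(comp, rep(max(comp) + 1L, nrow(ext$triangles)))
    tris <- rbind(tris, ext$triangles + nrow(verts))
    verts <- rbind(verts, ext$vertices)
    op$centroid <- op$centroid + len * nrm
    openings[[k]] <- op
  }
  meta <- g$metadata
  meta$extended_by_diameters <- n_diameters
  new_surface_geometry(verts, tris, comp, openings, meta)
}

#' Check that every component of a surface is closed
#'
#' A component is watertight when each undirected edge is shared by exactly
#' two triangles.
#'
#' @param g a [surface_geometry].
#' @return `TRUE` or `FALSE` (invisibly reports offending components).
#' @export
check_watertight <- function(g) {
  stopifnot(inherits(g, "surface_geometry"))
  ok <- TRUE
  for (cid in unique(g$component)) {
    tr <- g$triangles[g$component == cid, , drop = FALSE]
    e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    if (!all(table(key) == 2)) ok <- FALSE
  }
  ok
}

#' @export
print.surface_geometry <- function(x, ...) {
  labs <- vapply(x$openings, `[[`, "", "label")
  ds <- vapply(x$openings, `[[`, 0, "diameter")
  cat("<surface_geometry> ", nrow(x$vertices), " vertices, ",
      nrow(x$triangles), " triangles, ", length(unique(x$component)),
      " closed component(s)\n  openings: ",
      paste(sprintf("%s (d=%g mm)", labs, ds), collapse = ", "), "\n", sep = "")
  if (!is.null(x$metadata$ostium_plane)) {
    cat("  analytic ostium plane stored (sidewall sac, d_sac =",
        x$metadata$sac_diameter, "mm)\n")
  }
  invisible(x)
}
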