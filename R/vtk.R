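#' Export a voxel grid or flow field as legacy VTK for inspection
#'
#' Writes plain-text legacy VTK `STRUCTURED_POINTS`: the label field of a
#' [voxel_grid], optionally with the cycle-averaged speed of a flow field.
#'
#' @param grid a [voxel_grid].
#' @param path output `.vtk` path.
#' @param flow optional `flow_field` on the same grid.
#' @return `path`, invisibly.
#' @export
write_vtk_image <- function(grid, path, flow = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  dims <- dim(grid$labels)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "stentflow voxel grid", "ASCII",
               "DATASET STRUCTURED_POINTS",
               paste("DIMENSIONS", dims[1], dims[2], dims[3]),
               paste("ORIGIN", grid$origin[1], grid$origin[2], grid$origin[3]),
               paste("SPACING", grid$h, grid$h, grid$h),
               paste("POINT_DATA", prod(dims)),
               "SCALARS label int 1", "LOOKUP_TABLE default"), con)
  writeLines(paste(as.vector(grid$labels), collapse = " "), con)
  if (!is.null(flow)) {
    speed <- numeric(prod(dims))
    speed[flow$lin] <- flow$cycle_avg_speed
    writeLines(c("SCALARS mean_speed float 1", "LOOKUP_TABLE default"), con)
    writeLines(paste(format(speed, digits = 6, trim = TRUE), collapse = " "), con)
  }
  invisible(path)
}

#' Export a deployed stent as VTK polylines (plus a node CSV)
#'
#' @param stent a [deploy()]ed stent surface.
#' @param path output `.vtk` path; a sibling `.csv` of node positions is
#'   written alongside when `csv = TRUE`.
#' @param csv also write the node-position CSV.
#' @return `path`, invisibly.
#' @export
write_vtk_stent <- function(stent, path, csv = FALSE) {
  stopifnot(inherits(stent, "stent_surface"))
  p <- stent$node_positions
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "stentflow deployed stent", "ASCII",
               "DATASET POLYDATA", paste("POINTS", nrow(p), "float")), con)
  writeLines(apply(p, 1, function(r) paste(format(r, digits = 7), collapse = " ")), con)
  nseg <- length(stent$wires)
  sizes <- vapply(stent$wires, length, 0L)
  writeLines(paste("LINES", nseg, sum(sizes + 1L)), con)
  for (w in stent$wires) writeLines(paste(c(length(w), w - 1L), collapse = " "), con)
  if (csv) {
    write.csv(data.frame(x = p[, 1], y = p[, 2], z = p[, 3]),
              sub("\\.vtk$", ".csv", path), row.names = FALSE)
  }
  invisible(path)
}
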