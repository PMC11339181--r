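#' Write a surface geometry to STL
#'
#' Writes ASCII or binary STL. STL stores only a triangle soup, so the
#' opening labels (cap centroid, outward normal, diameter, label) are written
#' to a JSON sidecar file `<path>.openings.json`; [read_stl()] restores them.
#'
#' @param g a [surface_geometry].
#' @param path output file path (`.stl`).
#' @param ascii write ASCII STL (`TRUE`, default) or binary.
#' @param sidecar write the openings sidecar JSON (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_stl <- function(g, path, ascii = TRUE, sidecar = TRUE) {
  stopifnot(inherits(g, "surface_geometry"))
  v <- g$vertices; tr <- g$triangles
  e1 <- v[tr[, 2], ] - v[tr[, 1], ]; e2 <- v[tr[, 3], ] - v[tr[, 1], ]
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid stentflow", con)
    for (t in seq_len(nrow(tr))) {
      writeLines(c(
        sprintf("  facet normal %.9g %.9g %.9g", nrm[t, 1], nrm[t, 2], nrm[t, 3]),
        "    outer loop",
        sprintf("      vertex %.9g %.9g %.9g",
                v[tr[t, ], 1], v[tr[t, ], 2], v[tr[t, ], 3]),
        "    endloop", "  endfacet"), con)
    }
    writeLines("endsolid stentflow", con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nrow(tr)), con, size = 4, endian = "little")
    for (t in seq_len(nrow(tr))) {
      writeBin(as.numeric(c(nrm[t, ], t(v[tr[t, ], ]))), con, size = 4,
               endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  }
  if (sidecar && length(g$openings)) {
    jsonlite::write_json(
      lapply(g$openings, function(op) {
        list(label = op$label, centroid = op$centroid, normal = op$normal,
             diameter = op$diameter)
      }),
      paste0(path, ".openings.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read an STL surface
#'
#' Reads ASCII or binary STL (auto-detected), merges duplicate facet
#' vertices, reconstructs closed components from triangle connectivity, and
#' restores opening labels from the JSON sidecar if present. Imported
#' surfaces are checked for watertightness, not repaired.
#'
#' @param path STL file path.
#' @param sidecar path of the openings sidecar; default `<path>.openings.json`.
#' @return a [surface_geometry].
#' @export
read_stl <- function(path, sidecar = paste0(path, ".openings.json")) {
  hdr <- readBin(path, "raw", n = 5)
  is_ascii <- identical(rawToChar(hdr), "solid") && {
    # binary STLs may also start with 'solid'; verify by size bookkeeping
    con <- file(path, "rb"); on.exit(close(con))
    seek(con, 80); nt <- readBin(con, "integer", size = 4, endian = "little")
    file.size(path) != 84 + 50 * as.numeric(nt)
  }
  if (is_ascii) {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x) {
      as.numeric(x[2:4])
    }))
  } else {
    con2 <- file(path, "rb")
    on.exit(close(con2), add = TRUE)
    seek(con2, 80)
    nt <- readBin(con2, "integer", size = 4, endian = "little")
    nums <- matrix(0, 3 * nt, 3)
    for (t in seq_len(nt)) {
      rec <- readBin(con2, "numeric", n = 12, size = 4, endian = "little")
      readBin(con2, "integer", n = 1, size = 2, endian = "little")
      nums[3 * (t - 1) + 1:3, ] <- matrix(rec[4:12], 3, byrow = TRUE)
    }
  }
  if (nrow(nums) %% 3 != 0) stop("malformed STL: vertex count not divisible by 3")
  key <- apply(round(nums, 6), 1, paste, collapse = ",")
  uid <- match(key, unique(key))
  verts <- nums[!duplicated(key), , drop = FALSE]
  tris <- matrix(uid, ncol = 3, byrow = TRUE)
  comp <- triangle_components(tris, nrow(verts))
  openings <- list()
  if (file.exists(sidecar)) {
    raw_ops <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    openings <- lapply(seq_len(nrow(raw_ops)), function(i) {
      list(label = raw_ops$label[i], centroid = unlist(raw_ops$centroid[i]),
           normal = unlist(raw_ops$normal[i]), diameter = raw_ops$diameter[i])
    })
    # keep inlet first (boundary label codes follow opening order)
    openings <- openings[order(vapply(openings, `[[`, "", "label") != "inlet")]
  }
  g <- structure(list(vertices = verts, triangles = tris, component = comp,
                      openings = openings, metadata = list(generator = "stl")),
                 class = "surface_geometry")
  if (!check_watertight(g)) {
    warning("imported STL is not watertight; voxelize() will refuse it")
  }
  g
}

# connected components of triangles via shared EDGES (union-find over
# triangles); closed components that merely touch at isolated vertices stay
# separate, which the union-of-closed-components voxelizer requires
triangle_components <- function(tris, n_verts) {
  nt <- nrow(tris)
  parent <- seq_len(nt)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  keys <- c(edge_key(tris[, 1], tris[, 2]),
            edge_key(tris[, 2], tris[, 3]),
            edge_key(tris[, 3], tris[, 1]))
  tri_of <- rep(seq_len(nt), 3)
  grp <- split(tri_of, keys)
  for (g in grp) {
    if (length(g) > 1) {
      r <- find(g[1])
      for (t in g[-1]) parent[find(t)] <- r
    }
  }
  roots <- vapply(seq_len(nt), find, 0L)
  match(roots, unique(roots))
}
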