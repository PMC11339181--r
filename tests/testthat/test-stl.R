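test_that("STL round-trips in both encodings with labels intact", {
  g <- make_sidewall_aneurysm(4, 8, 4, 20)
  for (ascii in c(TRUE, FALSE)) {
    path <- tempfile(fileext = ".stl")
    write_stl(g, path, ascii = ascii)
    g2 <- read_stl(path)
    expect_identical(nrow(g2$triangles), nrow(g$triangles))
    expect_identical(length(unique(g2$component)), 2L)
    expect_true(check_watertight(g2))
    labs <- vapply(g2$openings, `[[`, "", "label")
    expect_identical(labs[1], "inlet")
    # voxelization of the re-imported surface matches the original
    expect_identical(sum(voxelize(g2, 0.4)$labels != 0L),
                     sum(voxelize(g, 0.4)$labels != 0L))
    unlink(c(path, paste0(path, ".openings.json")))
  }
})

test_that("imported non-watertight surfaces are flagged, not repaired", {
  g <- make_sidewall_aneurysm(4, 0, 0, 10)
  g$triangles <- g$triangles[-1, , drop = FALSE]   # puncture the surface
  g$component <- g$component[-1]
  path <- tempfile(fileext = ".stl")
  write_stl(g, path, ascii = TRUE, sidecar = FALSE)
  expect_warning(g2 <- read_stl(path), "watertight")
  expect_error(voxelize(g2, 0.4), "watertight")
  unlink(path)
})

test_that("voxel grids and stents export to legacy VTK text files", {
  g <- make_sidewall_aneurysm(4, 8, 4, 16)
  grid <- voxelize(g, 0.4)
  p1 <- tempfile(fileext = ".vtk")
  write_vtk_image(grid, p1)
  head <- readLines(p1, n = 5)
  expect_match(head[1], "vtk DataFile")
  expect_match(head[4], "STRUCTURED_POINTS")
  st <- deploy(build_braid(16, 4, 6, 60), vessel = list(diameter = 4, length = 16))
  p2 <- tempfile(fileext = ".vtk")
  write_vtk_stent(st, p2, csv = TRUE)
  expect_match(readLines(p2, n = 4)[4], "POLYDATA")
  expect_true(file.exists(sub("\\.vtk$", ".csv", p2)))
  unlink(c(p1, p2, sub("\\.vtk$", ".csv", p2)))
})
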