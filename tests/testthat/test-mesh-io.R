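test_that("a minimal ASCII STL parses to one open triangle", {
  path <- withr::local_tempfile(fileext = ".stl")
  writeLines(c(
    "solid one",
    " facet normal 0 0 1",
    "  outer loop",
    "   vertex 0 0 0",
    "   vertex 1 0 0",
    "   vertex 0 1 0",
    "  endloop",
    " endfacet",
    "endsolid one"
  ), path)
  m <- read_mesh(path)
  expect_equal(nrow(m$vertices), 3)
  expect_equal(nrow(m$faces), 1)
  expect_setequal(m$boundary_vertices, 1:3)
})

test_that("malformed STL errors name the offending line", {
  path <- withr::local_tempfile(fileext = ".stl")
  writeLines(c(
    "solid bad",
    " facet normal 0 0 1", "  outer loop",
    "   vertex 0 0 0", "   vertex 1 0 zero", "   vertex 0 1 0",
    "  endloop", " endfacet", "endsolid bad"
  ), path)
  expect_error(read_mesh(path), "line 5")
})

test_that("STL and PLY round-trip preserves topology and geometry", {
  face <- test_face()

  # PLY stores an indexed vertex list: round-trip is exactly identical
  ply <- withr::local_tempfile(fileext = ".ply")
  write_mesh(face$mesh, ply, format = "ply")
  back_ply <- read_mesh(ply)
  expect_identical(back_ply$faces, face$mesh$faces)
  expect_lt(max(abs(back_ply$vertices - face$mesh$vertices)), 1e-5)

  # STL stores a facet soup: vertices are re-ordered by first appearance,
  # so compare per-facet corner coordinates (facet order is preserved)
  stl <- withr::local_tempfile(fileext = ".stl")
  write_mesh(face$mesh, stl, format = "stl")
  back_stl <- read_mesh(stl)
  expect_equal(nrow(back_stl$vertices), nrow(face$mesh$vertices))
  expect_equal(nrow(back_stl$faces), nrow(face$mesh$faces))
  corner_coords <- function(m) {
    cbind(m$vertices[m$faces[, 1], ], m$vertices[m$faces[, 2], ],
          m$vertices[m$faces[, 3], ])
  }
  expect_lt(max(abs(corner_coords(back_stl) - corner_coords(face$mesh))),
            1e-5)
})

test_that("a closed cube has no boundary vertices; an open patch does", {
  cube <- unit_cube_mesh()
  expect_length(cube$boundary_vertices, 0)
  # independent enumeration: every cube edge must appear in exactly 2 faces
  e <- rbind(cube$faces[, c(1, 2)], cube$faces[, c(2, 3)],
             cube$faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  expect_true(all(table(key) == 2))
  patch <- grid_patch_mesh(4, 4)
  expect_gt(length(patch$boundary_vertices), 0)
})

test_that("degenerate faces are dropped with a message", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_message(m <- surface_mesh(v, rbind(c(1, 2, 3), c(1, 1, 2))),
                 "1 degenerate")
  expect_equal(nrow(m$faces), 1)
})

test_that("vertex normals are unit length and match a flat patch's plane", {
  patch <- grid_patch_mesh(6, 6)
  expect_equal(sqrt(rowSums(patch$vertex_normals^2)),
               rep(1, nrow(patch$vertices)), tolerance = 1e-9)
  expect_lt(max(abs(sweep(patch$vertex_normals, 2, c(0, 0, 1)))), 1e-6)
  face <- test_face()
  expect_equal(sqrt(rowSums(face$mesh$vertex_normals^2)),
               rep(1, nrow(face$mesh$vertices)), tolerance = 1e-6)
})

test_that("duplicate vertices merge so shared edges connect", {
  # two triangles written as an STL-style soup sharing an edge
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
             c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  mg <- merge_duplicate_vertices(v, rbind(1:3, 4:6))
  expect_equal(nrow(mg$vertices), 4)
  m <- surface_mesh(mg$vertices, mg$faces)
  # the shared diagonal is interior, the four outer edges are boundary
  expect_length(m$boundary_vertices, 4)
})

test_that("PLY carries vertex colours losslessly and STL refuses them", {
  patch <- grid_patch_mesh(4, 4)
  cols <- matrix(rep(c(120, 120, 120), each = nrow(patch$vertices)),
                 ncol = 3)
  path <- withr::local_tempfile(fileext = ".ply")
  write_mesh(patch, path, vertex_colors = cols)
  back <- read_mesh(path)
  expect_equal(attr(back, "vertex_colors"), cols, ignore_attr = TRUE)
  expect_error(
    write_mesh(patch, withr::local_tempfile(fileext = ".stl"),
               vertex_colors = cols),
    "colour"
  )
})

test_that("a 3-vertex mesh writes exactly one STL facet record", {
  m <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                    matrix(1:3, 1))
  path <- withr::local_tempfile(fileext = ".stl")
  write_mesh(m, path)
  expect_equal(sum(grepl("facet normal", readLines(path))), 1)
})

test_that("binary STL is auto-detected and read", {
  # write a tiny binary STL by hand
  path <- withr::local_tempfile(fileext = ".stl")
  con <- file(path, "wb")
  writeBin(raw(80), con)
  writeBin(2L, con, size = 4, endian = "little")
  tri <- list(
    rbind(c(0, 0, 1), c(0, 0, 0), c(2, 0, 0), c(0, 2, 0)),
    rbind(c(0, 0, 1), c(2, 0, 0), c(2, 2, 0), c(0, 2, 0))
  )
  for (t in tri) {
    writeBin(as.numeric(t(t)), con, size = 4, endian = "little")
    writeBin(as.raw(c(0, 0)), con)
  }
  close(con)
  m <- read_mesh(path)
  expect_equal(nrow(m$faces), 2)
  expect_equal(nrow(m$vertices), 4)  # shared edge merged
})
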