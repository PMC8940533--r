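test_that("closed and bordered meshes get the right boundary sets", {
  ico <- icosphere(0)
  expect_equal(nrow(ico$vertices), 12)
  expect_equal(nrow(ico$triangles), 20)
  expect_length(ico$boundary_vertices, 0)

  tri <- surf_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                   rbind(c(1, 2, 3)))
  expect_equal(tri$boundary_vertices, 1:3)

  # 5x5 vertex grid: 32 triangles, all 16 perimeter vertices on boundary
  g <- flat_grid(5, 5)
  expect_equal(nrow(g$triangles), 32)
  expect_length(g$boundary_vertices, 16)
  # oracle: endpoints of edges adjacent to exactly one triangle
  ed <- surfgpc:::mesh_edges(g$triangles)
  expect_setequal(g$boundary_vertices,
                  unique(c(ed$v1[ed$count == 1], ed$v2[ed$count == 1])))
})

test_that("invalid meshes are rejected with diagnostics", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1))
  expect_error(surf_mesh(v, rbind(c(1, 2, 6))), "out of range")
  expect_error(surf_mesh(v, rbind(c(1, 2, 2))), "repeated")
  expect_error(surf_mesh(rbind(v, c(0.5, 0.5, 0)),
                         rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5))),
               "non-manifold")
  # zero-area triangle
  expect_error(surf_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                               c(0, 1, 0)),
                         rbind(c(1, 2, 3), c(1, 2, 4))), "degenerate")
  # two disconnected components
  v2 <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
              c(5, 5, 5), c(6, 5, 5), c(5, 6, 5))
  expect_error(surf_mesh(v2, rbind(c(1, 2, 3), c(4, 5, 6))),
               "connected component")
})

test_that("geometry normalization divides by the largest per-axis sd", {
  m <- icosphere(1, radius = 1)
  n1 <- normalize_geometry(m)
  # oracle: the divisor is the max per-axis standard deviation
  s <- max(apply(m$vertices, 2, sd))
  expect_equal(n1$normalization_scale, s)
  expect_equal(n1$vertices, m$vertices / s)
  # unit sphere: per-axis sd ~ 1/sqrt(3)
  expect_equal(s, 1 / sqrt(3), tolerance = 0.02)
  # idempotence
  n2 <- normalize_geometry(n1)
  expect_equal(n2$vertices, n1$vertices, tolerance = 1e-12)
  # scale equivariance: 7x coordinates give the same normalized mesh
  m7 <- surf_mesh(m$vertices * 7, m$triangles)
  n7 <- normalize_geometry(m7)
  expect_equal(n7$vertices, n1$vertices, tolerance = 1e-12)
  expect_equal(n7$normalization_scale / n1$normalization_scale, 7,
               tolerance = 1e-12)
  # degenerate: all vertices coincident is caught upstream (zero area),
  # so check the sd guard via a direct call on a doctored object
  degen <- n1
  degen$vertices[] <- 1
  expect_error(normalize_geometry(degen), "zero standard deviation")
})

test_that("mesh file formats round-trip through the readers", {
  m <- icosphere(0)
  td <- withr::local_tempdir()

  off <- file.path(td, "m.off")
  writeLines(c("OFF", paste(nrow(m$vertices), nrow(m$triangles), 0),
               apply(m$vertices, 1, paste, collapse = " "),
               apply(m$triangles - 1L, 1, function(r)
                 paste(c(3, r), collapse = " "))), off)
  m_off <- read_mesh(off)
  expect_equal(m_off$vertices, m$vertices, ignore_attr = TRUE)
  expect_equal(m_off$triangles, m$triangles, ignore_attr = TRUE)

  ply <- file.path(td, "m.ply")
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(m$vertices)),
               "property float x", "property float y", "property float z",
               paste("element face", nrow(m$triangles)),
               "property list uchar int vertex_indices", "end_header",
               apply(m$vertices, 1, paste, collapse = " "),
               apply(m$triangles - 1L, 1, function(r)
                 paste(c(3, r), collapse = " "))), ply)
  m_ply <- read_mesh(ply)
  expect_equal(m_ply$triangles, m$triangles, ignore_attr = TRUE)

  vtk <- file.path(td, "m.vtk")
  write_vtk(m, vtk, point_data = list(height = m$vertices[, 3]))
  m_vtk <- read_mesh(vtk)
  expect_equal(m_vtk$vertices, m$vertices, ignore_attr = TRUE)
  expect_equal(m_vtk$triangles, m$triangles, ignore_attr = TRUE)

  stl <- file.path(td, "m.stl")
  tri_txt <- unlist(lapply(seq_len(nrow(m$triangles)), function(t) {
    p <- m$vertices[m$triangles[t, ], , drop = FALSE]
    c("facet normal 0 0 0", "outer loop",
      apply(p, 1, function(r) paste("vertex", paste(sprintf("%.17g", r),
                                                    collapse = " "))),
      "endloop", "endfacet")
  }))
  writeLines(c("solid m", tri_txt, "endsolid m"), stl)
  m_stl <- read_mesh(stl)
  expect_equal(nrow(m_stl$vertices), nrow(m$vertices))
  expect_equal(nrow(m_stl$triangles), nrow(m$triangles))
  # same surface area after vertex merging
  expect_equal(sum(surfgpc:::triangle_areas(m_stl$vertices,
                                            m_stl$triangles)),
               sum(surfgpc:::triangle_areas(m$vertices, m$triangles)),
               tolerance = 1e-12)

  expect_error(read_mesh(file.path(td, "missing.off")), "not found")
  bad <- file.path(td, "bad.off")
  writeLines(c("OFF", "4 1 0", "0 0 0", "1 0 0", "0 1 0", "0 0 1",
               "4 0 1 2 3"), bad)
  expect_error(read_mesh(bad), "non-triangle")
})

test_that("mesh checksum tracks geometry and connectivity", {
  m <- icosphere(1)
  expect_identical(mesh_checksum(m), mesh_checksum(m))
  m2 <- surf_mesh(m$vertices * 1.001, m$triangles)
  expect_false(identical(mesh_checksum(m), mesh_checksum(m2)))
})
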