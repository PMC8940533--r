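test_that("FEM matrices match closed forms on a unit equilateral triangle", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  fem <- assemble_fem(surf_mesh(v, rbind(c(1, 2, 3))))
  A <- as.matrix(fem$stiffness)
  M <- as.matrix(fem$mass)
  # cotangent Laplacian of a single equilateral triangle
  expect_equal(diag(A), rep(1 / sqrt(3), 3), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(A[lower.tri(A)], rep(-1 / (2 * sqrt(3)), 3),
               tolerance = 1e-12)
  # total mass = triangle area
  expect_equal(sum(M), sqrt(3) / 4, tolerance = 1e-12)
  # consistent mass pattern: off-diagonals half the diagonal
  expect_equal(M[1, 2] / M[1, 1], 0.5, tolerance = 1e-12)
})

test_that("stiffness has constants in its null space and mass sums to area", {
  for (m in list(icosphere(2), flat_grid(7, 5, 2, 1), torus_mesh(12, 8))) {
    fem <- assemble_fem(m)
    expect_lt(max(abs(Matrix::rowSums(fem$stiffness))), 1e-10)
    expect_equal(sum(fem$mass),
                 sum(surfgpc:::triangle_areas(m$vertices, m$triangles)),
                 tolerance = 1e-12)
    ev <- eigen(as.matrix(fem$stiffness), symmetric = TRUE,
                only.values = TRUE)$values
    expect_gt(min(ev), -1e-10 * max(ev))
  }
})

test_that("eigenbasis is mass-orthonormal with a constant first mode", {
  b <- ico2_basis()
  fem <- assemble_fem(b$mesh)
  G <- as.matrix(Matrix::crossprod(b$vectors, fem$mass %*% b$vectors))
  expect_lt(max(abs(G - diag(b$n_eig))), 1e-8)
  expect_equal(b$values[1], 0, tolerance = 1e-9)
  expect_lt(diff(range(b$vectors[, 1])), 1e-7 * max(abs(b$vectors[, 1])))
  expect_true(!is.unsorted(b$values))
})

test_that("sphere spectrum approaches l(l+1) with the right multiplicities", {
  m <- icosphere(3)
  b <- solve_eigenbasis(assemble_fem(m), 10, mesh = m)
  expect_equal(b$values[1], 0, tolerance = 1e-8)
  expect_equal(b$values[2:4], rep(2, 3), tolerance = 0.02)
  expect_equal(b$values[5:9], rep(6, 5), tolerance = 0.02)
})

test_that("square-patch spectrum matches the Neumann closed form", {
  m <- flat_grid(25, 25, 1, 1)
  b <- solve_eigenbasis(assemble_fem(m), 7, mesh = m)
  exact <- pi^2 * c(0, 1, 1, 2, 4, 4, 5)   # pi^2 (m^2 + n^2)
  expect_equal(b$values[-1], exact[-1], tolerance = 0.03)
})

test_that("eigenvalues scale as 1/s^2 under mesh scaling", {
  m <- icosphere(1)
  b1 <- solve_eigenbasis(assemble_fem(m), 12, mesh = m)
  ms <- surf_mesh(m$vertices * 3, m$triangles)
  b3 <- solve_eigenbasis(assemble_fem(ms), 12, mesh = ms)
  expect_equal(b3$values[-1], b1$values[-1] / 9, tolerance = 1e-8)
})

test_that("sphere eigenvalue error decreases monotonically with refinement", {
  exact <- c(2, 2, 2, 6, 6, 6, 6, 6)
  err <- vapply(1:3, function(l) {
    m <- icosphere(l)
    b <- solve_eigenbasis(assemble_fem(m), 9, mesh = m)
    max(abs(b$values[2:9] - exact) / exact)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("eigen-solver input validation and reproducible signs", {
  m <- icosphere(1)
  fem <- assemble_fem(m)
  expect_error(solve_eigenbasis(fem, nrow(m$vertices), mesh = m), "n_eig")
  b1 <- solve_eigenbasis(fem, 15, mesh = m)
  b2 <- solve_eigenbasis(fem, 15, mesh = m)
  expect_identical(b1$vectors, b2$vectors)
  for (k in seq_len(15)) {
    expect_gt(b1$vectors[which.max(abs(b1$vectors[, k])), k], 0)
  }
})

test_that("sparse and dense eigen-solvers agree", {
  skip_if_not_installed("RSpectra")
  m <- icosphere(2)
  fem <- assemble_fem(m)
  bd <- solve_eigenbasis(fem, 20, mesh = m, method = "dense")
  bs <- solve_eigenbasis(fem, 20, mesh = m, method = "sparse")
  # the last computed pair may sit inside a degenerate cluster cut off by
  # the truncation; compare the well-separated leading part
  expect_equal(bs$values[1:16], bd$values[1:16], tolerance = 1e-7)
  # eigenvectors agree up to sign within degenerate clusters: compare
  # the projector onto the first nontrivial eigenspace
  P1 <- bd$vectors[, 2:4] %*% t(bd$vectors[, 2:4])
  P2 <- bs$vectors[, 2:4] %*% t(bs$vectors[, 2:4])
  expect_equal(P2, P1, tolerance = 1e-6)
})

test_that("basis cache is reused only for the same mesh", {
  b <- ico2_basis()
  td <- withr::local_tempdir()
  p <- file.path(td, "basis.rds")
  save_basis_cache(b, p)
  expect_equal(load_basis_cache(p, b$mesh)$values, b$values)
  other <- normalize_geometry(icosphere(1))
  expect_error(load_basis_cache(p, other), "checksum")
})
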