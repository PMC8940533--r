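#' Assemble finite-element stiffness and mass matrices on a surface mesh
#'
#' Builds the sparse stiffness matrix `A` (the cotangent Laplacian,
#' discretizing the Laplace-Beltrami operator with natural/Neumann
#' boundary conditions) and the consistent mass matrix `M` from linear
#' shape functions on each triangle, summed over elements. Constants lie
#' in the null space of `A` (row sums are zero); the total sum of the
#' entries of `M` equals the surface area of the mesh.
#'
#' @param mesh a [surf_mesh()].
#' @param lump if `TRUE`, return the lumped (row-sum diagonal) mass matrix
#'   instead of the consistent one. The consistent matrix is the default.
#' @return An object of class `fem_matrices`: list with sparse symmetric
#'   matrices `stiffness` and `mass` (`Matrix::dsCMatrix`).
#' @export
assemble_fem <- function(mesh, lump = FALSE) {
  stopifnot(inherits(mesh, "surf_mesh"))
  v <- mesh$vertices; tr <- mesh$triangles
  ar <- triangle_areas(v, tr)
  degen <- ar < 1e-12 * mean(ar)
  if (any(degen))
    stop("degenerate triangle ", which(degen)[1], " (area ", ar[which(degen)[1]],
         ") below assembly tolerance")
  # edge vectors opposite each local vertex: e1 = p3-p2, e2 = p1-p3, e3 = p2-p1
  p1 <- v[tr[, 1], , drop = FALSE]
  p2 <- v[tr[, 2], , drop = FALSE]
  p3 <- v[tr[, 3], , drop = FALSE]
  e1 <- p3 - p2; e2 <- p1 - p3; e3 <- p2 - p1
  dot <- function(a, b) rowSums(a * b)
  # local stiffness K_ab = (e_a . e_b) / (4 A)
  k11 <- dot(e1, e1) / (4 * ar); k22 <- dot(e2, e2) / (4 * ar)
  k33 <- dot(e3, e3) / (4 * ar)
  k12 <- dot(e1, e2) / (4 * ar); k13 <- dot(e1, e3) / (4 * ar)
  k23 <- dot(e2, e3) / (4 * ar)
  ii <- c(tr[, 1], tr[, 2], tr[, 3], tr[, 1], tr[, 2], tr[, 1], tr[, 3],
          tr[, 2], tr[, 3])
  jj <- c(tr[, 1], tr[, 2], tr[, 3], tr[, 2], tr[, 1], tr[, 3], tr[, 1],
          tr[, 3], tr[, 2])
  kk <- c(k11, k22, k33, k12, k12, k13, k13, k23, k23)
  nv <- nrow(v)
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = kk, dims = c(nv, nv))
  # consistent mass: area/12 * [2 1 1; 1 2 1; 1 1 2]
  mm <- c(rep(ar / 6, 3), rep(ar / 12, 6))
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = mm, dims = c(nv, nv))
  if (lump) {
    M <- Matrix::Diagonal(nv, Matrix::rowSums(M))
  }
  structure(list(stiffness = Matrix::forceSymmetric(A),
                 mass = Matrix::forceSymmetric(M)),
            class = "fem_matrices")
}

#' Solve the generalized Laplace-Beltrami eigenproblem
#'
#' Computes the `n_eig` smallest-eigenvalue solutions of
#' `A v = lambda M v` for the FEM stiffness/mass pair, i.e. the discrete
#' Neumann eigenfunctions of the Laplace-Beltrami operator on the surface.
#' Eigenvectors are returned mass-orthonormal
#' (`t(Psi) %*% M %*% Psi = I`), eigenvalues ascending, with the sign of
#' each eigenvector fixed so its largest-magnitude entry is positive, so a
#' given mesh always yields the same reproducible basis.
#'
#' @param fem a `fem_matrices` object from [assemble_fem()], or a
#'   [surf_mesh()] (assembled on the fly).
#' @param n_eig number of eigenpairs, must be `< n_vertices`.
#' @param mesh the mesh the matrices came from (required when `fem` is a
#'   `fem_matrices`; used to attach geometry to the basis).
#' @param method `"dense"` (whitened full symmetric solve, exact and
#'   deterministic), `"sparse"` (shift-invert Lanczos via RSpectra, for
#'   large meshes), or `"auto"` (sparse when the mesh has more than 1500
#'   vertices and RSpectra is installed).
#'
#' @return An object of class `spectral_basis`: list with `values`
#'   (length `n_eig`, ascending, first ~0), `vectors`
#'   (`n_vertices x n_eig`), `n_eig`, `vertex_areas` (lumped mass row
#'   sums), `total_area`, `mesh` and `mesh_checksum`.
#' @export
solve_eigenbasis <- function(fem, n_eig, mesh = NULL,
                             method = c("auto", "dense", "sparse")) {
  method <- match.arg(method)
  if (inherits(fem, "surf_mesh")) {
    mesh <- fem
    fem <- assemble_fem(mesh)
  }
  stopifnot(inherits(fem, "fem_matrices"), inherits(mesh, "surf_mesh"))
  A <- fem$stiffness; M <- fem$mass
  nv <- nrow(A)
  n_eig <- as.integer(n_eig)
  if (n_eig < 1L) stop("n_eig must be positive")
  if (n_eig >= nv) stop("n_eig must be < number of vertices (", nv, ")")
  if (method == "auto") {
    method <- if (nv > 1500L && n_eig < nv / 2 &&
                  requireNamespace("RSpectra", quietly = TRUE))
      "sparse" else "dense"
  }
  if (method == "sparse" && !requireNamespace("RSpectra", quietly = TRUE)) {
    method <- "dense"
  }
  res <- if (method == "dense") eig_dense(A, M, n_eig) else
    eig_sparse(A, M, n_eig)
  vals <- res$values
  vecs <- res$vectors
  if (min(vals) < -1e-6 * max(abs(vals)))
    stop("eigen-solver returned significantly negative eigenvalue: ",
         min(vals))
  vals <- pmax(vals, 0)
  # reproducible sign: largest-magnitude entry of each eigenvector positive
  for (k in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, k]))
    if (vecs[i, k] < 0) vecs[, k] <- -vecs[, k]
  }
  areas <- as.numeric(Matrix::rowSums(M))
  structure(list(values = vals, vectors = vecs, n_eig = n_eig,
                 vertex_areas = areas,
                 # lumped-quadrature norms of the eigenfunctions, ~1 each;
                 # used so the kernel normalizer makes the vertex-area-weighted
                 # marginal variance exactly eta^2
                 lumped_norms = as.numeric(colSums(vecs^2 * areas)),
                 total_area = sum(M),
                 mesh = mesh, mesh_checksum = mesh_checksum(mesh)),
            class = "spectral_basis")
}

# dense whitened solve: M = U'U, B = U^{-T} A U^{-1}, eigen(B)
eig_dense <- function(A, M, n_eig) {
  Ad <- as.matrix(A); Md <- as.matrix(M)
  U <- chol(Md)
  S1 <- backsolve(U, Ad, transpose = TRUE)       # U^{-T} A
  B <- t(backsolve(U, t(S1), transpose = TRUE))  # U^{-T} A U^{-1}
  B <- (B + t(B)) / 2
  eg <- eigen(B, symmetric = TRUE)
  idx <- rev(seq(nrow(Ad) - n_eig + 1L, nrow(Ad)))
  vals <- eg$values[idx]
  vecs <- backsolve(U, eg$vectors[, idx, drop = FALSE])
  list(values = vals, vectors = vecs)
}

# shift-invert Lanczos on C = W' (A + sigma M)^{-1} W with M = W W',
# eigenvalues mu = 1/(lambda + sigma); polished by dense Rayleigh-Ritz.
eig_sparse <- function(A, M, n_eig) {
  nv <- nrow(A)
  sigma <- 1e-8 * mean(Matrix::diag(A))
  ch_m <- Matrix::Cholesky(M, perm = TRUE, LDL = FALSE)
  ex <- Matrix::expand(ch_m)
  W <- Matrix::t(ex$P) %*% ex$L                  # M = W W'
  AsM <- A + sigma * M
  ch_a <- Matrix::Cholesky(AsM, perm = TRUE, LDL = FALSE)
  opfun <- function(x, args = NULL) {
    as.numeric(Matrix::crossprod(
      W, Matrix::solve(ch_a, W %*% x, system = "A")))
  }
  eg <- RSpectra::eigs_sym(opfun, k = n_eig, n = nv, which = "LM",
                           opts = list(tol = 1e-10, maxitr = 5000))
  if (length(eg$values) < n_eig)
    stop("sparse eigen-solver did not converge to ", n_eig, " pairs")
  V <- as.matrix(Matrix::solve(ch_a, W %*% eg$vectors, system = "A"))
  # Rayleigh-Ritz polish in the recovered subspace
  At <- crossprod(V, as.matrix(A %*% V))
  Mt <- crossprod(V, as.matrix(M %*% V))
  Us <- chol((Mt + t(Mt)) / 2)
  Bs <- t(backsolve(Us, t(backsolve(Us, (At + t(At)) / 2, transpose = TRUE)),
                    transpose = TRUE))
  egs <- eigen((Bs + t(Bs)) / 2, symmetric = TRUE)
  ord <- rev(seq_along(egs$values))
  vals <- egs$values[ord][seq_len(n_eig)]
  coef <- backsolve(Us, egs$vectors)[, ord, drop = FALSE][, seq_len(n_eig),
                                                          drop = FALSE]
  list(values = vals, vectors = V %*% coef)
}

#' @export
print.spectral_basis <- function(x, ...) {
  cat(sprintf("spectral_basis: %d eigenpairs on %d vertices\n",
              x$n_eig, nrow(x$vectors)))
  cat(sprintf("  eigenvalue range: [%g, %g], total area %g\n",
              min(x$values), max(x$values), x$total_area))
  invisible(x)
}

#' Save / load a spectral basis cache
#'
#' The eigen-decomposition is the one expensive pre-processing step, so it
#' can be cached to disk and reused. The cache stores the mesh checksum and
#' is refused (never silently reused) if it does not match the mesh it is
#' loaded for.
#'
#' @param basis a `spectral_basis`.
#' @param path cache file path.
#' @return `path` (save) or the `spectral_basis` (load).
#' @export
save_basis_cache <- function(basis, path) {
  stopifnot(inherits(basis, "spectral_basis"))
  saveRDS(basis, path)
  invisible(path)
}

#' @rdname save_basis_cache
#' @param mesh the mesh the basis must belong to.
#' @export
load_basis_cache <- function(path, mesh) {
  basis <- readRDS(path)
  if (!inherits(basis, "spectral_basis")) stop("not a basis cache: ", path)
  if (!identical(basis$mesh_checksum, mesh_checksum(mesh)))
    stop("basis cache checksum does not match mesh; recompute the basis")
  basis
}
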