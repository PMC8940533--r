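#' Precompute factorizations for heat-method geodesic distances
#'
#' The heat method computes approximate geodesic distance in three steps:
#' integrate heat flow from a source indicator for a short time `t`
#' (backward Euler: solve `(M + t A) u = u0`), normalize the negated
#' per-triangle gradient of `u` to obtain a unit vector field pointing
#' away from the source, and recover the distance by solving a Poisson
#' equation with the integrated divergence of that field. Both linear
#' systems are prefactored here, so each distance field costs only two
#' triangular solves plus a gradient/divergence sweep.
#'
#' @param mesh a [surf_mesh()].
#' @param t_coef heat time as a multiple of the squared mean edge length
#'   (default 1, the standard choice).
#' @return an object of class `geodesic_solver`.
#' @export
geodesic_solver <- function(mesh, t_coef = 1) {
  stopifnot(inherits(mesh, "surf_mesh"))
  fem <- assemble_fem(mesh, lump = TRUE)
  A <- fem$stiffness
  M <- fem$mass
  v <- mesh$vertices; tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  elen <- sqrt(rowSums((v[e[, 1], ] - v[e[, 2], ])^2))
  t_heat <- t_coef * mean(elen)^2
  ch_heat <- Matrix::Cholesky(Matrix::forceSymmetric(M + t_heat * A),
                              perm = TRUE, LDL = FALSE)
  # Poisson operator: A is singular (Neumann); tiny mass shift pins it
  eps <- 1e-10 * mean(Matrix::diag(A))
  ch_pois <- Matrix::Cholesky(Matrix::forceSymmetric(
    A + eps * Matrix::Diagonal(nrow(A))), perm = TRUE, LDL = FALSE)

  # geometry caches for gradient/divergence sweeps
  p1 <- v[tr[, 1], , drop = FALSE]
  p2 <- v[tr[, 2], , drop = FALSE]
  p3 <- v[tr[, 3], , drop = FALSE]
  nrm <- cross3(p2 - p1, p3 - p1)
  dblA <- sqrt(rowSums(nrm^2))
  nrm <- nrm / dblA
  structure(list(mesh = mesh, stiffness = A, t_heat = t_heat,
                 ch_heat = ch_heat, ch_pois = ch_pois,
                 normals = nrm, dblA = dblA,
                 e1 = p3 - p2, e2 = p1 - p3, e3 = p2 - p1),
            class = "geodesic_solver")
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Heat-method geodesic distances from a source set
#'
#' @param solver a [geodesic_solver()] (or a [surf_mesh()], factored on
#'   the fly).
#' @param sources integer vector of source vertex indices (1-based).
#' @return numeric vector of approximate geodesic distances per vertex;
#'   zero is the minimum over the source set.
#' @export
geodesic_distances <- function(solver, sources) {
  if (inherits(solver, "surf_mesh")) solver <- geodesic_solver(solver)
  stopifnot(inherits(solver, "geodesic_solver"))
  nv <- nrow(solver$mesh$vertices)
  sources <- as.integer(sources)
  if (length(sources) == 0) stop("empty source set")
  if (min(sources) < 1L || max(sources) > nv)
    stop("source vertex index out of range")
  u0 <- numeric(nv)
  u0[sources] <- 1
  u <- as.numeric(Matrix::solve(solver$ch_heat, u0, system = "A"))

  tr <- solver$mesh$triangles
  # per-triangle gradient of u: (1/2A) sum_a u_a (n x e_a)
  gu <- (u[tr[, 1]] * cross3(solver$normals, solver$e1) +
         u[tr[, 2]] * cross3(solver$normals, solver$e2) +
         u[tr[, 3]] * cross3(solver$normals, solver$e3)) / solver$dblA
  gnorm <- sqrt(rowSums(gu^2))
  gnorm[gnorm < .Machine$double.eps] <- 1
  X <- -gu / gnorm

  # weak-form right-hand side: b_i = sum_T area_T grad(N_i) . X
  #                                = sum_T ((n x e_i) . X) / 2,
  # so that solving (stiffness) phi = b realizes Delta phi = div X with
  # natural boundary conditions.
  b <- numeric(nv)
  c1 <- rowSums(cross3(solver$normals, solver$e1) * X) / 2
  c2 <- rowSums(cross3(solver$normals, solver$e2) * X) / 2
  c3 <- rowSums(cross3(solver$normals, solver$e3) * X) / 2
  for (a in 1:3) {
    contrib <- list(c1, c2, c3)[[a]]
    acc <- tapply(contrib, tr[, a], sum)
    b[as.integer(names(acc))] <- b[as.integer(names(acc))] + acc
  }
  phi <- as.numeric(Matrix::solve(solver$ch_pois, b, system = "A"))
  if (stats::median(phi) < phi[sources[1]]) phi <- -phi
  phi - min(phi[sources])
}

#' Farthest-point experimental design on a mesh
#'
#' Builds a space-filling fixed design: the first vertex is drawn
#' uniformly at random (seeded); each subsequent vertex maximizes the
#' minimum geodesic distance to all vertices already selected. Ties are
#' broken by the lowest vertex index. The design of size `n` is by
#' construction a prefix of the design of size `n + 1` for the same seed.
#'
#' @param solver a [geodesic_solver()] or [surf_mesh()].
#' @param n design size (`<=` number of vertices).
#' @param seed integer seed selecting the initial vertex.
#' @return An object of class `fixed_design`: list with `vertices`
#'   (ordered index vector), `seed`, and `mean_pairwise_distance` (mean
#'   geodesic distance over all design pairs).
#' @export
farthest_point_design <- function(solver, n, seed = 1) {
  if (inherits(solver, "surf_mesh")) solver <- geodesic_solver(solver)
  stopifnot(inherits(solver, "geodesic_solver"))
  nv <- nrow(solver$mesh$vertices)
  n <- as.integer(n)
  if (n < 1L) stop("design size must be positive")
  if (n > nv) stop("design size exceeds number of vertices")
  old <- .Random.seed_exists()
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  sel <- integer(n)
  sel[1] <- sample.int(nv, 1)
  D <- matrix(NA_real_, nv, n)      # distance field from each design point
  D[, 1] <- geodesic_distances(solver, sel[1])
  if (n > 1L) {
    mind <- D[, 1]
    for (k in 2:n) {
      sel[k] <- which.max(mind)     # which.max: lowest index wins ties
      D[, k] <- geodesic_distances(solver, sel[k])
      mind <- pmin(mind, D[, k])
    }
  }
  pd <- D[sel, , drop = FALSE]
  mpd <- if (n > 1L) mean(pd[upper.tri(pd)] + t(pd)[upper.tri(pd)]) / 2
         else NA_real_
  structure(list(vertices = sel, seed = as.integer(seed),
                 mean_pairwise_distance = mpd),
            class = "fixed_design")
}

#' @export
print.fixed_design <- function(x, ...) {
  cat(sprintf("fixed_design: %d vertices (seed %d), mean pairwise geodesic distance %.4g\n",
              length(x$vertices), x$seed, x$mean_pairwise_distance))
  invisible(x)
}

#' Geodesic nearest-neighbor classifier
#'
#' Baseline classifier: each query vertex receives the label of the
#' geodesically nearest labeled vertex, with ties broken by the lowest
#' labeled-vertex index. One heat-method distance field is computed per
#' labeled vertex.
#'
#' @param solver a [geodesic_solver()] or [surf_mesh()].
#' @param labeled_vertices integer vector of labeled vertex indices.
#' @param labels binary labels (0/1), same length.
#' @param query_vertices integer vector of query indices (default: all
#'   vertices).
#' @return integer vector of predicted labels for the queries.
#' @export
nn_classify <- function(solver, labeled_vertices, labels,
                        query_vertices = NULL) {
  if (inherits(solver, "surf_mesh")) solver <- geodesic_solver(solver)
  stopifnot(inherits(solver, "geodesic_solver"))
  nv <- nrow(solver$mesh$vertices)
  if (length(labeled_vertices) == 0) stop("empty labeled set")
  if (length(labels) != length(labeled_vertices))
    stop("labels and labeled_vertices lengths differ")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  if (is.null(query_vertices)) query_vertices <- seq_len(nv)
  ord <- order(labeled_vertices)      # lowest-index tie-break
  labeled_vertices <- labeled_vertices[ord]
  labels <- labels[ord]
  best_d <- rep(Inf, length(query_vertices))
  best_lab <- rep(NA_integer_, length(query_vertices))
  for (j in seq_along(labeled_vertices)) {
    d <- geodesic_distances(solver, labeled_vertices[j])[query_vertices]
    take <- d < best_d
    best_d[take] <- d[take]
    best_lab[take] <- labels[j]
  }
  as.integer(best_lab)
}
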