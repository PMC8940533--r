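#' Built-in test meshes
#'
#' Programmatically generated meshes used by the synthetic benchmark and
#' the test-suite, so that no external mesh file is ever required:
#' an icosphere (subdivided icosahedron projected to the unit sphere), a
#' flat rectangular grid (a manifold with boundary), and a torus.
#'
#' @param name one of `"icosphere0"` .. `"icosphere4"` (the digit is the
#'   subdivision level), `"grid"`, or `"torus"`.
#' @param ... passed on to the specific constructor
#'   ([icosphere()], [flat_grid()], [torus_mesh()]).
#' @return a [surf_mesh()].
#' @export
builtin_mesh <- function(name, ...) {
  if (grepl("^icosphere[0-9]$", name))
    return(icosphere(as.integer(substring(name, 10)), ...))
  switch(name,
    grid = flat_grid(...),
    torus = torus_mesh(...),
    stop("unknown builtin mesh '", name,
         "' (use icosphere<L>, grid, torus)"))
}

#' @rdname builtin_mesh
#' @param level non-negative integer subdivision level; level `L` gives
#'   `10*4^L + 2` vertices.
#' @param radius sphere radius.
#' @export
icosphere <- function(level = 2, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (l in seq_len(level)) {
    sub <- subdivide_tris(v, f)
    v <- sub$vertices; f <- sub$triangles
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  surf_mesh(v, f)
}

# one loop-subdivision step (midpoint split, no smoothing)
subdivide_tris <- function(v, f) {
  env <- new.env()
  nv <- nrow(v)
  newv <- list()
  midpoint <- function(a, b) {
    key <- paste(min(a, b), max(a, b))
    id <- env[[key]]
    if (is.null(id)) {
      newv[[length(newv) + 1L]] <<- (v[a, ] + v[b, ]) / 2
      id <- nv + length(newv)
      env[[key]] <- id
    }
    id
  }
  nf <- nrow(f)
  out <- matrix(0L, 4L * nf, 3L)
  for (t in seq_len(nf)) {
    a <- f[t, 1]; b <- f[t, 2]; c <- f[t, 3]
    ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
    out[4L * t - 3L, ] <- c(a, ab, ca)
    out[4L * t - 2L, ] <- c(b, bc, ab)
    out[4L * t - 1L, ] <- c(c, ca, bc)
    out[4L * t, ] <- c(ab, bc, ca)
  }
  list(vertices = rbind(v, do.call(rbind, newv)), triangles = out)
}

#' @rdname builtin_mesh
#' @param nx,ny number of vertices along x and y.
#' @param lx,ly side lengths.
#' @export
flat_grid <- function(nx = 10, ny = 10, lx = 1, ly = 1) {
  stopifnot(nx >= 2, ny >= 2)
  xs <- seq(0, lx, length.out = nx)
  ys <- seq(0, ly, length.out = ny)
  v <- cbind(rep(xs, times = ny), rep(ys, each = nx), 0)
  id <- function(i, j) (j - 1L) * nx + i
  tris <- matrix(0L, 0, 3)
  for (j in seq_len(ny - 1L)) for (i in seq_len(nx - 1L)) {
    tris <- rbind(tris,
                  c(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L)),
                  c(id(i, j), id(i + 1L, j + 1L), id(i, j + 1L)))
  }
  surf_mesh(v, tris)
}

#' @rdname builtin_mesh
#' @param nu,nv vertex counts along the major and minor circles.
#' @param R,r major and minor radii.
#' @export
torus_mesh <- function(nu = 24, nv = 12, R = 1, r = 0.4) {
  stopifnot(nu >= 3, nv >= 3)
  us <- 2 * pi * (seq_len(nu) - 1) / nu
  vs <- 2 * pi * (seq_len(nv) - 1) / nv
  verts <- matrix(0, nu * nv, 3)
  for (j in seq_len(nv)) for (i in seq_len(nu)) {
    u <- us[i]; vv <- vs[j]
    verts[(j - 1L) * nu + i, ] <- c((R + r * cos(vv)) * cos(u),
                                    (R + r * cos(vv)) * sin(u),
                                    r * sin(vv))
  }
  id <- function(i, j) ((j - 1L) %% nv) * nu + ((i - 1L) %% nu) + 1L
  tris <- matrix(0L, 2L * nu * nv, 3L)
  k <- 0L
  for (j in seq_len(nv)) for (i in seq_len(nu)) {
    k <- k + 1L
    tris[2L * k - 1L, ] <- c(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L))
    tris[2L * k, ]      <- c(id(i, j), id(i + 1L, j + 1L), id(i, j + 1L))
  }
  surf_mesh(verts, tris)
}
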