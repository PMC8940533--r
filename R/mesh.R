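#' Construct a triangulated surface mesh
#'
#' Builds a `surf_mesh` object from vertex coordinates and triangle
#' connectivity, validates manifoldness, and computes the boundary vertex
#' set from edge adjacency. Triangle meshes are the discrete representation
#' of the 2-manifold on which all classifiers in this package operate (for
#' atrial applications, the mid-wall surface of the atria).
#'
#' @param vertices numeric matrix `[n_vertices x 3]` of coordinates.
#' @param triangles integer matrix `[n_triangles x 3]` of 1-based vertex
#'   indices.
#' @param normalization_scale positive scalar recording any divisor already
#'   applied to the coordinates (1 for raw geometry).
#'
#' @return An object of class `surf_mesh`: a list with elements `vertices`,
#'   `triangles`, `boundary_vertices` (sorted integer vector, possibly
#'   empty), and `normalization_scale`.
#'
#' @details
#' Validation enforces: all triangle indices valid; no degenerate
#' (zero-area) triangles, with the degeneracy cutoff at `1e-12` times the
#' mean triangle area; every edge shared by at most two triangles
#' (manifold-with-boundary); a single connected component. Boundary
#' vertices are exactly the endpoints of edges adjacent to one triangle.
#'
#' @seealso [read_mesh()], [normalize_geometry()], [assemble_fem()]
#' @export
surf_mesh <- function(vertices, triangles, normalization_scale = 1) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(triangles) != 3L) stop("triangles must have 3 columns")
  nv <- nrow(vertices)
  if (nv < 3L) stop("mesh must have at least 3 vertices")
  if (anyNA(vertices)) stop("vertex coordinates contain NA")
  if (anyNA(triangles)) stop("triangle indices contain NA")
  if (min(triangles) < 1L || max(triangles) > nv)
    stop("triangle indices out of range [1, ", nv, "]")
  if (any(triangles[, 1] == triangles[, 2] |
          triangles[, 1] == triangles[, 3] |
          triangles[, 2] == triangles[, 3]))
    stop("triangle with repeated vertex index")

  areas <- triangle_areas(vertices, triangles)
  degen <- areas < 1e-12 * mean(areas)
  if (any(degen))
    stop("degenerate (zero-area) triangle(s): ",
         paste(which(degen)[seq_len(min(5, sum(degen)))], collapse = ", "))

  ed <- mesh_edges(triangles)
  if (any(ed$count > 2L))
    stop("non-manifold edge shared by >2 triangles (e.g. edge ",
         ed$v1[ed$count > 2L][1], "-", ed$v2[ed$count > 2L][1], ")")
  bnd_edges <- ed$count == 1L
  boundary_vertices <- sort(unique(c(ed$v1[bnd_edges], ed$v2[bnd_edges])))

  mesh <- structure(
    list(vertices = vertices, triangles = triangles,
         boundary_vertices = as.integer(boundary_vertices),
         normalization_scale = as.numeric(normalization_scale)),
    class = "surf_mesh")
  if (n_components(mesh) > 1L)
    stop("mesh has more than one connected component")
  mesh
}

#' @export
print.surf_mesh <- function(x, ...) {
  cat(sprintf("surf_mesh: %d vertices, %d triangles, %d boundary vertices\n",
              nrow(x$vertices), nrow(x$triangles),
              length(x$boundary_vertices)))
  cat(sprintf("  normalization scale: %g, total area: %g\n",
              x$normalization_scale,
              sum(triangle_areas(x$vertices, x$triangles))))
  invisible(x)
}

# Unique undirected edges with adjacency counts.
mesh_edges <- function(triangles) {
  e <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(3, 1)])
  v1 <- pmin(e[, 1], e[, 2]); v2 <- pmax(e[, 1], e[, 2])
  key <- paste(v1, v2)
  tab <- table(key)
  first <- !duplicated(key)
  cnt <- as.integer(tab[key[first]])
  list(v1 = v1[first], v2 = v2[first], count = cnt)
}

triangle_areas <- function(vertices, triangles) {
  p1 <- vertices[triangles[, 1], , drop = FALSE]
  u <- vertices[triangles[, 2], , drop = FALSE] - p1
  v <- vertices[triangles[, 3], , drop = FALSE] - p1
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

n_components <- function(mesh) {
  nv <- nrow(mesh$vertices)
  tr <- mesh$triangles
  i <- c(tr[, 1], tr[, 2], tr[, 3])
  j <- c(tr[, 2], tr[, 3], tr[, 1])
  adj <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                              dims = c(nv, nv))
  # breadth-first sweep via repeated sparse matvec
  seen <- logical(nv)
  comp <- 0L
  while (!all(seen)) {
    comp <- comp + 1L
    front <- numeric(nv)
    front[which(!seen)[1]] <- 1
    reach <- front > 0
    repeat {
      front <- as.numeric(adj %*% front)
      new <- front > 0 & !reach
      if (!any(new)) break
      reach <- reach | new
    }
    seen <- seen | reach
  }
  comp
}

#' Normalize mesh geometry by its largest coordinate standard deviation
#'
#' Divides all vertex coordinates by the maximum over the three coordinate
#' axes of the per-axis standard deviation. After normalization, the same
#' kernel length-scale priors are meaningful across geometries of very
#' different physical size, so the classifier is scale-free. The operation
#' is idempotent up to floating-point tolerance.
#'
#' @param mesh a [surf_mesh()].
#' @return A `surf_mesh` with rescaled coordinates;
#'   `normalization_scale` accumulates the divisor applied.
#' @export
normalize_geometry <- function(mesh) {
  stopifnot(inherits(mesh, "surf_mesh"))
  s <- max(apply(mesh$vertices, 2, stats::sd))
  if (!is.finite(s) || s <= 0)
    stop("cannot normalize: zero standard deviation on all axes")
  mesh$vertices <- mesh$vertices / s
  mesh$normalization_scale <- mesh$normalization_scale * s
  mesh
}

#' Read a triangle mesh from a standard file format
#'
#' Parses OFF, ascii PLY, legacy ascii VTK (POLYDATA or UNSTRUCTURED_GRID
#' with triangle cells), or ascii STL files into a [surf_mesh()]. STL
#' files carry no connectivity, so coincident vertices are merged exactly.
#'
#' @param path path to the mesh file.
#' @param format one of `"off"`, `"ply"`, `"vtk"`, `"stl"`, or `"auto"`
#'   (default) to infer from the file extension.
#' @return a [surf_mesh()].
#' @export
read_mesh <- function(path, format = c("auto", "off", "ply", "vtk", "stl")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("mesh file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, off = "off", ply = "ply", vtk = "vtk", stl = "stl",
                     stop("cannot infer mesh format from extension '.",
                          ext, "'"))
  }
  parsed <- switch(format,
    off = parse_off(path), ply = parse_ply(path),
    vtk = parse_vtk(path), stl = parse_stl(path))
  surf_mesh(parsed$vertices, parsed$triangles)
}

read_tokens <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  toks <- unlist(strsplit(trimws(lines), "[[:space:]]+"))
  toks[nzchar(toks)]
}

parse_off <- function(path) {
  toks <- read_tokens(path)
  if (toupper(toks[1]) != "OFF") stop("not an OFF file: ", path)
  toks <- toks[-1]
  nv <- as.integer(toks[1]); nf <- as.integer(toks[2])
  toks <- toks[-(1:3)]
  verts <- matrix(as.numeric(toks[seq_len(3 * nv)]), ncol = 3, byrow = TRUE)
  toks <- toks[-seq_len(3 * nv)]
  tris <- matrix(0L, nf, 3)
  pos <- 1L
  for (f in seq_len(nf)) {
    k <- as.integer(toks[pos])
    if (k != 3L) stop("non-triangle face (", k, " vertices) in ", path)
    tris[f, ] <- as.integer(toks[pos + 1:3]) + 1L
    pos <- pos + k + 1L
  }
  list(vertices = verts, triangles = tris)
}

parse_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!grepl("^ply", lines[1])) stop("not a PLY file: ", path)
  if (!any(grepl("format\\s+ascii", lines))) stop("only ascii PLY supported")
  endh <- grep("^end_header", lines)[1]
  ev <- grep("^element\\s+vertex", lines[1:endh], value = TRUE)[1]
  ef <- grep("^element\\s+face", lines[1:endh], value = TRUE)[1]
  nv <- as.integer(strsplit(trimws(ev), "\\s+")[[1]][3])
  nf <- as.integer(strsplit(trimws(ef), "\\s+")[[1]][3])
  # count per-vertex scalar properties declared between vertex and face elements
  velem <- grep("^element\\s+vertex", lines[1:endh])
  felem <- grep("^element\\s+face", lines[1:endh])
  nprop <- sum(grepl("^property\\s", trimws(lines[velem:felem])))
  body <- lines[(endh + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  vdat <- t(vapply(body[seq_len(nv)],
                   function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]),
                   numeric(nprop), USE.NAMES = FALSE))
  tris <- t(vapply(body[nv + seq_len(nf)], function(l) {
    x <- as.integer(strsplit(trimws(l), "\\s+")[[1]])
    if (x[1] != 3L) stop("non-triangle face in ", path)
    x[2:4] + 1L
  }, integer(3), USE.NAMES = FALSE))
  list(vertices = vdat[, 1:3, drop = FALSE], triangles = tris)
}

parse_vtk <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("ASCII", lines[1:5], ignore.case = TRUE)))
    stop("only ascii legacy VTK supported")
  pts_i <- grep("^POINTS", lines)[1]
  if (is.na(pts_i)) stop("no POINTS section in ", path)
  nv <- as.integer(strsplit(trimws(lines[pts_i]), "\\s+")[[1]][2])
  toks <- unlist(strsplit(trimws(lines[(pts_i + 1):length(lines)]),
                          "[[:space:]]+"))
  toks <- toks[nzchar(toks)]
  verts <- matrix(as.numeric(toks[seq_len(3 * nv)]), ncol = 3, byrow = TRUE)
  cell_i <- grep("^(POLYGONS|CELLS)", lines)[1]
  if (is.na(cell_i)) stop("no POLYGONS/CELLS section in ", path)
  hdr <- strsplit(trimws(lines[cell_i]), "\\s+")[[1]]
  nf <- as.integer(hdr[2])
  ctoks <- unlist(strsplit(trimws(lines[(cell_i + 1):length(lines)]),
                           "[[:space:]]+"))
  ctoks <- suppressWarnings(as.integer(ctoks[nzchar(ctoks)]))
  tris <- matrix(0L, nf, 3)
  pos <- 1L
  for (f in seq_len(nf)) {
    k <- ctoks[pos]
    if (is.na(k) || k != 3L) stop("non-triangle cell in ", path)
    tris[f, ] <- ctoks[pos + 1:3] + 1L
    pos <- pos + 4L
  }
  list(vertices = verts, triangles = tris)
}

parse_stl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!grepl("^\\s*solid", lines[1], ignore.case = TRUE))
    stop("only ascii STL supported (missing 'solid' header)")
  vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vlines) %% 3 != 0) stop("malformed ascii STL: ", path)
  coords <- t(vapply(vlines, function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]][2:4])
  }, numeric(3), USE.NAMES = FALSE))
  key <- apply(coords, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  uid <- match(key, unique(key))
  verts <- coords[!duplicated(key), , drop = FALSE]
  tris <- matrix(uid, ncol = 3, byrow = TRUE)
  list(vertices = verts, triangles = tris)
}

#' Write a mesh (with optional per-vertex fields) as legacy ascii VTK
#'
#' @param mesh a [surf_mesh()].
#' @param path output file path.
#' @param point_data optional named list of numeric per-vertex vectors,
#'   written as VTK `POINT_DATA` scalar fields.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, point_data = NULL) {
  stopifnot(inherits(mesh, "surf_mesh"))
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$triangles)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "surfgpc mesh", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d double", nv)), con)
  writeLines(apply(mesh$vertices, 1, function(r)
    paste(sprintf("%.17g", r), collapse = " ")), con)
  writeLines(sprintf("POLYGONS %d %d", nf, 4L * nf), con)
  writeLines(apply(mesh$triangles - 1L, 1, function(r)
    paste(c(3L, r), collapse = " ")), con)
  if (!is.null(point_data) && length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", nv), con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      stopifnot(length(v) == nv)
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default",
                   sprintf("%.17g", as.numeric(v))), con)
    }
  }
  invisible(path)
}

#' Checksum identifying a mesh's geometry and connectivity
#'
#' Used to invalidate cached eigenbases when the underlying mesh changes.
#'
#' @param mesh a [surf_mesh()].
#' @return a character md5 string.
#' @export
mesh_checksum <- function(mesh) {
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf))
  writeLines(c(sprintf("%.12e", mesh$vertices),
               sprintf("%d", mesh$triangles)), tf)
  unname(tools::md5sum(tf))
}
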