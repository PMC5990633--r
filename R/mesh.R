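#' Triangle surface mesh
#'
#' Light S3 container for a triangulated surface: an `N x 3` matrix of vertex
#' coordinates (millimetres) and a `T x 3` integer matrix of 1-based vertex
#' indices.  All analysis functions in the package ([assemble_fem()],
#' [spectral_parcellate()], [geodesic_distance_map()], ...) operate on this
#' class and assume a closed genus-0 2-manifold, which [validate_mesh()]
#' checks.
#'
#' @param vertices numeric matrix, `N x 3`, vertex coordinates in mm.
#' @param triangles integer matrix, `T x 3`, 1-based vertex indices.
#' @param name optional character tag carried through I/O.
#' @return An object of class `triangle_mesh` with elements `vertices`,
#'   `triangles` and `name`.
#' @examples
#' ico <- make_icosphere(0)
#' mesh <- triangle_mesh(ico$mesh$vertices, ico$mesh$triangles, "icosahedron")
#' validate_mesh(mesh)$genus0
#' @export
triangle_mesh <- function(vertices, triangles, name = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  dimnames(triangles) <- NULL
  if (ncol(vertices) != 3L) stop("`vertices` must be an N x 3 matrix")
  if (ncol(triangles) != 3L) stop("`triangles` must be a T x 3 matrix")
  if (nrow(triangles) > 0L) {
    if (min(triangles) < 1L || max(triangles) > nrow(vertices))
      stop("triangle indices out of range [1, N]")
    degen <- triangles[, 1L] == triangles[, 2L] |
      triangles[, 2L] == triangles[, 3L] |
      triangles[, 1L] == triangles[, 3L]
    if (any(degen))
      stop("triangle(s) with fewer than 3 distinct vertices: ",
           paste(which(degen)[seq_len(min(5L, sum(degen)))], collapse = ", "))
  }
  structure(list(vertices = vertices, triangles = triangles, name = name),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh%s: %d vertices, %d triangles\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

#' Undirected edge list of a mesh
#'
#' @param mesh a [triangle_mesh].
#' @return integer matrix `E x 2`, each row an edge with `v1 < v2`, no
#'   duplicates.
#' @keywords internal
mesh_edges <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1L, 2L)], tr[, c(2L, 3L)], tr[, c(3L, 1L)])
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  unique(e)
}

# directed half-edge table: one row per triangle side, with triangle id
mesh_halfedges <- function(mesh) {
  tr <- mesh$triangles
  nt <- nrow(tr)
  cbind(v1 = c(tr[, 1L], tr[, 2L], tr[, 3L]),
        v2 = c(tr[, 2L], tr[, 3L], tr[, 1L]),
        tri = rep.int(seq_len(nt), 3L))
}

#' Per-triangle areas
#' @param mesh a [triangle_mesh].
#' @return numeric vector of triangle areas (mm^2).
#' @export
triangle_areas <- function(mesh) {
  v <- mesh$vertices
  tr <- mesh$triangles
  e1 <- v[tr[, 2L], , drop = FALSE] - v[tr[, 1L], , drop = FALSE]
  e2 <- v[tr[, 3L], , drop = FALSE] - v[tr[, 1L], , drop = FALSE]
  cx <- e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L]
  cy <- e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L]
  cz <- e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Total surface area
#' @param mesh a [triangle_mesh].
#' @return total area in mm^2.
#' @export
surface_area <- function(mesh) sum(triangle_areas(mesh))

#' Validate mesh topology
#'
#' Checks that a mesh is a closed 2-manifold of genus 0, the domain on which
#' the Laplace-Beltrami eigenproblem is posed.  Meshes failing any check are
#' rejected by downstream stages rather than repaired, since repair would
#' change the spectrum.
#'
#' @param mesh a [triangle_mesh].
#' @return A list of class `mesh_validation` with booleans `closed`,
#'   `manifold`, `genus0`, `ok` (conjunction of the three), counts
#'   `n_vertices`, `n_edges`, `n_triangles`, the Euler characteristic
#'   `euler`, and index lists `boundary_edges` (edges on exactly one
#'   triangle), `nonmanifold_edges` (edges on three or more triangles) and
#'   `degenerate_triangles` (area below 1e-12 mm^2).
#' @examples
#' validate_mesh(make_icosphere(2)$mesh)$ok
#' @export
validate_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  he <- mesh_halfedges(mesh)
  key <- paste(pmin(he[, 1L], he[, 2L]), pmax(he[, 1L], he[, 2L]))
  mult <- table(key)
  edges <- mesh_edges(mesh)
  n_e <- nrow(edges)
  boundary <- names(mult)[mult == 1L]
  nonmanifold <- names(mult)[mult >= 3L]
  parse_edges <- function(k) {
    if (length(k) == 0L) return(matrix(integer(0), 0L, 2L))
    m <- do.call(rbind, strsplit(k, " ", fixed = TRUE))
    matrix(as.integer(m), ncol = 2L)
  }
  areas <- triangle_areas(mesh)
  degenerate <- which(areas < 1e-12)
  closed <- length(boundary) == 0L
  manifold <- length(nonmanifold) == 0L && length(degenerate) == 0L
  euler <- nrow(mesh$vertices) - n_e + nrow(mesh$triangles)
  genus0 <- closed && manifold && euler == 2L
  structure(list(
    closed = closed, manifold = manifold, genus0 = genus0,
    ok = closed && manifold && genus0,
    n_vertices = nrow(mesh$vertices), n_edges = n_e,
    n_triangles = nrow(mesh$triangles), euler = euler,
    boundary_edges = parse_edges(boundary),
    nonmanifold_edges = parse_edges(nonmanifold),
    degenerate_triangles = degenerate
  ), class = "mesh_validation")
}

#' @export
print.mesh_validation <- function(x, ...) {
  cat(sprintf(
    "mesh_validation: V=%d E=%d F=%d (euler %d)\n  closed=%s manifold=%s genus0=%s\n",
    x$n_vertices, x$n_edges, x$n_triangles, x$euler,
    x$closed, x$manifold, x$genus0))
  invisible(x)
}

# stop unless the mesh is a closed genus-0 manifold
assert_valid_mesh <- function(mesh) {
  rep <- validate_mesh(mesh)
  if (!rep$ok)
    stop("mesh is not a closed genus-0 2-manifold (closed=", rep$closed,
         ", manifold=", rep$manifold, ", genus0=", rep$genus0, ")")
  invisible(rep)
}

#' Vertex adjacency list
#' @param mesh a [triangle_mesh].
#' @return list of length N; element i holds the sorted neighbours of vertex i.
#' @keywords internal
vertex_adjacency <- function(mesh) {
  e <- mesh_edges(mesh)
  adj <- split(c(e[, 2L], e[, 1L]), c(e[, 1L], e[, 2L]))
  out <- vector("list", nrow(mesh$vertices))
  out[as.integer(names(adj))] <- lapply(adj, function(v) sort(unique(v)))
  out[vapply(out, is.null, TRUE)] <- list(integer(0))
  out
}

#' Spherical parameterization of a mesh
#'
#' Per-vertex unit directions on the sphere, index-aligned with a mesh.  The
#' parameterization is consumed, not computed: it either comes from an
#' external tool (e.g. a FreeSurfer-style sphere) or from the synthetic
#' generators, whose icosphere directions are exact.
#'
#' @param sphere_vertices `N x 3` matrix of unit vectors.
#' @return object of class `spherical_param`.
#' @export
spherical_param <- function(sphere_vertices) {
  sv <- as.matrix(sphere_vertices)
  storage.mode(sv) <- "double"
  if (ncol(sv) != 3L) stop("`sphere_vertices` must be N x 3")
  nrm <- sqrt(rowSums(sv^2))
  if (any(abs(nrm - 1) > 1e-9))
    stop("spherical parameterization rows must be unit vectors (max deviation ",
         format(max(abs(nrm - 1))), ")")
  structure(list(sphere_vertices = sv), class = "spherical_param")
}

#' Ordered sulcal line on a mesh
#'
#' @param vertex_indices ordered integer vector of 1-based mesh vertex
#'   indices; consecutive entries must be edge-adjacent and no index repeats.
#' @param label character name of the line (e.g. a sulcus name).
#' @param mesh optional [triangle_mesh]; when given, adjacency is checked.
#' @return object of class `sulcal_line`.
#' @export
sulcal_line <- function(vertex_indices, label = "line", mesh = NULL) {
  vertex_indices <- as.integer(vertex_indices)
  if (anyDuplicated(vertex_indices))
    stop("sulcal line must not repeat a vertex")
  if (!is.null(mesh) && length(vertex_indices) > 1L) {
    e <- mesh_edges(mesh)
    ek <- paste(e[, 1L], e[, 2L])
    a <- vertex_indices[-length(vertex_indices)]
    b <- vertex_indices[-1L]
    k <- paste(pmin(a, b), pmax(a, b))
    bad <- which(!(k %in% ek))
    if (length(bad))
      stop("consecutive sulcal-line vertices not edge-adjacent at position(s) ",
           paste(bad[seq_len(min(5L, length(bad)))], collapse = ", "))
  }
  structure(list(vertex_indices = vertex_indices, label = label),
            class = "sulcal_line")
}

#' Constraint region (set of excluded vertices)
#'
#' Vertices excluded from the unsupervised clustering, the analogue of the
#' non-cortical cingulate pole on clinical meshes.  Label 0 is reserved for
#' this set in constrained parcellations.
#'
#' @param vertex_indices integer vector of 1-based mesh vertex indices.
#' @param n_vertices optional mesh vertex count for range checking.
#' @return object of class `constraint_region`.
#' @export
constraint_region <- function(vertex_indices, n_vertices = NULL) {
  vertex_indices <- sort(unique(as.integer(vertex_indices)))
  if (length(vertex_indices) &&
      (!is.null(n_vertices)) &&
      (min(vertex_indices) < 1L || max(vertex_indices) > n_vertices))
    stop("constraint indices out of range")
  structure(list(vertex_indices = vertex_indices), class = "constraint_region")
}
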