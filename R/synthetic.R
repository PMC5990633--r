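#' Icosphere with exact spherical parameterization
#'
#' Recursively subdivided icosahedron projected onto the sphere.  The vertex
#' count is `10 * 4^s + 2`.  Because vertices lie exactly on the sphere, the
#' returned parameterization (`vertices / radius`) is exact, making the
#' icosphere the common spherical template for relabeling, consensus and
#' rotation null models.
#'
#' @param subdivisions integer >= 0 (and <= 7, to bound mesh size).
#' @param radius sphere radius in mm (> 0).
#' @return list with `mesh` (a [triangle_mesh]) and `param`
#'   (a [spherical_param]).
#' @examples
#' ico <- make_icosphere(3)
#' nrow(ico$mesh$vertices)  # 642
#' @export
make_icosphere <- function(subdivisions, radius = 1) {
  subdivisions <- as.integer(subdivisions)
  if (subdivisions < 0L || subdivisions > 7L)
    stop("`subdivisions` must be in [0, 7]")
  if (radius <= 0) stop("`radius` must be positive")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  tr <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  storage.mode(tr) <- "integer"
  for (s in seq_len(subdivisions)) {
    n <- nrow(v)
    e <- rbind(tr[, c(1L, 2L)], tr[, c(2L, 3L)], tr[, c(3L, 1L)])
    e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
    ue <- unique(e)
    mid <- (v[ue[, 1L], , drop = FALSE] + v[ue[, 2L], , drop = FALSE]) / 2
    mid <- mid / sqrt(rowSums(mid^2))
    key <- function(a, b) pmin(a, b) * (n + 1) + pmax(a, b)
    midx <- n + match(key(e[, 1L], e[, 2L]), key(ue[, 1L], ue[, 2L]))
    nt <- nrow(tr)
    m12 <- midx[seq_len(nt)]
    m23 <- midx[nt + seq_len(nt)]
    m31 <- midx[2L * nt + seq_len(nt)]
    v <- rbind(v, mid)
    tr <- rbind(cbind(tr[, 1L], m12, m31),
                cbind(tr[, 2L], m23, m12),
                cbind(tr[, 3L], m31, m23),
                cbind(m12, m23, m31))
    storage.mode(tr) <- "integer"
  }
  mesh <- triangle_mesh(v * radius, tr,
                        name = sprintf("icosphere_s%d_r%g", subdivisions, radius))
  list(mesh = mesh, param = spherical_param(v))
}

# band-limited folding field on the unit sphere: `frequency` seeded sinusoids
# with random wave vectors and phases, normalized to max |w| = 1
folding_field <- function(directions, frequency, seed) {
  with_rng(seed, {
    w <- numeric(nrow(directions))
    for (j in seq_len(frequency)) {
      d <- stats::rnorm(3)
      d <- d / sqrt(sum(d^2))
      kappa <- stats::runif(1, 4, 8)
      phase <- stats::runif(1, 0, 2 * pi)
      w <- w + sin(kappa * (directions %*% d) + phase)
    }
    m <- max(abs(w))
    if (m > 0) w <- w / m
    as.numeric(w)
  })
}

#' Folded ellipsoid fixture
#'
#' Synthetic analogue of a folded cortical hemisphere: an icosphere with unit
#' directions `u` mapped to `(a u_x, b u_y, c u_z) * (1 + amplitude * w(u))`,
#' where `w` is a seeded band-limited sum of spherical sinusoids normalized
#' to `max |w| = 1`.  The generating icosphere directions serve as a known,
#' exact spherical parameterization.  `amplitude = 0` gives the exact
#' ellipsoid.
#'
#' @param semi_axes numeric length-3 `(a, b, c)` in mm with `a >= b >= c > 0`.
#' @param amplitude folding amplitude in `[0, 1)` (dimensionless fraction of
#'   the local radius).
#' @param frequency integer number of sinusoidal components of the folding
#'   field.
#' @param subdivisions icosphere subdivision level.
#' @param seed integer seed of the folding field; generation is a pure
#'   function of its arguments.
#' @return list with `mesh` and `param`, as [make_icosphere()].
#' @examples
#' fe <- make_folded_ellipsoid(c(3, 1.5, 1), amplitude = 0.1, seed = 7)
#' validate_mesh(fe$mesh)$ok
#' @export
make_folded_ellipsoid <- function(semi_axes, amplitude = 0.15, frequency = 4L,
                                  subdivisions = 3L, seed = 1L) {
  semi_axes <- as.numeric(semi_axes)
  if (length(semi_axes) != 3L || any(semi_axes <= 0) ||
      semi_axes[1] < semi_axes[2] || semi_axes[2] < semi_axes[3])
    stop("`semi_axes` must satisfy a >= b >= c > 0")
  if (amplitude < 0) stop("`amplitude` must be nonnegative")
  if (amplitude >= 1)
    stop("`amplitude` >= 1 risks self-intersection; use a value in [0, 1)")
  ico <- make_icosphere(subdivisions, radius = 1)
  u <- ico$param$sphere_vertices
  scale <- if (amplitude > 0)
    1 + amplitude * folding_field(u, as.integer(frequency), seed) else 1
  v <- u * rep(semi_axes, each = nrow(u)) * scale
  mesh <- triangle_mesh(v, ico$mesh$triangles,
                        name = sprintf("folded_ellipsoid_seed%d", as.integer(seed)))
  list(mesh = mesh, param = ico$param)
}

#' Polar constraint cap
#'
#' All vertices whose spherical direction lies within an angular radius of a
#' center direction: the synthetic stand-in for the labeled cingulate pole
#' excluded from constrained clustering.
#'
#' @param param a [spherical_param].
#' @param center_direction length-3 direction (normalized with a warning if
#'   not unit).
#' @param angular_radius cap half-angle in degrees, in `[0, 180]`; vertices
#'   with angle strictly below it are included (`>= 180` selects all).
#' @return a [constraint_region].
#' @export
make_constraint_cap <- function(param, center_direction = c(0, 0, 1),
                                angular_radius = 25) {
  stopifnot(inherits(param, "spherical_param"))
  if (angular_radius < 0 || angular_radius > 180)
    stop("`angular_radius` must be in [0, 180] degrees")
  d <- as.numeric(center_direction)
  nrm <- sqrt(sum(d^2))
  if (nrm == 0) stop("`center_direction` must be nonzero")
  if (abs(nrm - 1) > 1e-9) {
    warning("`center_direction` normalized to unit length")
    d <- d / nrm
  } else d <- d / nrm
  if (angular_radius >= 180) {
    idx <- seq_len(nrow(param$sphere_vertices))
  } else {
    cosang <- pmin(1, pmax(-1, param$sphere_vertices %*% d))
    idx <- which(acos(cosang) * 180 / pi < angular_radius)
  }
  constraint_region(idx, n_vertices = nrow(param$sphere_vertices))
}

#' Synthetic sulcal line by plane intersection
#'
#' Intersects the surface with a plane `normal . x = offset` and snaps the
#' intersection curve to mesh vertices, producing an ordered edge-adjacent
#' vertex path -- a stand-in for manually traced sulcal lines.  Each crossing
#' edge contributes its endpoint nearer to the plane, so every returned
#' vertex lies within one local edge length of the plane.
#'
#' @param mesh a [triangle_mesh].
#' @param normal length-3 plane normal (need not be unit).
#' @param offset scalar plane offset.
#' @param label character name for the resulting [sulcal_line].
#' @return a [sulcal_line].
#' @examples
#' ico <- make_icosphere(3)
#' line <- make_synthetic_sulcus(ico$mesh, normal = c(0, 0, 1), offset = 0)
#' @export
make_synthetic_sulcus <- function(mesh, normal, offset = 0, label = "sulcus") {
  n <- as.numeric(normal)
  n <- n / sqrt(sum(n^2))
  side <- as.numeric(mesh$vertices %*% n) - offset
  tr <- mesh$triangles
  s <- matrix(side[tr] > 0, ncol = 3L)
  cut_tri <- which(rowSums(s) %in% c(1L, 2L))
  if (length(cut_tri) == 0L) stop("plane does not intersect the surface")

  # each cut triangle has exactly two crossing edges; adjacent cut triangles
  # share one, so the cut triangles form closed strips we can walk
  cut_edges_of <- function(ti) {
    vs <- tr[ti, ]
    pairs <- rbind(vs[c(1L, 2L)], vs[c(2L, 3L)], vs[c(3L, 1L)])
    cross <- (side[pairs[, 1L]] > 0) != (side[pairs[, 2L]] > 0)
    pairs[cross, , drop = FALSE]
  }
  edge_key <- function(e) paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  tri_edges <- lapply(cut_tri, cut_edges_of)
  keys <- lapply(tri_edges, edge_key)
  # map crossing-edge key -> the (<= 2) cut triangles that contain it
  edge2tri <- split(rep(seq_along(cut_tri), lengths(keys)), unlist(keys))

  # walk the strip starting from the first cut triangle
  start <- 1L
  visited <- logical(length(cut_tri))
  path_edges <- character(0)
  cur <- start
  cur_edge <- keys[[cur]][1L]
  repeat {
    visited[cur] <- TRUE
    path_edges <- c(path_edges, cur_edge)
    nxt_edge <- setdiff(keys[[cur]], cur_edge)
    if (length(nxt_edge) == 0L) break
    nxt_edge <- nxt_edge[1L]
    cand <- edge2tri[[nxt_edge]]
    cand <- cand[cand != cur & !visited[cand]]
    if (length(cand) == 0L) { path_edges <- c(path_edges, nxt_edge); break }
    cur <- cand[1L]
    cur_edge <- nxt_edge
  }
  em <- do.call(rbind, strsplit(unique(path_edges), " ", fixed = TRUE))
  em <- matrix(as.integer(em), ncol = 2L)
  # snap each crossing edge to its endpoint nearer the plane
  nearer <- ifelse(abs(side[em[, 1L]]) <= abs(side[em[, 2L]]),
                   em[, 1L], em[, 2L])
  # drop consecutive duplicates, then any later re-occurrences
  keep <- c(TRUE, nearer[-1L] != nearer[-length(nearer)])
  verts <- nearer[keep]
  verts <- verts[!duplicated(verts)]
  # ensure consecutive adjacency (edges of cut triangles suffice: consecutive
  # snapped vertices share a cut triangle); drop vertices that break it
  ct <- tr[cut_tri, , drop = FALSE]
  ek <- unique(c(paste(pmin(ct[, 1L], ct[, 2L]), pmax(ct[, 1L], ct[, 2L])),
                 paste(pmin(ct[, 2L], ct[, 3L]), pmax(ct[, 2L], ct[, 3L])),
                 paste(pmin(ct[, 3L], ct[, 1L]), pmax(ct[, 3L], ct[, 1L]))))
  out <- verts[1L]
  for (v in verts[-1L]) {
    last <- out[length(out)]
    if (paste(min(last, v), max(last, v)) %in% ek) out <- c(out, v)
  }
  if (length(out) < 2L)
    stop("plane intersection too small to form a sulcal line")
  sulcal_line(out, label = label)
}
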