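#' Haar-uniform random rotation
#'
#' QR decomposition of a 3x3 matrix of independent standard normals, with
#' the sign correction (column `j` of `Q` multiplied by the sign of
#' `R[j, j]`) that makes the draw Haar-uniform over the orthogonal group;
#' a determinant of -1 is then folded into the rotation group by negating
#' the last column, so the null model uses proper rotations only.
#'
#' @return 3x3 rotation matrix (orthogonal, determinant +1).  Consumes the
#'   current RNG stream; seed with `set.seed()` for reproducibility.
#' @examples
#' set.seed(1)
#' Q <- random_rotation()
#' crossprod(Q)  # identity
#' @export
random_rotation <- function() {
  A <- matrix(stats::rnorm(9L), 3L, 3L)
  qrA <- qr(A)
  Q <- qr.Q(qrA)
  R <- qr.R(qrA)
  Q <- Q %*% diag(sign(diag(R)))
  if (det(Q) < 0) Q[, 3L] <- -Q[, 3L]
  Q
}

#' Rotate a parcellation on the sphere
#'
#' Nearest-neighbour label pullback: the rotated map at template vertex `v`
#' takes the label of the template vertex nearest to `Q' v`, i.e. the map is
#' carried forward by the rotation `Q`.
#'
#' @param map a [parcellation] on the template vertices.
#' @param param the template [spherical_param].
#' @param Q 3x3 rotation matrix.
#' @return a [parcellation].
#' @export
rotate_labels <- function(map, param, Q) {
  V <- param$sphere_vertices
  if (length(map$labels) != nrow(V))
    stop("map must be defined on the template vertices")
  idx <- nearest_vertex(V, V %*% Q)  # row i of V %*% Q is Q' v_i
  parcellation(map$labels[idx], map$n_clusters, map$constrained)
}

#' Rotation-null significance of partition agreement
#'
#' Tests whether an automatic parcellation is closer to a reference map
#' than expected under a null of independent placement: the automatic map
#' is rotated `n_rot` times by Haar-uniform random rotations on the sphere
#' (which preserve region sizes up to resampling error), the partition
#' distance to the reference is recomputed for each rotation, and the
#' p-value is the fraction of null distances strictly smaller than the
#' observed one.  Both maps must live on the template vertex set; their
#' cluster counts may differ (the rand distance accepts rectangular
#' contingency tables).
#'
#' @param auto,ref [parcellation] objects on the template vertices.
#' @param template the template [spherical_param].
#' @param n_rot number of random rotations (>= 1); 500 is the conventional
#'   default.
#' @param estimator `"strict"` for `#(null < d) / n_rot`, or
#'   `"conservative"` for `(#(null < d) + 1) / (n_rot + 1)` (unbiased under
#'   the null).
#' @param seed optional integer seed for the rotation stream.
#' @return list of class `significance_result` with `observed`,
#'   `null_distances`, `p_value` and `n_rot`.
#' @export
significance_test <- function(auto, ref, template, n_rot = 500L,
                              estimator = c("strict", "conservative"),
                              seed = NULL) {
  estimator <- match.arg(estimator)
  n_rot <- as.integer(n_rot)
  if (n_rot < 1L) stop("`n_rot` must be >= 1")
  if (length(auto$labels) != length(ref$labels) ||
      length(auto$labels) != nrow(template$sphere_vertices))
    stop("`auto`, `ref` and `template` must share the vertex set")
  run <- function() {
    observed <- rand_distance(contingency(auto, ref))$rand_distance
    null_d <- vapply(seq_len(n_rot), function(i) {
      Q <- random_rotation()
      rot <- rotate_labels(auto, template, Q)
      rand_distance(contingency(rot, ref))$rand_distance
    }, numeric(1))
    count <- sum(null_d < observed)
    p <- if (estimator == "strict") count / n_rot else
      (count + 1) / (n_rot + 1)
    structure(list(observed = observed, null_distances = null_d,
                   p_value = p, n_rot = n_rot),
              class = "significance_result")
  }
  if (is.null(seed)) run() else with_rng(seed, run())
}

#' @export
print.significance_result <- function(x, ...) {
  cat(sprintf(
    "significance_result: observed rand = %.4g, null %d rotations [%.4g, %.4g] median %.4g, p = %.4g\n",
    x$observed, x$n_rot, min(x$null_distances), max(x$null_distances),
    stats::median(x$null_distances), x$p_value))
  invisible(x)
}

#' Area distortion of a spherical parameterization
#'
#' The rotation null assumes a near-area-preserving parameterization; this
#' helper reports the per-vertex ratio between mesh and sphere vertex areas
#' (one third of incident triangle areas) and warns when the spread exceeds
#' a factor above the median.
#'
#' @param mesh a [triangle_mesh].
#' @param param its [spherical_param].
#' @param warn_factor warn when some ratio exceeds `warn_factor` times the
#'   median ratio.
#' @return numeric vector of per-vertex area ratios (invisibly the warning
#'   state as attribute `distorted`).
#' @export
area_distortion <- function(mesh, param, warn_factor = 2) {
  va <- function(vrt, tri) {
    m <- triangle_mesh(vrt, tri)
    ar <- triangle_areas(m) / 3
    acc <- rep(0, nrow(vrt))
    for (j in 1:3) {
      s <- tapply(ar, tri[, j], sum)
      acc[as.integer(names(s))] <- acc[as.integer(names(s))] + s
    }
    acc
  }
  ratio <- va(mesh$vertices, mesh$triangles) /
    va(param$sphere_vertices, mesh$triangles)
  med <- stats::median(ratio)
  distorted <- max(max(ratio) / med, med / min(ratio)) > warn_factor
  if (distorted)
    warning("spherical parameterization area distortion exceeds ",
            warn_factor, "x the median; rotation null may be biased")
  structure(ratio, distorted = distorted)
}
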