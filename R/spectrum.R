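#' Laplace-Beltrami spectrum (discrete Fourier modes)
#'
#' Computes the `n_eigs` smallest generalized eigenpairs of
#' `G U = lambda M U`, the surface's intrinsic Fourier modes.  Eigenvalues
#' are in 1/mm^2 and returned ascending, starting with the numerically zero
#' eigenvalue whose eigenvector is constant.  Eigenvectors are M-orthonormal
#' and each is sign-fixed so that its entry of largest magnitude is positive,
#' making the output deterministic up to solver tolerance.
#'
#' For large meshes the problem is solved by shift-invert Lanczos (ARPACK
#' via RSpectra) with a small positive shift `sigma` that regularizes the
#' singular stiffness matrix (constants are in its kernel), a fixed
#' deterministic starting vector, and a Cholesky factorization of the mass
#' matrix used to transform the generalized problem to a standard symmetric
#' one.  Small meshes fall back to a dense LAPACK solve.
#'
#' @param fem [fem_matrices] from [assemble_fem()].
#' @param n_eigs number of eigenpairs, `1 <= n_eigs <= N - 1`.
#' @param sigma positive regularization shift (default `1e-8`).
#' @param dense_threshold meshes with `N` at or below this use the dense
#'   solver.
#' @return list of class `spectral_basis` with `values` (length `n_eigs`)
#'   and `vectors` (`N x n_eigs`).
#' @examples
#' basis <- compute_spectrum(assemble_fem(make_icosphere(2)$mesh), 5)
#' basis$values  # 0, then ~2 with multiplicity 3 (unit sphere, l = 1)
#' @export
compute_spectrum <- function(fem, n_eigs, sigma = 1e-8,
                             dense_threshold = 400L) {
  stopifnot(inherits(fem, "fem_matrices"))
  G <- fem$stiffness
  M <- fem$mass
  n <- nrow(G)
  n_eigs <- as.integer(n_eigs)
  if (n_eigs < 1L || n_eigs > n - 1L)
    stop("`n_eigs` must be in [1, N-1]")

  if (n <= dense_threshold || n_eigs > n %/% 3L) {
    R <- chol(as.matrix(M))
    W <- forwardsolve(t(R), as.matrix(G))
    A <- t(forwardsolve(t(R), t(W)))
    es <- eigen((A + t(A)) / 2, symmetric = TRUE)
    idx <- n:(n - n_eigs + 1L)
    vals <- es$values[idx]
    vecs <- backsolve(R, es$vectors[, idx, drop = FALSE])
  } else {
    chM <- Matrix::Cholesky(M, perm = TRUE, LDL = FALSE, super = FALSE)
    L <- Matrix::expand1(chM, "L")
    p <- Matrix::expand1(chM, "P1")@perm  # M[p, p] = L L'
    chG <- Matrix::Cholesky(G + sigma * M, perm = TRUE, LDL = FALSE)
    # standard form: A = Rt^-1 G Rt^-T with M = Rt Rt^T, Rt = P1' L;
    # shift-inverted operator (A + sigma I)^-1 = Rt' (G + sigma M)^-1 Rt
    opfun <- function(x, args = NULL) {
      t1 <- numeric(n)
      t1[p] <- as.numeric(L %*% x)
      t2 <- Matrix::solve(chG, t1, system = "A")
      as.numeric(Matrix::crossprod(L, t2[p]))
    }
    # generous subspace (ncv) so repeated eigenvalues (sphere-like shapes
    # with multiplicities) are fully resolved
    ncv <- min(n, max(4L * n_eigs + 1L, 25L))
    res <- RSpectra::eigs_sym(opfun, k = n_eigs, which = "LM", n = n,
                              opts = list(initvec = sin(seq_len(n)),
                                          ncv = ncv, tol = 1e-12,
                                          maxitr = 5000))
    if (length(res$values) < n_eigs || anyNA(res$values))
      stop("eigensolver did not converge (", res$nconv, "/", n_eigs,
           " eigenpairs after ", res$niter, " iterations); ",
           "increase maxitr or use the dense path")
    vals <- 1 / res$values - sigma          # mu descending -> lambda ascending
    y <- res$vectors
    vecs <- matrix(0, n, n_eigs)
    for (j in seq_len(n_eigs)) {
      z <- as.numeric(Matrix::solve(Matrix::t(L), y[, j]))
      vecs[p, j] <- z
    }
  }
  ord <- order(vals)
  vals <- pmax(vals[ord], 0)
  vecs <- vecs[, ord, drop = FALSE]
  # M-normalize (guards against roundoff) and fix signs
  for (j in seq_len(n_eigs)) {
    nj <- sqrt(as.numeric(Matrix::crossprod(vecs[, j], M %*% vecs[, j])))
    vecs[, j] <- vecs[, j] / nj
    if (vecs[which.max(abs(vecs[, j])), j] < 0) vecs[, j] <- -vecs[, j]
  }
  structure(list(values = vals, vectors = vecs), class = "spectral_basis")
}

#' @export
print.spectral_basis <- function(x, ...) {
  cat(sprintf("spectral_basis: %d modes on %d vertices\n  eigenvalues: %s%s\n",
              length(x$values), nrow(x$vectors),
              paste(signif(utils::head(x$values, 6), 4), collapse = ", "),
              if (length(x$values) > 6) ", ..." else ""))
  invisible(x)
}

#' Nodal domains of an eigenfunction
#'
#' Connected regions of constant sign of a discrete eigenfunction under
#' vertex adjacency, with exact zeros counted as positive.  By Courant's
#' nodal theorem the i-th eigenfunction (0-based, i >= 1) has between 2 and
#' i + 1 nodal domains in the continuous setting; the discrete count is the
#' standard empirical analogue.
#'
#' @param mesh a [triangle_mesh].
#' @param eigenvector numeric vector of length N.
#' @return list of class `nodal_decomposition`: `domain_id` (per-vertex
#'   component index), `n_domains`, and `nodal_line_vertices` (endpoints of
#'   sign-changing edges).
#' @export
nodal_domains <- function(mesh, eigenvector) {
  n <- nrow(mesh$vertices)
  if (length(eigenvector) != n)
    stop("eigenvector length must equal the vertex count")
  pos <- eigenvector >= 0
  e <- mesh_edges(mesh)
  same <- pos[e[, 1L]] == pos[e[, 2L]]
  g <- igraph::graph_from_edgelist(e[same, , drop = FALSE], directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  comp <- igraph::components(g)
  structure(list(
    domain_id = comp$membership[seq_len(n)],
    n_domains = comp$no,
    nodal_line_vertices = sort(unique(as.integer(e[!same, ])))
  ), class = "nodal_decomposition")
}

#' Fiedler-extremal geodesic length
#'
#' Geodesic distance between the vertices where the first nontrivial
#' eigenfunction (the Fiedler vector) attains its maximum and minimum.  On
#' elongated surfaces these extrema approximate the two most geodesically
#' distant points, so the length serves as the size normalizer for
#' sulcus-boundary distances.
#'
#' @param mesh a [triangle_mesh].
#' @param basis a `spectral_basis` with at least 2 columns.
#' @param method geodesic scheme, see [geodesic_distance_map()].
#' @return list with `length_mm` and `vertices` (the two extremal indices).
#' @export
fiedler_extremal_geodesic <- function(mesh, basis, method = "fast_marching") {
  stopifnot(inherits(basis, "spectral_basis"))
  if (ncol(basis$vectors) < 2L)
    stop("basis must contain at least 2 eigenvectors")
  f <- basis$vectors[, 2L]
  vmax <- which.max(f)
  vmin <- which.min(f)
  d <- geodesic_distance_map(mesh, vmax, method = method)
  list(length_mm = d[vmin], vertices = c(vmax, vmin))
}
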