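#' First-order FEM matrices of the Laplace-Beltrami operator
#'
#' Assembles the sparse stiffness matrix `G` (cotangent formula) and mass
#' matrix `M` (consistent P1 by default) of the discrete generalized
#' eigenproblem `G U = lambda M U` on a triangle mesh.  For the edge `ij`
#' shared by two triangles with opposite angles `alpha` and `beta`,
#' `G_ij = -(cot alpha + cot beta) / 2` and the diagonal is minus the
#' off-diagonal row sum, so constants are in the kernel.  The consistent P1
#' mass accumulates, per triangle of area `A`, `A/6` on its three diagonal
#' entries and `A/12` on its off-diagonal entries; the lumped option places
#' the full row sum on the diagonal instead.
#'
#' @param mesh a [triangle_mesh]; must pass [validate_mesh()] unless
#'   `check = FALSE` (used for single-element unit checks on open meshes).
#' @param lumped logical; if `TRUE` use the lumped (diagonal) mass matrix.
#' @param check logical; validate topology first (default `TRUE`).
#' @return list of class `fem_matrices` with sparse symmetric `stiffness`
#'   and `mass` (`dsCMatrix`), both `N x N`.
#' @examples
#' fem <- assemble_fem(make_icosphere(2)$mesh)
#' sum(fem$mass)      # total surface area, close to 4*pi
#' @export
assemble_fem <- function(mesh, lumped = FALSE, check = TRUE) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (check) assert_valid_mesh(mesh)
  v <- mesh$vertices
  tr <- mesh$triangles
  areas <- triangle_areas(mesh)
  bad <- which(areas < 1e-12)
  if (length(bad))
    stop("degenerate triangle(s) with area < 1e-12 mm^2: ",
         paste(bad[seq_len(min(5L, length(bad)))], collapse = ", "))
  n <- nrow(v)
  i1 <- tr[, 1L]; i2 <- tr[, 2L]; i3 <- tr[, 3L]
  # cot of angle at vertex a opposite edge (b, c)
  cot_at <- function(a, b, c) {
    u <- v[b, , drop = FALSE] - v[a, , drop = FALSE]
    w <- v[c, , drop = FALSE] - v[a, , drop = FALSE]
    dot <- rowSums(u * w)
    cx <- u[, 2L] * w[, 3L] - u[, 3L] * w[, 2L]
    cy <- u[, 3L] * w[, 1L] - u[, 1L] * w[, 3L]
    cz <- u[, 1L] * w[, 2L] - u[, 2L] * w[, 1L]
    dot / sqrt(cx^2 + cy^2 + cz^2)
  }
  c1 <- cot_at(i1, i2, i3)  # opposite edge (i2, i3)
  c2 <- cot_at(i2, i3, i1)  # opposite edge (i3, i1)
  c3 <- cot_at(i3, i1, i2)  # opposite edge (i1, i2)
  ii <- c(i2, i3, i1)
  jj <- c(i3, i1, i2)
  ww <- -0.5 * c(c1, c2, c3)
  # symmetrize off-diagonals, then set diagonal to minus the row sums
  G <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(ww, ww),
                            dims = c(n, n))
  Matrix::diag(G) <- Matrix::diag(G) - Matrix::rowSums(G)
  G <- Matrix::forceSymmetric(G)

  if (lumped) {
    mdiag <- rep(0, n)
    acc <- tapply(rep(areas / 3, 3L), c(i1, i2, i3), sum)
    mdiag[as.integer(names(acc))] <- acc
    M <- Matrix::forceSymmetric(as(Matrix::Diagonal(n, mdiag), "CsparseMatrix"))
  } else {
    off <- rep(areas / 12, 3L)
    dia <- rep(areas / 6, 3L)
    M <- Matrix::sparseMatrix(
      i = c(ii, jj, i1, i2, i3),
      j = c(jj, ii, i1, i2, i3),
      x = c(off, off, dia),
      dims = c(n, n))
    M <- Matrix::forceSymmetric(M)
  }
  structure(list(stiffness = as(G, "CsparseMatrix"),
                 mass = as(M, "CsparseMatrix"),
                 lumped = lumped),
            class = "fem_matrices")
}

#' @export
print.fem_matrices <- function(x, ...) {
  cat(sprintf("fem_matrices: N=%d, %s mass, area=%.6g mm^2\n",
              nrow(x$stiffness), if (x$lumped) "lumped" else "consistent P1",
              sum(x$mass)))
  invisible(x)
}
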