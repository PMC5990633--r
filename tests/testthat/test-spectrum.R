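test_that("trivial eigenpair is numerically zero with a constant mode", {
  b <- spectrum_fixture("ico3", ico(3)$mesh, 9)
  expect_lt(b$values[1L], 1e-8 * b$values[2L])
  v0 <- b$vectors[, 1L]
  expect_lt(stats::sd(v0) / abs(mean(v0)), 1e-6)
  expect_true(all(diff(b$values) >= -1e-10))
})

test_that("eigenvectors are M-orthonormal and reproducible", {
  fem <- assemble_fem(ico(3)$mesh)
  b1 <- compute_spectrum(fem, 6)
  b2 <- compute_spectrum(fem, 6)
  expect_identical(b1$vectors, b2$vectors)
  gram <- as.matrix(Matrix::crossprod(b1$vectors, fem$mass %*% b1$vectors))
  expect_lt(max(abs(gram - diag(6))), 1e-6)
  # sign convention: largest-magnitude entry positive
  for (j in 1:6)
    expect_gt(b1$vectors[which.max(abs(b1$vectors[, j])), j], 0)
})

test_that("dense and shift-invert solver paths agree", {
  # tri-axial ellipsoid: simple (non-degenerate) low eigenvalues, so the
  # two solvers must agree column by column up to sign
  fe <- make_folded_ellipsoid(c(3, 1.2, 1), 0.15, seed = 4)
  fem <- assemble_fem(fe$mesh)
  bs <- compute_spectrum(fem, 6)                         # ARPACK (N = 642)
  bd <- compute_spectrum(fem, 6, dense_threshold = 1e6)  # dense LAPACK
  expect_equal(bs$values, bd$values, tolerance = 1e-7)
  # compare eigenspaces grouped by near-equal eigenvalues (a close pair may
  # legitimately return a rotated basis): M-Gram singular values must be 1
  M <- fem$mass
  groups <- split(seq_len(6), cumsum(c(1, diff(bs$values) >
                                         1e-3 * (bs$values[-1L] + 1))))
  for (g in groups) {
    C <- as.matrix(Matrix::crossprod(bs$vectors[, g, drop = FALSE],
                                     M %*% bd$vectors[, g, drop = FALSE]))
    expect_true(all(abs(svd(C)$d - 1) < 1e-5))
  }
})

test_that("eigenvalues scale as 1/r^2 and refinement error decreases", {
  b1 <- spectrum_fixture("ico3", ico(3)$mesh, 9)
  b2 <- compute_spectrum(assemble_fem(make_icosphere(3, radius = 2)$mesh), 9)
  expect_equal(b1$values[2:9] / b2$values[2:9], rep(4, 8), tolerance = 0.02)
  errs <- vapply(2:4, function(s) {
    b <- spectrum_fixture(paste0("ico", s), ico(s)$mesh, 4)
    abs(b$values[2L] - 2)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("nodal domains split signs into connected components", {
  fe <- fixture("prolate3", make_folded_ellipsoid(c(3, 1, 1), 0, seed = 1,
                                                  subdivisions = 4))
  b <- spectrum_fixture("prolate3", fe$mesh, 3)
  nd <- nodal_domains(fe$mesh, b$vectors[, 2L])
  expect_equal(nd$n_domains, 2L)
  # Fiedler nodal line hugs the x = 0 symmetry plane (within one local edge)
  x <- fe$mesh$vertices[nd$nodal_line_vertices, 1L]
  expect_lt(max(abs(x)), 0.3)
  const <- nodal_domains(fe$mesh, rep(1, nrow(fe$mesh$vertices)))
  expect_equal(const$n_domains, 1L)
  expect_length(const$nodal_line_vertices, 0L)
  expect_error(nodal_domains(fe$mesh, 1:5), "length")
})

test_that("Fiedler extrema are antipodal on the sphere and axial on ellipsoids", {
  b <- spectrum_fixture("ico4", ico(4)$mesh, 2)
  fg <- fiedler_extremal_geodesic(ico(4)$mesh, b)
  expect_lt(abs(fg$length_mm - pi) / pi, 0.03)
  fe <- fixture("prolate3", make_folded_ellipsoid(c(3, 1, 1), 0, seed = 1,
                                                  subdivisions = 4))
  bp <- spectrum_fixture("prolate3", fe$mesh, 3)
  fgp <- fiedler_extremal_geodesic(fe$mesh, bp)
  expect_true(all(abs(fe$mesh$vertices[fgp$vertices, 1L]) > 2.7))
  # invariant to the sign of the Fiedler vector
  bf <- bp
  bf$vectors[, 2L] <- -bf$vectors[, 2L]
  expect_equal(fiedler_extremal_geodesic(fe$mesh, bf)$length_mm,
               fgp$length_mm)
})

test_that("requesting an invalid number of eigenpairs errors", {
  fem <- assemble_fem(ico(1)$mesh)
  expect_error(compute_spectrum(fem, 0), "n_eigs")
  expect_error(compute_spectrum(fem, nrow(fem$mass)), "n_eigs")
})
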