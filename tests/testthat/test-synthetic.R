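test_that("icosphere has the closed-form vertex/triangle counts and radius", {
  expect_equal(nrow(ico(0)$mesh$vertices), 12L)
  expect_equal(nrow(ico(0)$mesh$triangles), 20L)
  expect_equal(nrow(ico(3)$mesh$vertices), 642L)   # 10 * 4^3 + 2
  expect_equal(nrow(ico(3)$mesh$triangles), 1280L)
  r2 <- make_icosphere(4, radius = 2)
  expect_lt(max(abs(sqrt(rowSums(r2$mesh$vertices^2)) - 2)), 1e-9)
  expect_error(make_icosphere(2, radius = -1), "positive")
  expect_error(make_icosphere(8), "\\[0, 7\\]")
})

test_that("icosphere area converges monotonically to the sphere area", {
  errs <- vapply(2:4, function(s)
    abs(surface_area(ico(s)$mesh) - 4 * pi), numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3L] / (4 * pi), 0.005)
})

test_that("every generated fixture passes full topological validation", {
  for (m in list(ico(2)$mesh,
                 make_folded_ellipsoid(c(3, 1.2, 1), 0.15, seed = 3)$mesh,
                 make_folded_ellipsoid(c(2, 2, 2), 0, seed = 1,
                                       subdivisions = 2)$mesh))
    expect_true(validate_mesh(m)$ok)
})

test_that("folded ellipsoid is a pure function of its arguments", {
  a <- make_folded_ellipsoid(c(3, 1, 1), amplitude = 0.15, seed = 7)
  b <- make_folded_ellipsoid(c(3, 1, 1), amplitude = 0.15, seed = 7)
  expect_identical(a$mesh$vertices, b$mesh$vertices)
  expect_identical(a$mesh$triangles, b$mesh$triangles)
  c <- make_folded_ellipsoid(c(3, 1, 1), amplitude = 0.15, seed = 8)
  expect_false(identical(a$mesh$vertices, c$mesh$vertices))
})

test_that("zero amplitude yields the exact ellipsoid; invalid args rejected", {
  fe <- make_folded_ellipsoid(c(3, 2, 1), amplitude = 0, seed = 1)
  u <- sweep(fe$mesh$vertices, 2L, c(3, 2, 1), "/")
  expect_lt(max(abs(sqrt(rowSums(u^2)) - 1)), 1e-12)
  sph <- make_folded_ellipsoid(c(1, 1, 1), amplitude = 0, subdivisions = 4,
                               seed = 1)
  expect_lt(abs(surface_area(sph$mesh) - 4 * pi) / (4 * pi), 0.005)
  expect_error(make_folded_ellipsoid(c(3, 1, 1), amplitude = 1, seed = 1),
               "self-intersection")
  expect_error(make_folded_ellipsoid(c(1, 2, 1), amplitude = 0, seed = 1),
               "a >= b >= c")
})

test_that("constraint cap matches a brute-force angular test", {
  p <- ico(3)$param
  expect_length(make_constraint_cap(p, c(0, 0, 1), 0)$vertex_indices, 0L)
  expect_length(make_constraint_cap(p, c(0, 0, 1), 180)$vertex_indices,
                nrow(p$sphere_vertices))
  cap <- make_constraint_cap(p, c(0, 0, 1), 30)
  ang <- acos(pmin(1, pmax(-1, p$sphere_vertices[, 3L]))) * 180 / pi
  expect_identical(cap$vertex_indices, which(ang < 30))
  expect_warning(make_constraint_cap(p, c(0, 0, 2), 30), "normalized")
})

test_that("synthetic sulcus is an edge-adjacent vertex path near the plane", {
  m <- ico(3)$mesh
  line <- make_synthetic_sulcus(m, c(0, 0, 1), 0)
  v <- line$vertex_indices
  expect_gt(length(v), 10L)
  expect_false(anyDuplicated(v) > 0L)
  ek <- paste(pmin(mesh_edges_test(m)[, 1L], mesh_edges_test(m)[, 2L]),
              pmax(mesh_edges_test(m)[, 1L], mesh_edges_test(m)[, 2L]))
  pairs <- paste(pmin(v[-length(v)], v[-1L]), pmax(v[-length(v)], v[-1L]))
  expect_true(all(pairs %in% ek))
  # every line vertex within one local edge length of the plane
  el <- max(sqrt(rowSums((m$vertices[mesh_edges_test(m)[, 1L], ] -
                            m$vertices[mesh_edges_test(m)[, 2L], ])^2)))
  expect_true(all(abs(m$vertices[v, 3L]) < el))
  expect_error(make_synthetic_sulcus(m, c(0, 0, 1), 2), "does not intersect")
})
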