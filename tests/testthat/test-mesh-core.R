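test_that("tet_volume matches closed forms and the cofactor oracle", {
  expect_equal(tet_volume(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                                c(0, 0, 1))), 1 / 6)
  # coplanar points are degenerate
  expect_equal(tet_volume(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                                c(1, 1, 0))), 0)
  set.seed(42)
  for (i in 1:20) {
    p <- matrix(runif(12, -5, 5), 4, 3)
    expect_equal(tet_volume(p), oracle_tet_volume(p), tolerance = 1e-12)
  }
})

test_that("element volumes of a slab sum to the analytic box volume", {
  m <- small_slab()
  expect_equal(sum(tet_volumes(m)), 10 * 10 * 4, tolerance = 1e-9)
  expect_true(all(tet_volumes(m) > 0))
})

test_that("locate_point finds centroids, rejects outside points, and agrees with the exhaustive scan", {
  m <- small_slab()
  for (e in c(1L, 7L, 150L, m$n_elements)) {
    cen <- colMeans(m$nodes[m$elements[e, ], ])
    found <- locate_point(m, cen)
    # centroid is strictly interior, so the answer is unique
    expect_identical(found, e)
  }
  expect_identical(locate_point(m, c(50, 50, 50)), NA_integer_)
  expect_identical(locate_point(m, c(-0.5, 5, 2)), NA_integer_)

  set.seed(7)
  n_agree <- 0L
  for (i in 1:100) {
    p <- c(runif(1, 0, 10), runif(1, 0, 10), runif(1, 0, 4))
    a <- locate_point(m, p)
    b <- oracle_locate(m, p)
    if (identical(a, b)) {
      n_agree <- n_agree + 1L
    } else {
      # points on shared faces may legitimately return either element;
      # both must contain the point
      bar <- mmcadapt:::barycentric_in_element(m, a, p)
      expect_true(all(bar >= -1e-8))
    }
  }
  expect_gte(n_agree, 99L)
})

test_that("edge_set enumerates edges and incidences like the brute-force scan", {
  one <- unit_right_tet()
  es <- edge_set(one)
  expect_identical(nrow(es$edges), 6L)
  expect_true(all(lengths(es$incident) == 1L))

  two <- two_tet_mesh()
  es2 <- edge_set(two)
  expect_identical(nrow(es2$edges), 9L)
  shared <- vapply(seq_len(nrow(es2$edges)), function(i)
    all(es2$edges[i, ] %in% 2:4), TRUE)
  expect_identical(sum(shared), 3L)
  expect_true(all(lengths(es2$incident)[shared] == 2L))
  expect_true(all(lengths(es2$incident)[!shared] == 1L))

  m <- small_slab()
  es3 <- edge_set(m)
  orc <- oracle_edges(m)
  expect_identical(nrow(es3$edges), length(ls(orc)))
  for (i in seq_len(nrow(es3$edges))) {
    k <- paste(es3$edges[i, 1], es3$edges[i, 2], sep = "_")
    expect_identical(sort(es3$incident[[i]]), sort(orc[[k]]))
  }
})

test_that("mean-ratio quality is 1 for regular tets, small for slivers, monotone under flattening", {
  expect_equal(min_quality(regular_tet_mesh()), 1, tolerance = 1e-9)

  sliver <- tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                           c(0.5, 0.5, 1e-3)), matrix(1:4, 1))
  expect_lt(min_quality(sliver), 0.05)

  # move the apex of a regular tet toward the opposite face
  base <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1))
  apex0 <- c(-1, -1, 1)
  target <- colMeans(base)
  qs <- vapply(seq(0, 0.9, by = 0.1), function(s) {
    nodes <- rbind(base, apex0 + s * (target - apex0))
    min_quality(tet_mesh(nodes, reorient_elements(nodes, matrix(1:4, 1))))
  }, 1.0)
  expect_true(all(diff(qs) < 0))
})

test_that("conformity validation accepts fixtures and rejects broken meshes", {
  expect_true(validate_mesh(small_slab()))
  expect_true(validate_mesh(make_slice_phantom(6, 4, 4, 1.5)))
  # an element repeating a node
  expect_error(tet_mesh(diag(3), rbind(c(1, 1, 2, 3))), "repeats")
  # index out of range
  expect_error(
    tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
             rbind(c(1, 2, 3, 5))), "outside")
  # nonpositive volume (flipped orientation)
  expect_error(
    tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
             rbind(c(1, 3, 2, 4))), "nonpositive")
})

test_that("node volume shares partition the mesh volume", {
  m <- small_slab()
  expect_equal(sum(node_volumes(m)), mesh_volume(m), tolerance = 1e-12)
  expect_true(all(node_volumes(m) > 0))
})

test_that("boundary extraction identifies the slab surface", {
  m <- small_slab()
  bn <- boundary_nodes(m)
  on_surface <- m$nodes[, 1] %in% c(0, 10) | m$nodes[, 2] %in% c(0, 10) |
                m$nodes[, 3] %in% c(0, 4)
  expect_identical(bn, on_surface)
  # interior faces shared by exactly 2 elements: neighbor table symmetric
  nb <- element_neighbors(m)
  for (e in c(1L, 50L, 299L)) for (f in 1:4) {
    other <- nb[e, f]
    if (!is.na(other)) expect_true(e %in% nb[other, ])
  }
})
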