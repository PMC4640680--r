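test_that("the transformation between identical meshes is the identity", {
  m <- make_slab_mesh(6, 6, 4, 2)
  tr <- build_transformation(m, m)
  expect_true(all(tr$cases == "carried"))
  expect_equal(as.matrix(tr$matrix), diag(m$n_nodes), tolerance = 0)
  set.seed(1)
  W <- matrix(runif(5 * m$n_nodes), 5, m$n_nodes)
  expect_identical(rescale_jacobian(W, tr), W)
})

test_that("a node at the centroid of a regular tet gets four equal weights", {
  old <- regular_tet_mesh()
  cen <- colMeans(old$nodes)
  new_nodes <- rbind(cen, cen + c(0.3, 0, 0), cen + c(0, 0.3, 0),
                     cen + c(0, 0, 0.3))
  new <- tet_mesh(new_nodes, reorient_elements(new_nodes, matrix(1:4, 1)))
  tr <- build_transformation(old, new)
  expect_identical(tr$cases[1], "interior")
  expect_equal(as.numeric(tr$matrix[, 1]), rep(0.25, 4), tolerance = 1e-12)
})

test_that("inverse-distance weights match the hand-computed reference point", {
  old <- unit_right_tet()
  p <- c(0.25, 0.25, 0.25)
  new_nodes <- rbind(p, p + c(0.2, 0, 0), p + c(0, 0.2, 0),
                     p + c(0, 0, 0.2))
  new <- tet_mesh(new_nodes, reorient_elements(new_nodes, matrix(1:4, 1)))
  tr <- build_transformation(old, new)
  # distances 0.4330 (origin) and 0.8292 (other three vertices)
  expect_equal(as.numeric(tr$matrix[, 1]),
               c(0.390, 0.203, 0.203, 0.203), tolerance = 2e-3)
})

test_that("the opt-in barycentric mode reproduces linear shape functions", {
  old <- unit_right_tet()
  p <- c(0.1, 0.2, 0.3)
  new_nodes <- rbind(p, p + c(0.1, 0, 0), p + c(0, 0.1, 0),
                     p + c(0, 0, 0.1))
  new <- tet_mesh(new_nodes, reorient_elements(new_nodes, matrix(1:4, 1)))
  tr <- build_transformation(old, new, method = "barycentric")
  expect_equal(as.numeric(tr$matrix[, 1]), c(0.4, 0.1, 0.2, 0.3),
               tolerance = 1e-12)
  # a constant field is preserved in either mode
  expect_lt(max(abs(Matrix::colSums(tr$matrix) - 1)), 1e-12)
})

test_that("nodes outside the input mesh use their four nearest input nodes", {
  old <- make_slab_mesh(4, 4, 4, 2)
  p <- c(2, 2, 5.5)                      # above the slab
  new_nodes <- rbind(p, p + c(0.5, 0, 0), p + c(0, 0.5, 0),
                     p + c(0, 0, 0.5))
  new <- tet_mesh(new_nodes, reorient_elements(new_nodes, matrix(1:4, 1)))
  tr <- build_transformation(old, new)
  expect_identical(tr$cases[1], "exterior")
  col <- tr$matrix[, 1]
  nz <- which(col != 0)
  expect_length(nz, 4L)
  d <- sqrt(rowSums((old$nodes - matrix(p, old$n_nodes, 3, byrow = TRUE))^2))
  expect_setequal(nz, order(d)[1:4])
  w <- 1 / d[nz]
  expect_equal(as.numeric(col[nz]), w / sum(w), tolerance = 1e-12)
})

test_that("every transformation column is a convex combination", {
  f <- slice_fixture()
  res <- adapt_loop(f$mesh, "attenuation", size_field_params(1.25),
                    adapt_config(max_iterations = 3),
                    optodes = f$optodes, props = f$props)
  for (tr in res$transformations) {
    cs <- Matrix::colSums(tr$matrix)
    expect_lt(max(abs(cs - 1)), 1e-12)
    expect_true(all(tr$matrix@x >= 0))
    nnz <- diff(tr$matrix@p)
    expect_true(all(nnz >= 1 & nnz <= 4))
  }
})

test_that("rescaling preserves constants, nonnegativity and interior value ranges", {
  set.seed(2)
  old <- make_slab_mesh(8, 8, 4, 2)
  # random refinement so interior/exterior cases appear
  es <- edge_set(old)
  new <- old
  for (i in sample(nrow(es$edges), 5)) {
    esn <- edge_set(new)
    new <- split_edge(new, esn$edges[sample(nrow(esn$edges), 1), ])
  }
  tr <- build_transformation(old, new)
  expect_true(any(tr$cases != "carried"))

  const <- matrix(3.25, 2, old$n_nodes)
  expect_equal(as.numeric(rescale_jacobian(const, tr)),
               rep(3.25, 2 * new$n_nodes), tolerance = 1e-12)

  W <- matrix(rexp(3 * old$n_nodes), 3, old$n_nodes)
  Wr <- rescale_jacobian(W, tr)
  expect_true(all(Wr >= 0))
  interior_cols <- which(tr$cases == "interior")
  for (j in interior_cols) {
    expect_lte(max(Wr[, j]), max(W) + 1e-12)
    expect_gte(min(Wr[, j]), min(W) - 1e-12)
  }

  # per-node oracle: explicit weight loop
  Tm <- as.matrix(tr$matrix)
  for (j in sample(new$n_nodes, 20)) {
    oracle <- as.numeric(W %*% Tm[, j])
    expect_equal(as.numeric(Wr[, j]), oracle, tolerance = 1e-12)
  }
})

test_that("composed transformations equal sequential rescaling", {
  f <- slice_fixture()
  set.seed(6)
  res <- adapt_loop(f$mesh, "attenuation", size_field_params(1.25),
                    adapt_config(max_iterations = 2),
                    optodes = f$optodes, props = f$props)
  expect_gte(length(res$transformations), 2L)
  t1 <- res$transformations[[1]]
  t2 <- res$transformations[[2]]
  W <- matrix(rexp(2 * f$mesh$n_nodes), 2, f$mesh$n_nodes)
  seq_r <- rescale_jacobian(rescale_jacobian(W, t1), t2)
  one_r <- rescale_jacobian(W, compose_transformations(t1, t2))
  expect_equal(seq_r, one_r, tolerance = 1e-12)
})

test_that("transformations round-trip through the triplet container", {
  old <- make_slab_mesh(6, 6, 4, 2)
  new <- split_edge(old, edge_set(old)$edges[10, ])
  tr <- build_transformation(old, new)
  path <- file.path(tempdir(), "trans.json")
  write_transformation(tr, path)
  back <- read_transformation(path)
  expect_equal(as.matrix(back$matrix), as.matrix(tr$matrix))
  expect_identical(back$cases, tr$cases)
})
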