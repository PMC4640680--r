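test_that("splitting an edge of the unit tet bisects it exactly", {
  m <- unit_right_tet()
  out <- split_edge(m, c(1, 2))
  expect_identical(out$n_elements, 2L)
  expect_identical(out$n_nodes, 5L)
  expect_equal(sort(tet_volumes(out)), c(1 / 12, 1 / 12), tolerance = 1e-15)
  expect_true(validate_mesh(out))
  expect_error(split_edge(m, c(1, 9)), "node indices")
})

test_that("splitting the shared edge of a two-tet mesh keeps it conforming", {
  m <- two_tet_mesh()
  out <- split_edge(m, c(2, 3))     # edge on the shared face
  expect_identical(out$n_elements, 4L)
  expect_identical(out$n_nodes, 6L)
  expect_true(validate_mesh(out))
  expect_equal(mesh_volume(out), mesh_volume(m), tolerance = 1e-12)
})

test_that("any split conserves total volume to machine precision", {
  m <- small_slab()
  es <- edge_set(m)
  set.seed(4)
  for (i in sample(nrow(es$edges), 10)) {
    out <- split_edge(m, es$edges[i, ])
    expect_equal(mesh_volume(out), mesh_volume(m), tolerance = 1e-12)
    expect_identical(out$n_nodes, m$n_nodes + 1L)
    expect_true(validate_mesh(out))
  }
})

test_that("collapsing an interior edge removes one node and keeps volumes positive", {
  m <- make_slab_mesh(8, 8, 8, 2)
  interior <- which(!boundary_nodes(m))
  es <- edge_set(m)
  both_int <- which(es$edges[, 1] %in% interior &
                    es$edges[, 2] %in% interior)
  expect_gt(length(both_int), 0)
  e <- es$edges[both_int[1], ]
  out <- collapse_edge(m, e, kept_node = e[1])
  expect_false(is_rejected(out))
  expect_identical(out$n_nodes, m$n_nodes - 1L)
  expect_true(all(tet_volumes(out) > 0))
  expect_true(validate_mesh(out))
  expect_equal(mesh_volume(out), mesh_volume(m), tolerance = 1e-9)
})

test_that("a collapse that would invert an element is rejected", {
  # ring of three nodes around interior edge (a, b) at x = 0.5, plus a far
  # element behind that plane: pulling b onto a flips the far element
  nodes <- rbind(c(0, 0, 0),                    # a
                 c(1, 0, 0),                    # b
                 c(0.5, 0, 1),                  # ring
                 c(0.5, -0.866, -0.5),
                 c(0.5, 0.866, -0.5))
  el <- rbind(c(1, 2, 3, 4), c(1, 2, 4, 5), c(1, 2, 5, 3),
              c(2, 3, 4, 5))
  m <- tet_mesh(nodes, reorient_elements(nodes, el))
  res <- collapse_edge(m, c(1, 2), kept_node = 1)
  expect_true(is_rejected(res))
  expect_identical(res$reason, "inversion")
})

test_that("boundary nodes may not merge into the interior", {
  m <- make_slab_mesh(8, 8, 8, 2)
  bn <- boundary_nodes(m)
  es <- edge_set(m)
  mixed <- which(bn[es$edges[, 1]] != bn[es$edges[, 2]])
  e <- es$edges[mixed[1], ]
  interior_end <- if (bn[e[1]]) e[2] else e[1]
  res <- collapse_edge(m, e, kept_node = interior_end)
  expect_true(is_rejected(res))
  expect_identical(res$reason, "boundary")
})

test_that("a unit size field is a fixed point of adapt_once", {
  m <- make_slab_mesh(8, 8, 4, 2)
  out <- adapt_once(m, uniform_size_field(m, 1))
  expect_identical(out$mesh$n_nodes, m$n_nodes)
  expect_identical(out$mesh$n_elements, m$n_elements)
  expect_identical(out$record$splits, 0L)
  expect_identical(out$record$collapses, 0L)
})

test_that("uniform coarsening and refinement move node counts in the expected direction", {
  fine <- make_slab_mesh(10, 10, 4, 1)
  co <- adapt_once(fine, uniform_size_field(fine, 1.5))
  expect_lt(co$mesh$n_nodes, fine$n_nodes)
  expect_gt(co$record$collapses, 0L)
  expect_true(validate_mesh(co$mesh))

  coarse <- make_slab_mesh(8, 8, 8, 4)
  re <- adapt_once(coarse, uniform_size_field(coarse, 0.5))
  expect_gt(re$mesh$n_nodes, coarse$n_nodes)
  expect_gt(re$record$splits, 0L)
  expect_true(validate_mesh(re$mesh))
})

test_that("adaptation passes preserve conformity and total volume within 2 percent", {
  m <- make_slice_phantom(6, 4, 4, 1)
  opt <- place_transmission_optodes(m, 3, 3)
  res <- adapt_loop(m, "attenuation", size_field_params(1.25),
                    adapt_config(max_iterations = 12),
                    optodes = opt, props = default_properties(),
                    build_transforms = FALSE)
  expect_true(validate_mesh(res$mesh))
  drift <- abs(mesh_volume(res$mesh) - mesh_volume(m)) / mesh_volume(m)
  expect_lt(drift, 0.02)
  # node counts never increase under a coarsening-only recipe
  counts <- c(m$n_nodes, res$report$nodes)
  expect_true(all(diff(counts) <= 0))
})

test_that("a degenerate size-factor range converges immediately", {
  m <- make_slice_phantom(6, 4, 4, 1.5)
  opt <- place_transmission_optodes(m, 3, 3)
  res <- adapt_loop(m, "attenuation",
                    size_field_params(max_size_factor = 1,
                                      min_size_factor = 1),
                    optodes = opt, props = default_properties(),
                    build_transforms = FALSE)
  expect_identical(nrow(res$report), 1L)
  expect_true(res$converged)
  expect_identical(res$report$nodes[1], m$n_nodes)
})

test_that("the volume cutoff stops the loop at the first offending iteration", {
  m <- make_slice_phantom(6, 4, 4, 1)
  opt <- place_transmission_optodes(m, 3, 3)
  cutoff <- max(tet_volumes(m)) * 1.05
  res <- adapt_loop(m, "attenuation", size_field_params(1.35),
                    adapt_config(max_iterations = 12,
                                 volume_cutoff = cutoff),
                    optodes = opt, props = default_properties(),
                    build_transforms = FALSE)
  expect_identical(res$stopped_by, "volume_cutoff")
  r <- res$report
  expect_gte(r$max_elem_vol_mm3[nrow(r)], cutoff)
  if (nrow(r) > 1)
    expect_true(all(r$max_elem_vol_mm3[seq_len(nrow(r) - 1)] < cutoff))
})

test_that("Jacobian-based recipes require a Jacobian", {
  m <- make_slab_mesh(6, 6, 4, 2)
  expect_error(adapt_loop(m, "sum_jacobian", size_field_params(1.25)),
               "Jacobian")
})
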