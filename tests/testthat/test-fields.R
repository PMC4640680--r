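fake_jacobian <- function(W_array, mesh) {
  s <- optode(c(0, 0, 0), c(0, 0, 1), "source")
  d <- optode(c(0, 0, 1), c(0, 0, -1), "detector")
  gat <- time_gating(50, dim(W_array)[2])
  slices <- lapply(seq_len(dim(W_array)[1]), function(p)
    matrix(W_array[p, , ], nrow = dim(W_array)[2]))
  jac <- jacobian(slices, rep(list(list(source = s, detector = d)),
                              dim(W_array)[1]), gat, mesh)
  jac
}

test_that("sensitivity sums and their log match explicit loops", {
  m <- make_slab_mesh(4, 4, 4, 4)   # 8 nodes... actually 2x2x2 grid
  n <- m$n_nodes
  set.seed(77)
  W <- array(rexp(3 * 4 * n), dim = c(3, 4, n))
  jac <- fake_jacobian(W, m)

  oracle <- numeric(n)
  for (p in 1:3) for (k in 1:4) for (r in 1:n)
    oracle[r] <- oracle[r] + W[p, k, r]
  f <- sum_jacobian(jac)
  expect_equal(f$values, oracle, tolerance = 1e-12)
  expect_identical(f$orientation, "coarsen_low")

  # single pair, single gate: the field is that slice
  W1 <- array(rexp(n), dim = c(1, 1, n))
  expect_equal(sum_jacobian(fake_jacobian(W1, m))$values, W1[1, 1, ],
               tolerance = 1e-12)
  # all-zero Jacobian
  W0 <- array(0, dim = c(1, 2, n))
  expect_true(all(sum_jacobian(fake_jacobian(W0, m))$values == 0))

  # log of sums (1, e, e^2, ...) is about (0, 1, 2, ...)
  vals <- exp(seq_len(n) - 1)
  Wl <- array(0, dim = c(1, 1, n)); Wl[1, 1, ] <- vals
  lf <- log_sum_jacobian(fake_jacobian(Wl, m))
  expect_equal(lf$values, seq_len(n) - 1, tolerance = 1e-5)
  expect_equal(log_sum_jacobian(jac)$values, log(oracle + min(oracle) * 1e-6),
               tolerance = 1e-12)
})

test_that("normalized sum scales each pair-gate row to unit maximum", {
  m <- make_slab_mesh(4, 4, 4, 4)
  n <- m$n_nodes
  set.seed(13)
  one <- array(rexp(n), dim = c(1, 1, n))
  f1 <- normalized_sum(fake_jacobian(one, m))
  expect_equal(max(f1$values), 1)

  two <- array(0, dim = c(2, 1, n))
  two[1, 1, ] <- one[1, 1, ]; two[2, 1, ] <- one[1, 1, ]
  f2 <- normalized_sum(fake_jacobian(two, m))
  expect_equal(max(f2$values), 2)

  W <- array(rexp(2 * 3 * n), dim = c(2, 3, n))
  W[1, 2, ] <- 0                       # a zero row must be skipped
  oracle <- numeric(n)
  for (p in 1:2) for (k in 1:3) {
    row <- W[p, k, ]
    if (max(row) > 0) oracle <- oracle + row / max(row)
  }
  expect_equal(normalized_sum(fake_jacobian(W, m))$values, oracle,
               tolerance = 1e-12)
})

test_that("curvature operator annihilates constants and matches the dense product", {
  m <- make_slab_mesh(4, 4, 4, 4)
  const <- solution_field(rep(3.7, m$n_nodes), "sum_jacobian")
  expect_equal(curvature(const)$values, rep(0, m$n_nodes),
               tolerance = 1e-12)

  two <- solution_field(c(1, 3), "sum_jacobian")
  expect_equal(curvature(two)$values, c(-2, 2))
  expect_equal(sum(curvature(two)$values), 0)

  set.seed(99)
  s <- rnorm(50)
  L <- matrix(-1 / 49, 50, 50); diag(L) <- 1
  expect_equal(curvature(solution_field(s, "sum_jacobian"))$values,
               as.numeric(L %*% s), tolerance = 1e-12)
  expect_error(curvature(solution_field(1, "sum_jacobian")), "2 nodes")
})

test_that("distance and attenuation fields reduce to closed forms", {
  m <- make_slab_mesh(10, 10, 4, 2)
  corner <- optode(c(0, 0, 0), c(0, 0, 1), "source")
  df <- distance_field(m, list(corner))
  expect_identical(df$orientation, "coarsen_high")
  expect_equal(df$values, sqrt(rowSums(m$nodes^2)), tolerance = 1e-12)
  expect_equal(df$values[1], 0)

  af0 <- attenuation_field(m, list(corner), mu = 0)
  expect_true(all(af0$values == 1))
  af <- attenuation_field(m, list(corner), mu = 0.5)
  expect_identical(af$orientation, "coarsen_low")
  node_at_2 <- which(abs(df$values - 2) < 1e-9)[1]
  expect_equal(af$values[node_at_2], exp(-1), tolerance = 1e-12)
  expect_error(attenuation_field(m, list(corner), mu = -1), "mu")
  expect_error(distance_field(m, list()), "optode")

  # multi-optode minimum against brute force
  f <- slice_fixture()
  dm <- distance_field(f$mesh, f$optodes)
  brute <- apply(vapply(f$optodes, function(o)
    sqrt(rowSums((f$mesh$nodes - matrix(o$position, f$mesh$n_nodes, 3,
                                        byrow = TRUE))^2)),
    numeric(f$mesh$n_nodes)), 1, min)
  expect_equal(dm$values, brute, tolerance = 1e-12)
})

test_that("the size-field map is continuous at thresholds, clamped and monotone", {
  params <- size_field_params(max_size_factor = 1.25)
  med <- 10
  t_lo <- 0.2 * med; t_hi <- 8 * t_lo
  # values straddling the full range, median 10
  x <- c(0.1, 1, t_lo, 3, (t_lo + t_hi) / 2, 10, 14, t_hi, 20, 30, 40)
  sf <- to_size_field(solution_field(x, "sum_jacobian"), params)
  expect_true(all(sf$factors >= 1 & sf$factors <= 1.25))
  expect_equal(sf$factors[x == t_lo], 1.25, tolerance = 1e-12)
  expect_equal(sf$factors[x == t_hi], 1, tolerance = 1e-12)
  expect_equal(sf$factors[x == (t_lo + t_hi) / 2], sqrt(1.25),
               tolerance = 1e-12)
  expect_lt(sf$factors[x == 10], 1.25)
  # monotone nonincreasing in the field value
  ord <- order(x)
  expect_true(all(diff(sf$factors[ord]) <= 1e-12))
  expect_true(all(sf$factors[x < t_lo] == 1.25))

  # coarsen_high mirror: large distances get the large factor
  dmesh <- make_slab_mesh(10, 10, 4, 2)
  dfield <- distance_field(dmesh, list(optode(c(0, 0, 0), c(0, 0, 1),
                                              "source")))
  dsf <- to_size_field(dfield, params)
  expect_equal(cor(dfield$values, dsf$factors) > 0, TRUE)
  expect_equal(dsf$factors[which.max(dfield$values)], 1.25)
})

test_that("nonpositive medians are rejected unless the shift fallback is chosen", {
  params <- size_field_params(1.25)
  neg <- solution_field(c(-3, -2, -1, 0.5, 1), "log_sum_jacobian")
  expect_error(to_size_field(neg, params), "median")
  shifted <- to_size_field(neg, params, fallback = "shift")
  expect_true(all(shifted$factors >= 1 & shifted$factors <= 1.25))
})

test_that("the recipe dispatcher enforces its input contracts", {
  m <- make_slab_mesh(4, 4, 4, 4)
  expect_error(compute_solution_field("sum_jacobian", m), "Jacobian")
  expect_error(compute_solution_field("attenuation", m), "optodes")
  opt <- list(optode(c(0, 0, 0), c(0, 0, 1), "source"))
  f <- compute_solution_field("distance", m, optodes = opt)
  expect_identical(f$kind, "distance")
  f2 <- compute_solution_field("attenuation", m, optodes = opt,
                               props = default_properties())
  expect_identical(f2$kind, "attenuation")
})
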