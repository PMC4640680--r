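# shared fixture builders and independent oracles (kept deliberately
# separate from the package's own code paths)

unit_right_tet <- function() {
  tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
           matrix(1:4, 1))
}

regular_tet_mesh <- function() {
  nodes <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  tet_mesh(nodes, reorient_elements(nodes, matrix(1:4, 1)))
}

two_tet_mesh <- function() {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                 c(1, 1, 1))
  el <- rbind(c(1, 2, 3, 4), c(2, 3, 4, 5))
  tet_mesh(nodes, reorient_elements(nodes, el))
}

small_slab <- function() make_slab_mesh(10, 10, 4, 2)

# volume by explicit cofactor expansion of the 3x3 edge matrix
oracle_tet_volume <- function(p) {
  a <- p[2, ] - p[1, ]; b <- p[3, ] - p[1, ]; c <- p[4, ] - p[1, ]
  d <- a[1] * (b[2] * c[3] - b[3] * c[2]) -
       a[2] * (b[1] * c[3] - b[3] * c[1]) +
       a[3] * (b[1] * c[2] - b[2] * c[1])
  abs(d) / 6
}

# exhaustive point location: barycentric test via solve() on every element
oracle_locate <- function(mesh, p, tol = 1e-8) {
  for (e in seq_len(mesh$n_elements)) {
    idx <- mesh$elements[e, ]
    M <- cbind(mesh$nodes[idx[2], ] - mesh$nodes[idx[1], ],
               mesh$nodes[idx[3], ] - mesh$nodes[idx[1], ],
               mesh$nodes[idx[4], ] - mesh$nodes[idx[1], ])
    l <- tryCatch(solve(M, p - mesh$nodes[idx[1], ]),
                  error = function(err) rep(NA_real_, 3))
    if (anyNA(l)) next
    if (all(c(1 - sum(l), l) >= -tol)) return(e)
  }
  NA_integer_
}

# all (edge, incident elements) pairs by scanning every element's 6 edges
oracle_edges <- function(mesh) {
  out <- new.env(parent = emptyenv())
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (e in seq_len(mesh$n_elements)) {
    row <- mesh$elements[e, ]
    for (r in seq_len(6)) {
      k <- paste(sort(row[pairs[r, ]]), collapse = "_")
      out[[k]] <- c(out[[k]], e)
    }
  }
  out
}

# synthetic green_function with prescribed values (bypasses transport)
fake_green <- function(values, gating, kind = "source") {
  opt <- optode(c(0, 0, 0), c(0, 0, 1), kind)
  mmcadapt:::new_green_function(values, opt, n_photons = 1, seed = 0,
                                gating = gating,
                                conservation = list(),
                                adjoint = identical(kind, "detector"))
}

# brute-force reference: triple-loop double convolution per node
oracle_jacobian <- function(X, M, tau, dt) {
  n <- nrow(X); K <- ncol(X)
  W <- matrix(0, K, n)
  for (r in seq_len(n)) {
    inner <- numeric(K)
    for (kp in 0:(K - 1))
      for (kpp in 0:kp)
        inner[kp + 1] <- inner[kp + 1] +
          X[r, kp - kpp + 1] * M[r, kpp + 1] * dt
    for (k in 0:(K - 1))
      for (kp in 0:k)
        W[k + 1, r] <- W[k + 1, r] +
          exp(-(k - kp) * dt / tau) * inner[kp + 1] * dt
  }
  W
}

uniform_size_field <- function(mesh, factor) {
  structure(list(factors = rep(factor, mesh$n_nodes),
                 params = NULL, kind = "uniform"),
            class = "size_field")
}

slice_fixture <- function() {
  mesh <- make_slice_phantom(12, 8, 4, 1)
  list(mesh = mesh,
       optodes = place_transmission_optodes(mesh, 7, 7),
       props = default_properties(),
       gating = time_gating(50, 40))
}
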