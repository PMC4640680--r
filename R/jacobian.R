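# content fingerprint used to tie Jacobians to the mesh they live on
mesh_hash <- function(mesh) {
  sprintf("%d-%d-%.10e-%.10e", mesh$n_nodes, mesh$n_elements,
          sum(mesh$nodes), sum(as.double(mesh$elements)^1.5))
}

#' Assemble one source-detector Jacobian slice
#'
#' Combines a forward (source) and an adjoint (detector) Green's function
#' into the time-resolved sensitivity of the fluorescence measurement to
#' the effective quantum yield at every node, by the forward-adjoint Born
#' form: the two Green's functions are convolved in time at each node and
#' the result is convolved with the fluorophore's exponential lifetime
#' decay `exp(-t/tau)`.  Discretization is a left-endpoint Riemann sum with
#' `dt` equal to the gate width:
#' `inner[k'] = sum_{k'' <= k'} Gx[k'-k''] Gm[k''] dt` per node, then
#' `W[k] = sum_{k' <= k} exp(-(k-k') dt / tau) inner[k'] dt`.
#'
#' @param gx forward `green_function` (from a source).
#' @param gm adjoint `green_function` (from a detector).
#' @param tau fluorophore lifetime, ps (> 0).
#' @param gating optional [time_gating()]; defaults to the Green functions'
#'   own (which must agree).
#' @return numeric matrix `n_gates x n_nodes`, nonnegative.
#' @export
assemble_jacobian <- function(gx, gm, tau, gating = NULL) {
  if (tau <= 0) stop("tau must be > 0")
  if (!same_gating(gx$gating, gm$gating))
    stop("forward and adjoint Green functions have different gatings")
  if (nrow(gx$values) != nrow(gm$values))
    stop("forward and adjoint Green functions live on different meshes (",
         nrow(gx$values), " vs ", nrow(gm$values), " nodes)")
  if (!is.null(gating) && !same_gating(gating, gx$gating))
    stop("requested gating differs from the Green functions' gating")
  gating <- gx$gating
  dt <- gating$gate_width
  K <- gating$n_gates
  X <- gx$values                     # nodes x gates
  M <- gm$values
  inner <- matrix(0, nrow(X), K)
  for (k in seq_len(K)) {            # gate k is time index k-1
    # sum_{i=1..k} X[, k-i+1] * M[, i] * dt
    idx <- seq_len(k)
    inner[, k] <- (X[, rev(idx), drop = FALSE] *
                   M[, idx, drop = FALSE]) %*% rep(dt, k)
  }
  decay <- exp(-(0:(K - 1)) * dt / tau)
  W <- matrix(0, K, ncol = nrow(X))
  for (k in seq_len(K)) {
    idx <- seq_len(k)
    W[k, ] <- (inner[, idx, drop = FALSE] %*% (decay[rev(idx)] * dt))
  }
  W
}

#' Bundle per-pair Jacobian slices
#'
#' @param slices list of `n_gates x n_nodes` matrices from
#'   [assemble_jacobian()], one per source-detector pair.
#' @param pairs list of `list(source =, detector =)` [optode()] pairs.
#' @param gating the shared [time_gating()].
#' @param mesh the [tet_mesh()] the slices are defined on.
#' @return an object of class `jacobian` with `W` (array
#'   `pairs x gates x nodes`), `pairs`, `gating`, `mesh_hash`.
#' @export
jacobian <- function(slices, pairs, gating, mesh) {
  stopifnot(length(slices) == length(pairs), length(slices) >= 1)
  K <- gating$n_gates
  n <- ncol(slices[[1]])
  W <- array(0, dim = c(length(slices), K, n))
  for (p in seq_along(slices)) {
    stopifnot(nrow(slices[[p]]) == K, ncol(slices[[p]]) == n)
    W[p, , ] <- slices[[p]]
  }
  structure(list(W = W, pairs = pairs, gating = gating,
                 mesh_hash = mesh_hash(mesh)),
            class = "jacobian")
}

#' @export
print.jacobian <- function(x, ...) {
  d <- dim(x$W)
  cat(sprintf("jacobian: %d pair(s) x %d gates x %d nodes\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Forward time-resolved measurement (TPSF) from a Jacobian slice
#'
#' Discretizes the volume integral of sensitivity times yield with nodal
#' volume shares: `U[k] = sum_r W[k, r] eta(r) V(r)`.
#'
#' @param w_slice `n_gates x n_nodes` matrix.
#' @param eta per-node effective quantum yield (scalar recycled), >= 0.
#' @param mesh the [tet_mesh()] the slice is defined on.
#' @return numeric vector of per-gate measurements.
#' @export
forward_tpsf <- function(w_slice, eta, mesh) {
  if (any(eta < 0)) stop("eta must be >= 0")
  eta <- rep_len(as.numeric(eta), mesh$n_nodes)
  if (ncol(w_slice) != mesh$n_nodes)
    stop("Jacobian slice has ", ncol(w_slice), " nodes; mesh has ",
         mesh$n_nodes)
  as.numeric(w_slice %*% (eta * node_volumes(mesh)))
}

#' Rising-gate index of a TPSF
#'
#' Smallest gate index at which the TPSF reaches the given fraction of its
#' maximum (the "25% rising gate" convention by default).
#'
#' @param tpsf per-gate values with a strictly positive maximum.
#' @param fraction threshold fraction of the maximum, default 0.25.
#' @return gate index (1-based).
#' @export
rising_gate <- function(tpsf, fraction = 0.25) {
  m <- max(tpsf)
  if (!is.finite(m) || m <= 0)
    stop("TPSF must have a strictly positive maximum")
  which(tpsf >= fraction * m)[1]
}

#' Persist a Jacobian as a JSON container
#'
#' Stores `/W` (pairs x gates x nodes), pair optodes, gating and the mesh
#' fingerprint.
#'
#' @param jac a [jacobian()].
#' @param path output file path.
#' @return `path` invisibly.
#' @export
write_jacobian <- function(jac, path) {
  obj <- list(
    dim = dim(jac$W),
    W = as.numeric(jac$W),
    pairs = lapply(jac$pairs, function(p) list(
      source = list(position = p$source$position,
                    direction = p$source$direction),
      detector = list(position = p$detector$position,
                      direction = p$detector$direction))),
    gating = unclass(jac$gating),
    mesh_hash = jac$mesh_hash)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a Jacobian written by [write_jacobian()]
#'
#' @param path file path.
#' @return a `jacobian` object.
#' @export
read_jacobian <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  gt <- obj$gating
  pairs <- lapply(obj$pairs, function(p)
    list(source = optode(unlist(p$source$position),
                         unlist(p$source$direction), "source"),
         detector = optode(unlist(p$detector$position),
                           unlist(p$detector$direction), "detector")))
  structure(list(W = array(unlist(obj$W), dim = unlist(obj$dim)),
                 pairs = pairs,
                 gating = time_gating(gt$gate_width, gt$n_gates, gt$t0),
                 mesh_hash = obj$mesh_hash),
            class = "jacobian")
}
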