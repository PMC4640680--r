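#' Per-node solution field
#'
#' A scalar field over mesh nodes that drives size-field generation.  The
#' `orientation` records which end of the value range should be coarsened:
#' `"coarsen_low"` (low values get large size factors -- all
#' sensitivity-derived fields and the attenuation field) or
#' `"coarsen_high"` (the distance field, where nodes far from every optode
#' should be coarsened most).
#'
#' @param values numeric per-node vector, finite.
#' @param kind one of `"sum_jacobian"`, `"log_sum_jacobian"`,
#'   `"normalized_sum"`, `"curvature"`, `"log_curvature"`, `"distance"`,
#'   `"attenuation"`.
#' @return an object of class `solution_field`.
#' @export
solution_field <- function(values,
                           kind = c("sum_jacobian", "log_sum_jacobian",
                                    "normalized_sum", "curvature",
                                    "log_curvature", "distance",
                                    "attenuation")) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("solution field values must be finite")
  orientation <- if (kind == "distance") "coarsen_high" else "coarsen_low"
  structure(list(values = values, kind = kind, orientation = orientation),
            class = "solution_field")
}

#' @export
print.solution_field <- function(x, ...) {
  cat(sprintf("solution_field '%s' (%s): %d nodes, range [%.4g, %.4g]\n",
              x$kind, x$orientation, length(x$values), min(x$values),
              max(x$values)))
  invisible(x)
}

# per-node sums over all pairs and gates of a jacobian array
jacobian_node_sums <- function(jac) {
  stopifnot(inherits(jac, "jacobian"))
  apply(jac$W, 3, sum)
}

#' Sensitivity-sum solution field
#'
#' The per-node sum of the Jacobian over all source-detector pairs and time
#' gates: the total sensitivity of the data set at each node.
#'
#' @param jac a [jacobian()].
#' @return a [solution_field()] of kind `sum_jacobian`.
#' @export
sum_jacobian <- function(jac) {
  solution_field(jacobian_node_sums(jac), "sum_jacobian")
}

#' Log sensitivity-sum solution field
#'
#' Natural log of the per-node Jacobian sums; compresses the large dynamic
#' range of diffuse light.  Zero sums are guarded by adding
#' `eps = smallest positive sum * 1e-6`.  Note the log can produce
#' negative values and hence a negative median, which
#' [to_size_field()] rejects by default.
#'
#' @param jac a [jacobian()].
#' @return a [solution_field()] of kind `log_sum_jacobian`.
#' @export
log_sum_jacobian <- function(jac) {
  s <- jacobian_node_sums(jac)
  pos <- s[s > 0]
  eps <- if (length(pos)) min(pos) * 1e-6 else 1
  solution_field(log(s + eps), "log_sum_jacobian")
}

#' Normalized sensitivity-sum solution field
#'
#' Each (pair, gate) row of the Jacobian is scaled to unit maximum before
#' the per-node sum, mitigating the dynamic range caused by unequal
#' source-detector path lengths.  All-zero rows are skipped.
#'
#' @param jac a [jacobian()].
#' @return a [solution_field()] of kind `normalized_sum`.
#' @export
normalized_sum <- function(jac) {
  d <- dim(jac$W)
  out <- numeric(d[3])
  for (p in seq_len(d[1])) {
    for (k in seq_len(d[2])) {
      row <- jac$W[p, k, ]
      m <- max(row)
      if (m > 0) out <- out + row / m
    }
  }
  solution_field(out, "normalized_sum")
}

#' Curvature solution field
#'
#' Applies the dense Laplacian-type operator `L` with 1 on the diagonal and
#' `-1/(n-1)` off-diagonal to a solution field `S`:
#' `u_i = S_i - mean of the other values`.  `L` annihilates constants, so
#' `u` highlights nodes deviating from the field average.
#'
#' @param field a [solution_field()] (typically the sensitivity sum).
#' @return a [solution_field()] of kind `curvature`.
#' @export
curvature <- function(field) {
  s <- field$values
  n <- length(s)
  if (n < 2) stop("curvature needs at least 2 nodes")
  u <- s - (sum(s) - s) / (n - 1)
  solution_field(u, "curvature")
}

#' Log-curvature solution field
#'
#' Log of the positive part of the curvature metric,
#' `log(max(u, 0) + eps)` with `eps` the smallest positive `|u|` times
#' 1e-6.  Like the log sensitivity sum, this can yield negative medians;
#' see [to_size_field()].
#'
#' @param field a [solution_field()].
#' @return a [solution_field()] of kind `log_curvature`.
#' @export
log_curvature <- function(field) {
  u <- curvature(field)$values
  pos <- abs(u)[abs(u) > 0]
  eps <- if (length(pos)) min(pos) * 1e-6 else 1
  solution_field(log(pmax(u, 0) + eps), "log_curvature")
}

min_optode_distance <- function(mesh, optodes) {
  if (length(optodes) < 1) stop("need at least one optode")
  d2 <- rep(Inf, mesh$n_nodes)
  for (o in optodes) {
    p <- o$position
    d2 <- pmin(d2, (mesh$nodes[, 1] - p[1])^2 + (mesh$nodes[, 2] - p[2])^2 +
                   (mesh$nodes[, 3] - p[3])^2)
  }
  sqrt(d2)
}

#' Distance solution field
#'
#' Per node, the minimum Euclidean distance to any source or detector.
#' Far nodes are visited by fewest photons, so the orientation is
#' `coarsen_high`.
#'
#' @param mesh a [tet_mesh()].
#' @param optodes list of [optode()] objects.
#' @return a [solution_field()] of kind `distance`.
#' @export
distance_field <- function(mesh, optodes) {
  solution_field(min_optode_distance(mesh, optodes), "distance")
}

#' Attenuation solution field
#'
#' Beer-Lambert weighting of the minimum optode distance:
#' `Att = exp(-mu * dist)` with `mu` the total attenuation coefficient.
#' Low values (far, strongly attenuated nodes) are coarsened most.
#'
#' @param mesh a [tet_mesh()].
#' @param optodes list of [optode()] objects.
#' @param mu total attenuation coefficient, mm^-1 (>= 0).  When omitted and
#'   `props` is given, defaults to `mu_a + mu_s'` (the transport
#'   attenuation scale).
#' @param props optional [optical_properties()] used for the default `mu`.
#' @return a [solution_field()] of kind `attenuation`.
#' @export
attenuation_field <- function(mesh, optodes, mu = NULL, props = NULL) {
  if (is.null(mu)) {
    if (is.null(props)) stop("give either mu or props")
    mu <- props$mu_a + props$mu_s_prime
  }
  if (mu < 0) stop("mu must be >= 0")
  solution_field(exp(-mu * min_optode_distance(mesh, optodes)),
                 "attenuation")
}

#' Size-field thresholds and bounds
#'
#' @param max_size_factor largest allowed per-node size factor (> 1
#'   coarsens).
#' @param min_size_factor smallest allowed factor (< 1 refines); default 1
#'   (no refinement).
#' @param lower_frac lower threshold as a fraction of the field median
#'   (default 0.2).
#' @param upper_mult upper threshold as a multiple of the lower threshold
#'   (default 8).
#' @return an object of class `size_field_params`.
#' @export
size_field_params <- function(max_size_factor, min_size_factor = 1,
                              lower_frac = 0.2, upper_mult = 8) {
  if (!(min_size_factor > 0)) stop("min_size_factor must be > 0")
  if (max_size_factor < min_size_factor)
    stop("max_size_factor must be >= min_size_factor")
  if (lower_frac <= 0) stop("lower_frac must be > 0")
  if (upper_mult <= 1) stop("upper_mult must be > 1")
  structure(list(max_size_factor = max_size_factor,
                 min_size_factor = min_size_factor,
                 lower_frac = lower_frac, upper_mult = upper_mult),
            class = "size_field_params")
}

#' Convert a solution field into a size field
#'
#' Thresholds are `T_lo = lower_frac * median(values)` and
#' `T_hi = upper_mult * T_lo`.  Values below `T_lo` map to the maximum
#' size factor, values above `T_hi` to the minimum, and values between
#' follow the exponential `y(x) = max_sf * (min_sf/max_sf)^((x - T_lo) /
#' (T_hi - T_lo))`, which is continuous at both thresholds.  For
#' `coarsen_high` fields the value axis is mirrored
#' (`x <- T_lo + T_hi - x`) before the map is applied.
#'
#' A nonpositive median (possible for log-family fields) makes the two
#' thresholds cross and the map ill-defined; by default this raises an
#' error.  With `fallback = "shift"` the field is first shifted to
#' positive values (`x - min(x)` plus a small offset).
#'
#' @param field a [solution_field()].
#' @param params a [size_field_params()].
#' @param fallback `"error"` (default) or `"shift"`.
#' @return an object of class `size_field` with per-node `factors` in
#'   `[min_size_factor, max_size_factor]`.
#' @export
to_size_field <- function(field, params, fallback = c("error", "shift")) {
  fallback <- match.arg(fallback)
  x <- field$values
  med <- median(x)
  if (med <= 0) {
    if (fallback == "error")
      stop("solution field has nonpositive median (", signif(med, 4),
           "); the threshold map is ill-defined.  Use fallback = \"shift\" ",
           "to shift the field to positive values.")
    rng <- max(x) - min(x)
    x <- x - min(x) + if (rng > 0) 1e-3 * rng else 1
    med <- median(x)
  }
  t_lo <- params$lower_frac * med
  t_hi <- params$upper_mult * t_lo
  if (field$orientation == "coarsen_high") x <- t_lo + t_hi - x
  lo <- params$min_size_factor
  hi <- params$max_size_factor
  y <- hi * (lo / hi)^((x - t_lo) / (t_hi - t_lo))
  y[x < t_lo] <- hi
  y[x > t_hi] <- lo
  y <- pmin(pmax(y, lo), hi)
  structure(list(factors = y, params = params,
                 thresholds = c(lower = t_lo, upper = t_hi),
                 kind = field$kind),
            class = "size_field")
}

#' @export
print.size_field <- function(x, ...) {
  cat(sprintf("size_field from '%s': %d nodes, factors in [%.4g, %.4g]\n",
              x$kind, length(x$factors), min(x$factors), max(x$factors)))
  invisible(x)
}

#' Compute a named solution-field recipe
#'
#' Dispatcher used by the adaptation loop and the command-line tool.
#' Jacobian-based recipes (`sum_jacobian`, `log_sum`, `normalized_sum`,
#' `curvature`, `log_curvature`) need `jac`; geometry recipes (`distance`,
#' `attenuation`) need `optodes` (and `mu` or `props` for attenuation).
#'
#' @param recipe recipe name.
#' @param mesh a [tet_mesh()].
#' @param jac optional [jacobian()] on `mesh`.
#' @param optodes optional list of [optode()]s.
#' @param mu,props see [attenuation_field()].
#' @return a [solution_field()].
#' @export
compute_solution_field <- function(recipe, mesh, jac = NULL, optodes = NULL,
                                   mu = NULL, props = NULL) {
  recipe <- match.arg(recipe,
                      c("sum_jacobian", "log_sum", "log_sum_jacobian",
                        "normalized_sum", "curvature", "log_curvature",
                        "distance", "attenuation"))
  needs_jac <- recipe %in% c("sum_jacobian", "log_sum", "log_sum_jacobian",
                             "normalized_sum", "curvature", "log_curvature")
  if (needs_jac) {
    if (is.null(jac))
      stop("recipe '", recipe, "' requires a Jacobian")
    if (dim(jac$W)[3] != mesh$n_nodes)
      stop("Jacobian has ", dim(jac$W)[3], " nodes; mesh has ",
           mesh$n_nodes)
    switch(recipe,
           sum_jacobian = sum_jacobian(jac),
           log_sum = ,
           log_sum_jacobian = log_sum_jacobian(jac),
           normalized_sum = normalized_sum(jac),
           curvature = curvature(sum_jacobian(jac)),
           log_curvature = log_curvature(sum_jacobian(jac)))
  } else {
    if (is.null(optodes))
      stop("recipe '", recipe, "' requires optodes")
    switch(recipe,
           distance = distance_field(mesh, optodes),
           attenuation = attenuation_field(mesh, optodes, mu = mu,
                                           props = props))
  }
}
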