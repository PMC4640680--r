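#' Sample the Henyey-Greenstein scattering cosine
#'
#' Inverse-CDF sampling of the polar scattering cosine for anisotropy `g`,
#' evaluated at given uniform variates.  For `g = 0` the isotropic branch
#' `2 xi - 1` is used.  The transport kernel uses the identical formula.
#'
#' @param g anisotropy factor in `[0, 1)`.
#' @param xi uniform variates in `[0, 1)`.
#' @return scattering cosines in `[-1, 1]`.
#' @export
sample_hg_cosine <- function(g, xi) {
  if (length(g) != 1 || is.na(g) || g < 0 || g >= 1)
    stop("g must be a single value in [0, 1)")
  hg_cosine_cpp(g, as.numeric(xi))
}

new_green_function <- function(values, optode, n_photons, seed, gating,
                               conservation, adjoint = FALSE) {
  structure(list(values = values, optode = optode,
                 n_photons = n_photons, seed = seed, gating = gating,
                 conservation = conservation, adjoint = adjoint),
            class = "green_function")
}

#' @export
print.green_function <- function(x, ...) {
  cat(sprintf(
    "green_function (%s%s): %d nodes x %d gates, %g photons, seed %d\n",
    x$optode$kind, if (x$adjoint) ", adjoint" else "",
    nrow(x$values), ncol(x$values), x$n_photons, x$seed))
  invisible(x)
}

#' Time-gated Green's function by mesh-based Monte Carlo
#'
#' Launches `n_photons` weighted photon packets from an optode on the mesh
#' boundary and tallies the time-gated fluence density at every node.
#' Step lengths are sampled as `-log(xi)/mu_t` with `mu_t = mu_a + mu_s`
#' and `mu_s = mu_s'/(1 - g)`; packets traverse element faces by
#' ray-tracing, deposit an absorbed fraction `mu_a/mu_t` of their weight at
#' each interaction (spread over the containing element's nodes by
#' barycentric shares), scatter by the Henyey-Greenstein phase function,
#' undergo Russian roulette below the weight floor, and are
#' Fresnel-reflected at the external boundary (`n_refr` against air).
#' Elapsed time advances by `path * n_refr / c`; packets exceeding the
#' gated window are terminated.
#'
#' Deposited weight is converted to fluence by dividing by `mu_a`, the
#' nodal volume share, and the number of launched photons, so values are
#' per launched photon, per mm^3, per gate.  The run is deterministic for a
#' fixed seed.
#'
#' @param mesh a [tet_mesh()].
#' @param props an [optical_properties()].
#' @param opt an [optode()] on the mesh boundary.
#' @param n_photons number of photon packets (>= 1).
#' @param gating a [time_gating()].
#' @param seed RNG seed (nonnegative integer).
#' @param rr_threshold,rr_survive Russian roulette weight floor and
#'   survival probability.
#' @return a `green_function`: `values` (nodes x gates matrix), optode and
#'   run metadata, and a `conservation` list of weight buckets
#'   (`deposited`, `exited`, `killed`, `expired`, `lost`, `boosted`,
#'   `launched`) satisfying
#'   `deposited + exited + killed + expired + lost - boosted = launched`
#'   exactly up to round-off.
#' @export
propagate <- function(mesh, props, opt, n_photons, gating = time_gating(),
                      seed = 1L, rr_threshold = 1e-4, rr_survive = 0.1) {
  stopifnot(inherits(mesh, "tet_mesh"), inherits(props, "optical_properties"),
            inherits(opt, "optode"), inherits(gating, "time_gating"))
  n_photons <- as.numeric(n_photons)
  if (is.na(n_photons) || n_photons < 1)
    stop("n_photons must be >= 1")
  seed <- as.integer(seed)
  musc <- mu_s(props)

  # containing element at launch: nudge the boundary position inward
  eps <- 1e-6 * bbox_diagonal(mesh)
  start <- locate_point(mesh, opt$position + eps * opt$direction)
  if (is.na(start))
    stop("optode position is not on the mesh boundary (no containing ",
         "element along its direction)")

  res <- mmc_transport_cpp(mesh$nodes, mesh$elements,
                           element_neighbors_cached(mesh),
                           opt$position, opt$direction, start,
                           props$mu_a, musc, props$g, props$n_refr,
                           n_photons, gating$gate_width, gating$n_gates,
                           gating$t0, seed, rr_threshold, rr_survive)
  vn <- node_volumes(mesh)
  if (props$mu_a > 0) {
    values <- res$deposit / (props$mu_a * vn * n_photons)
  } else {
    values <- res$deposit * 0
  }
  conservation <- res[c("deposited", "exited", "killed", "expired", "lost",
                        "boosted", "launched")]
  new_green_function(values, opt, n_photons, seed, gating, conservation,
                     adjoint = identical(opt$kind, "detector"))
}

#' Adjoint Green's function from a detector
#'
#' Identical transport to [propagate()], launched from the detector
#' position and direction; the result is tagged as adjoint.
#'
#' @inheritParams propagate
#' @param detector an [optode()] with `kind = "detector"`.
#' @return a `green_function` with `adjoint = TRUE`.
#' @export
adjoint_green <- function(mesh, props, detector, n_photons,
                          gating = time_gating(), seed = 1L,
                          rr_threshold = 1e-4, rr_survive = 0.1) {
  if (!identical(detector$kind, "detector"))
    stop("adjoint_green expects an optode of kind 'detector'")
  g <- propagate(mesh, props, detector, n_photons, gating, seed,
                 rr_threshold, rr_survive)
  g$adjoint <- TRUE
  g
}

#' Weight-conservation residual of a transport run
#'
#' @param green a `green_function`.
#' @return `deposited + exited + killed + expired + lost - boosted -
#'   launched`, which is zero up to floating-point round-off.
#' @export
conservation_residual <- function(green) {
  with(green$conservation,
       deposited + exited + killed + expired + lost - boosted - launched)
}

#' Persist a Green's function as a JSON container
#'
#' Stores `/values` (nodes x gates) together with the optode, photon count,
#' seed, gating and conservation metadata.
#'
#' @param green a `green_function`.
#' @param path output file path.
#' @return `path` invisibly.
#' @export
write_green <- function(green, path) {
  obj <- list(
    values = green$values,
    meta = list(
      optode = list(position = green$optode$position,
                    direction = green$optode$direction,
                    kind = green$optode$kind),
      n_photons = green$n_photons, seed = green$seed,
      gating = unclass(green$gating),
      conservation = green$conservation,
      adjoint = green$adjoint))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a Green's function written by [write_green()]
#'
#' @param path file path.
#' @return a `green_function`.
#' @export
read_green <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  gt <- obj$meta$gating
  new_green_function(
    values = as.matrix(obj$values),
    optode = optode(obj$meta$optode$position, obj$meta$optode$direction,
                    obj$meta$optode$kind),
    n_photons = obj$meta$n_photons, seed = obj$meta$seed,
    gating = time_gating(gt$gate_width, gt$n_gates, gt$t0),
    conservation = as.list(obj$meta$conservation),
    adjoint = isTRUE(obj$meta$adjoint))
}
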