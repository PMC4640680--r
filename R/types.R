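# speed of light in vacuum, mm/ps
C_MM_PS <- 0.299792458

#' Optical properties of a homogeneous medium
#'
#' Internal units are mm^-1 throughout the package; literature values in
#' cm^-1 can be passed with `unit = "cm"` and are converted on construction.
#'
#' @param mu_a absorption coefficient (>= 0).
#' @param mu_s_prime reduced scattering coefficient `mu_s (1 - g)` (> 0).
#' @param g scattering anisotropy (mean cosine), in `[0, 1)`.
#' @param n_refr refractive index (>= 1).
#' @param unit `"mm"` (default) or `"cm"` for the two coefficients.
#' @return an object of class `optical_properties` with fields in mm^-1.
#' @export
optical_properties <- function(mu_a, mu_s_prime, g = 0, n_refr = 1,
                               unit = c("mm", "cm")) {
  unit <- match.arg(unit)
  if (unit == "cm") {
    mu_a <- mu_a / 10
    mu_s_prime <- mu_s_prime / 10
  }
  if (mu_a < 0) stop("mu_a must be >= 0")
  if (mu_s_prime <= 0) stop("mu_s_prime must be > 0")
  if (g < 0 || g >= 1) stop("g must be in [0, 1)")
  if (n_refr < 1) stop("n_refr must be >= 1")
  structure(list(mu_a = mu_a, mu_s_prime = mu_s_prime, g = g,
                 n_refr = n_refr),
            class = "optical_properties")
}

#' Scattering coefficient implied by the reduced coefficient
#'
#' `mu_s = mu_s' / (1 - g)`.
#'
#' @param props an [optical_properties()] object.
#' @return scalar mm^-1.
#' @export
mu_s <- function(props) props$mu_s_prime / (1 - props$g)

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf(
    "optical_properties: mu_a=%.4g mm^-1, mu_s'=%.4g mm^-1 (mu_s=%.4g), g=%.3g, n=%.3g\n",
    x$mu_a, x$mu_s_prime, mu_s(x), x$g, x$n_refr))
  invisible(x)
}

#' A point source or detector on the mesh boundary
#'
#' @param position length-3 numeric, mm.
#' @param direction length-3 numeric; normalized to unit length, must point
#'   into the domain.
#' @param kind `"source"` or `"detector"`.
#' @return an object of class `optode`.
#' @export
optode <- function(position, direction, kind = c("source", "detector")) {
  kind <- match.arg(kind)
  position <- as.numeric(position)
  direction <- as.numeric(direction)
  if (length(position) != 3 || length(direction) != 3)
    stop("position and direction must have length 3")
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("direction must be nonzero")
  structure(list(position = position, direction = direction / nrm,
                 kind = kind),
            class = "optode")
}

#' Time gating scheme for time-resolved quantities
#'
#' Gate `k` (1-based) covers `[t0 + (k-1) w, t0 + k w)` picoseconds.
#'
#' @param gate_width gate width `w` in ps (> 0).
#' @param n_gates number of gates (>= 1).
#' @param t0 start of the first gate, ps.
#' @return an object of class `time_gating`.
#' @export
time_gating <- function(gate_width = 50, n_gates = 40, t0 = 0) {
  if (gate_width <= 0) stop("gate_width must be > 0")
  n_gates <- as.integer(n_gates)
  if (is.na(n_gates) || n_gates < 1) stop("n_gates must be >= 1")
  structure(list(gate_width = gate_width, n_gates = n_gates, t0 = t0),
            class = "time_gating")
}

#' Gate center times
#'
#' @param gating a [time_gating()].
#' @return numeric vector of gate midpoints in ps.
#' @export
gate_times <- function(gating) {
  gating$t0 + (seq_len(gating$n_gates) - 0.5) * gating$gate_width
}

same_gating <- function(a, b) {
  isTRUE(all.equal(a$gate_width, b$gate_width)) &&
    a$n_gates == b$n_gates && isTRUE(all.equal(a$t0, b$t0))
}
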