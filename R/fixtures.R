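#' Default tissue optical properties
#'
#' Homogeneous absorption and scattering typical of mouse tissue in the
#' near-infrared: `mu_a = 0.3 cm^-1`, `mu_s' = 15 cm^-1`, `g = 0.9`,
#' `n = 1.37`, converted to the package's mm^-1 convention
#' (`mu_a = 0.03`, `mu_s' = 1.5`).
#'
#' @return an [optical_properties()] object.
#' @export
default_properties <- function() {
  optical_properties(mu_a = 0.3, mu_s_prime = 15, g = 0.9, n_refr = 1.37,
                     unit = "cm")
}

#' Structured tetrahedral slab mesh
#'
#' A box `[0, lx] x [0, ly] x [0, lz]` divided into a regular grid of
#' hexahedral cells, each split into 6 tetrahedra (Freudenthal/Kuhn
#' subdivision, conforming across cells).  Deterministic: the same
#' parameters always produce the identical mesh.
#'
#' @param lx,ly,lz box dimensions (mm).
#' @param h target edge length (mm); the grid uses `ceiling(l/h)` cells per
#'   axis, so the box dimensions are honored exactly.
#' @return a [tet_mesh()] with total volume exactly `lx*ly*lz`.
#' @export
make_slab_mesh <- function(lx, ly, lz, h) {
  if (any(c(lx, ly, lz, h) <= 0)) stop("dimensions and h must be > 0")
  if (h > min(lx, ly, lz))
    stop("h (", h, ") exceeds the smallest box dimension (",
         min(lx, ly, lz), ")")
  nx <- ceiling(lx / h); ny <- ceiling(ly / h); nz <- ceiling(lz / h)
  xs <- seq(0, lx, length.out = nx + 1)
  ys <- seq(0, ly, length.out = ny + 1)
  zs <- seq(0, lz, length.out = nz + 1)
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs,
                                 KEEP.OUT.ATTRS = FALSE))
  idx <- function(i, j, k) 1L + i + (nx + 1L) * (j + (ny + 1L) * k)

  # Kuhn subdivision: one tet per permutation of the axes, walking from the
  # low corner to the high corner of each cell.
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  cells <- expand.grid(i = 0:(nx - 1), j = 0:(ny - 1), k = 0:(nz - 1),
                       KEEP.OUT.ATTRS = FALSE)
  nc <- nrow(cells)
  elements <- matrix(0L, nc * 6L, 4L)
  row <- 1L
  for (p in seq_len(6)) {
    e <- diag(3)[perms[p, ], , drop = FALSE]
    o <- as.matrix(cells)
    v1 <- idx(o[, 1], o[, 2], o[, 3])
    s1 <- o + matrix(e[1, ], nc, 3, byrow = TRUE)
    v2 <- idx(s1[, 1], s1[, 2], s1[, 3])
    s2 <- s1 + matrix(e[2, ], nc, 3, byrow = TRUE)
    v3 <- idx(s2[, 1], s2[, 2], s2[, 3])
    v4 <- idx(o[, 1] + 1, o[, 2] + 1, o[, 3] + 1)
    elements[row:(row + nc - 1L), ] <- cbind(v1, v2, v3, v4)
    row <- row + nc
  }
  elements <- reorient_elements(nodes, elements)
  mesh <- tet_mesh(nodes, elements)
  attr(mesh, "phantom") <- list(shape = "slab", lx = lx, ly = ly, lz = lz,
                                h = h)
  mesh
}

# Triangulated unit disk: center node, rings j = 1..m of 6j nodes at radius
# j/m.  Annuli triangulated by an angular two-pointer merge.  Returns 2D
# nodes and CCW triangles.
unit_disk_triangulation <- function(m) {
  nodes <- matrix(c(0, 0), 1, 2)
  ring_start <- integer(m + 1)   # index of first node of ring j (1-based)
  ring_start[1] <- 1             # ring 0 = center
  for (j in seq_len(m)) {
    nj <- 6L * j
    th <- 2 * pi * (0:(nj - 1)) / nj
    ring_start[j + 1] <- nrow(nodes) + 1L
    nodes <- rbind(nodes, (j / m) * cbind(cos(th), sin(th)))
  }
  tris <- matrix(0L, 0L, 3L)
  for (j in seq_len(m)) {
    no <- 6L * j
    outer0 <- ring_start[j + 1] - 1L   # outer ring node = outer0 + k (k 1..no)
    if (j == 1L) {
      k <- 1:no
      tris <- rbind(tris, cbind(1L, outer0 + k, outer0 + (k %% no) + 1L))
      next
    }
    ni <- 6L * (j - 1L)
    inner0 <- ring_start[j] - 1L
    ii <- 0L; oo <- 0L
    new_tris <- matrix(0L, ni + no, 3L)
    t <- 1L
    while (ii < ni || oo < no) {
      adv_outer <- if (oo >= no) FALSE
      else if (ii >= ni) TRUE
      else (oo + 1) / no <= (ii + 1) / ni
      ic <- inner0 + (ii %% ni) + 1L
      oc <- outer0 + (oo %% no) + 1L
      if (adv_outer) {
        onx <- outer0 + ((oo + 1L) %% no) + 1L
        new_tris[t, ] <- c(ic, oc, onx)
        oo <- oo + 1L
      } else {
        inx <- inner0 + ((ii + 1L) %% ni) + 1L
        new_tris[t, ] <- c(ic, oc, inx)
        ii <- ii + 1L
      }
      t <- t + 1L
    }
    tris <- rbind(tris, new_tris)
  }
  # enforce CCW orientation (positive signed area)
  a <- nodes[tris[, 1], , drop = FALSE]
  b <- nodes[tris[, 2], , drop = FALSE]
  c2 <- nodes[tris[, 3], , drop = FALSE]
  area2 <- (b[, 1] - a[, 1]) * (c2[, 2] - a[, 2]) -
           (b[, 2] - a[, 2]) * (c2[, 1] - a[, 1])
  flip <- area2 < 0
  tmp <- tris[flip, 2]
  tris[flip, 2] <- tris[flip, 3]
  tris[flip, 3] <- tmp
  list(nodes = nodes, tris = tris)
}

# Subdivide a triangular prism into 3 tetrahedra using the smallest-global-
# index diagonal rule, so that adjacent prisms split shared quadrilateral
# faces identically (Dompierre-style indirect addressing).
split_prism <- function(v) {
  rot <- c(2L, 3L, 1L, 5L, 6L, 4L)
  flip <- c(4L, 6L, 5L, 1L, 3L, 2L)
  w <- v
  if (which.min(w) > 3L) w <- w[flip]
  while (which.min(w[1:3]) != 1L) w <- w[rot]
  if (min(w[2], w[6]) < min(w[3], w[5])) {
    rbind(w[c(1, 2, 3, 6)], w[c(1, 2, 6, 5)], w[c(1, 5, 6, 4)])
  } else {
    rbind(w[c(1, 2, 3, 5)], w[c(1, 5, 3, 6)], w[c(1, 5, 6, 4)])
  }
}

#' Elliptical slice phantom mesh
#'
#' An extruded elliptical cross-section (semi-axes `a`, `b` in x and y,
#' centered at the origin; z from 0 to `thickness`), emulating a thin
#' cross-sectional slice of a small-animal torso.  The cross-section is a
#' ring-structured triangulation scaled to the ellipse; each prism layer is
#' split into tetrahedra with consistent diagonals, so the mesh is
#' conforming.  Deterministic for fixed parameters.
#'
#' @param a,b ellipse semi-axes (mm).  Defaults 12 and 8.
#' @param thickness slice thickness (mm).  Default 4.
#' @param h target edge length (mm).
#' @return a [tet_mesh()] with volume close to `pi*a*b*thickness`
#'   (inscribed-polygon faceting makes it slightly smaller).
#' @export
make_slice_phantom <- function(a = 12, b = 8, thickness = 4, h = 1) {
  if (any(c(a, b, thickness, h) <= 0)) stop("all parameters must be > 0")
  m <- max(2L, as.integer(ceiling(max(a, b) / h)))
  disk <- unit_disk_triangulation(m)
  n2d <- nrow(disk$nodes)
  nz <- max(1L, as.integer(ceiling(thickness / h)))
  zs <- seq(0, thickness, length.out = nz + 1)
  nodes <- do.call(rbind, lapply(zs, function(z)
    cbind(disk$nodes[, 1] * a, disk$nodes[, 2] * b, z)))
  nt <- nrow(disk$tris)
  elements <- matrix(0L, nt * nz * 3L, 4L)
  row <- 1L
  for (l in seq_len(nz)) {
    lo <- (l - 1L) * n2d
    hi <- l * n2d
    for (t in seq_len(nt)) {
      tri <- disk$tris[t, ]
      tets <- split_prism(c(tri + lo, tri + hi))
      elements[row:(row + 2L), ] <- tets
      row <- row + 3L
    }
  }
  elements <- reorient_elements(nodes, elements)
  mesh <- tet_mesh(nodes, elements)
  attr(mesh, "phantom") <- list(shape = "elliptical_slice", a = a, b = b,
                                thickness = thickness, h = h)
  mesh
}

# closest point on triangle (p1, p2, p3) to point p (Ericson, Real-Time
# Collision Detection)
closest_point_on_triangle <- function(p, p1, p2, p3) {
  ab <- p2 - p1; ac <- p3 - p1; ap <- p - p1
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(p1)
  bp <- p - p2
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(p2)
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) return(p1 + (d1 / (d1 - d3)) * ab)
  cp <- p - p3
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(p3)
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) return(p1 + (d2 / (d2 - d6)) * ac)
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0)
    return(p2 + ((d4 - d3) / ((d4 - d3) + (d5 - d6))) * (p3 - p2))
  denom <- 1 / (va + vb + vc)
  p1 + ab * (vb * denom) + ac * (vc * denom)
}

# project a point onto the mesh boundary surface (nearest point on any
# boundary triangle; triangles preselected by vertex distance)
project_to_boundary <- function(mesh, point) {
  bf <- boundary_faces(mesh)
  cent <- (mesh$nodes[bf[, 1], , drop = FALSE] +
           mesh$nodes[bf[, 2], , drop = FALSE] +
           mesh$nodes[bf[, 3], , drop = FALSE]) / 3
  d2 <- (cent[, 1] - point[1])^2 + (cent[, 2] - point[2])^2 +
        (cent[, 3] - point[3])^2
  cand <- order(d2)[seq_len(min(30L, nrow(bf)))]
  best <- NULL; bestd <- Inf
  for (f in cand) {
    q <- closest_point_on_triangle(point,
                                   mesh$nodes[bf[f, 1], ],
                                   mesh$nodes[bf[f, 2], ],
                                   mesh$nodes[bf[f, 3], ])
    d <- sum((q - point)^2)
    if (d < bestd) { bestd <- d; best <- q }
  }
  best
}

#' Transmission optode layout
#'
#' Places `n_sources` point sources evenly along one side of the phantom
#' boundary and `n_detectors` point detectors on the opposite side, with
#' inward-pointing directions (transmission geometry).  For the elliptical
#' slice, optodes sit at mid-thickness on opposing 90-degree arcs of the
#' perimeter; for a slab, on the two opposing y-faces.  Analytic positions
#' are projected onto the faceted mesh boundary.
#'
#' @param mesh a phantom from [make_slab_mesh()] or [make_slice_phantom()].
#' @param n_sources,n_detectors number of optodes per side (>= 1).
#' @return list of [optode()] objects, sources first.
#' @export
place_transmission_optodes <- function(mesh, n_sources = 7,
                                       n_detectors = 7) {
  if (n_sources < 1 || n_detectors < 1) stop("need at least 1 optode per side")
  ph <- attr(mesh, "phantom")
  make_side <- function(n, side, kind) {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      f <- if (n == 1) 0.5 else (i - 1) / (n - 1)
      if (!is.null(ph) && ph$shape == "elliptical_slice") {
        # 90-degree arcs centred on -y (sources) and +y (detectors);
        # detector i faces source i across the minor axis
        th <- if (side > 0) -pi / 2 + (f - 0.5) * pi / 2
              else pi / 2 + (0.5 - f) * pi / 2
        pos <- c(ph$a * cos(th), ph$b * sin(th), ph$thickness / 2)
        nrm <- c(cos(th) / ph$a, sin(th) / ph$b, 0)
        dir <- -nrm / sqrt(sum(nrm^2))
      } else {
        bb <- apply(mesh$nodes, 2, range)
        xs <- bb[1, 1] + (0.15 + 0.7 * f) * (bb[2, 1] - bb[1, 1])
        y <- if (side > 0) bb[1, 2] else bb[2, 2]
        pos <- c(xs, y, (bb[1, 3] + bb[2, 3]) / 2)
        dir <- c(0, side, 0)
      }
      pos <- project_to_boundary(mesh, pos)
      out[[i]] <- optode(pos, dir, kind)
    }
    out
  }
  c(make_side(n_sources, +1, "source"),
    make_side(n_detectors, -1, "detector"))
}
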