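#' Tetrahedral mesh container
#'
#' Builds the mesh object every other component of the package operates on:
#' a set of 3D node coordinates (mm) and a set of tetrahedral elements given
#' as 4-tuples of node indices (1-based).  Elements must be positively
#' oriented (strictly positive signed volume); use [reorient_elements()] on
#' raw connectivity of unknown orientation.
#'
#' @param nodes numeric matrix, one row per node, columns x/y/z in mm.
#' @param elements integer matrix, one row per tetrahedron, 4 columns of
#'   node indices.
#' @param validate run the full validity check ([validate_mesh()]) on the
#'   result.  Disable only for meshes known valid by construction.
#' @return an object of class `tet_mesh` with fields `nodes`, `elements`,
#'   `n_nodes`, `n_elements`.
#' @export
tet_mesh <- function(nodes, elements, validate = TRUE) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  elements <- as.matrix(elements)
  storage.mode(elements) <- "integer"
  if (ncol(nodes) != 3L) stop("nodes must have 3 columns (x, y, z)")
  if (ncol(elements) != 4L) stop("elements must have 4 columns")
  dimnames(nodes) <- NULL
  dimnames(elements) <- NULL
  mesh <- structure(
    list(nodes = nodes, elements = elements,
         n_nodes = nrow(nodes), n_elements = nrow(elements)),
    class = "tet_mesh")
  if (validate) validate_mesh(mesh)
  mesh
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("tet_mesh: %d nodes, %d elements\n", x$n_nodes, x$n_elements))
  bb <- apply(x$nodes, 2, range)
  cat(sprintf("  bbox: [%.3g, %.3g] x [%.3g, %.3g] x [%.3g, %.3g] mm\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' Volume of a single tetrahedron
#'
#' @param coords 4 x 3 matrix of vertex coordinates (mm).
#' @return volume in mm^3; 0 for degenerate (coplanar) vertices.
#' @export
tet_volume <- function(coords) {
  coords <- as.matrix(coords)
  a <- coords[2, ] - coords[1, ]
  b <- coords[3, ] - coords[1, ]
  c <- coords[4, ] - coords[1, ]
  abs(det(rbind(a, b, c))) / 6
}

#' Signed volumes of all elements of a mesh
#'
#' Vectorized signed volume (positive under the package orientation
#' convention) for every element.
#'
#' @param mesh a [tet_mesh()].
#' @return numeric vector of length `n_elements` (mm^3).
#' @export
tet_volumes <- function(mesh) {
  nd <- mesh$nodes
  el <- mesh$elements
  p1 <- nd[el[, 1], , drop = FALSE]
  a <- nd[el[, 2], , drop = FALSE] - p1
  b <- nd[el[, 3], , drop = FALSE] - p1
  c <- nd[el[, 4], , drop = FALSE] - p1
  # triple product a . (b x c)
  (a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) +
   a[, 2] * (b[, 3] * c[, 1] - b[, 1] * c[, 3]) +
   a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

#' Flip negatively oriented elements
#'
#' Swaps two vertices of any element with negative signed volume so the
#' whole mesh satisfies the positive-orientation convention.
#'
#' @param nodes node coordinate matrix.
#' @param elements connectivity matrix.
#' @return connectivity matrix with all signed volumes >= 0.
#' @export
reorient_elements <- function(nodes, elements) {
  m <- tet_mesh(nodes, elements, validate = FALSE)
  v <- tet_volumes(m)
  neg <- which(v < 0)
  if (length(neg)) {
    tmp <- elements[neg, 3L]
    elements[neg, 3L] <- elements[neg, 4L]
    elements[neg, 4L] <- tmp
  }
  elements
}

# Sorted face table: one row per element face (4 per element), with the
# owning element and the local face index (face j is opposite local vertex j).
face_table <- function(mesh) {
  el <- mesh$elements
  m <- nrow(el)
  # face opposite local vertex 1..4
  f1 <- el[, c(2L, 3L, 4L), drop = FALSE]
  f2 <- el[, c(1L, 3L, 4L), drop = FALSE]
  f3 <- el[, c(1L, 2L, 4L), drop = FALSE]
  f4 <- el[, c(1L, 2L, 3L), drop = FALSE]
  faces <- rbind(f1, f2, f3, f4)
  faces_sorted <- t(apply(faces, 1L, sort.int))
  if (m == 0L) faces_sorted <- matrix(integer(0), 0L, 3L)
  list(faces = faces_sorted,
       elem = rep.int(seq_len(m), 4L),
       local = rep(1:4, each = m))
}

# keys identifying faces uniquely (character)
face_keys <- function(faces) {
  paste(faces[, 1], faces[, 2], faces[, 3], sep = "_")
}

#' Boundary faces of a mesh
#'
#' Faces incident to exactly one element.
#'
#' @param mesh a [tet_mesh()].
#' @return integer matrix with 3 columns of node indices (sorted per row).
#' @export
boundary_faces <- function(mesh) {
  ft <- face_table(mesh)
  keys <- face_keys(ft$faces)
  cnt <- table(keys)
  bnd <- names(cnt)[cnt == 1L]
  ft$faces[keys %in% bnd, , drop = FALSE]
}

#' Nodes lying on the mesh boundary
#'
#' @param mesh a [tet_mesh()].
#' @return logical vector of length `n_nodes`.
#' @export
boundary_nodes <- function(mesh) {
  bf <- boundary_faces(mesh)
  out <- logical(mesh$n_nodes)
  out[as.vector(bf)] <- TRUE
  out
}

#' Element adjacency across faces
#'
#' @param mesh a [tet_mesh()].
#' @return integer matrix `n_elements` x 4; entry `[i, j]` is the element
#'   sharing the face of element `i` opposite its local vertex `j`, or `NA`
#'   when that face is on the boundary.
#' @export
element_neighbors <- function(mesh) {
  ft <- face_table(mesh)
  keys <- face_keys(ft$faces)
  ord <- order(keys, ft$elem)
  k <- keys[ord]
  e <- ft$elem[ord]
  l <- ft$local[ord]
  nb <- matrix(NA_integer_, mesh$n_elements, 4L)
  n <- length(k)
  if (n >= 2L) {
    same_next <- c(k[-1L] == k[-n], FALSE)
    i <- which(same_next)           # pairs (i, i+1) share a face
    nb[cbind(e[i], l[i])] <- e[i + 1L]
    nb[cbind(e[i + 1L], l[i + 1L])] <- e[i]
  }
  nb
}

#' Validate a tetrahedral mesh
#'
#' Checks index validity, element non-degeneracy, strictly positive signed
#' volumes, and conformity (each face shared by exactly 1 or 2 elements,
#' with no face appearing more than twice).
#'
#' @param mesh a [tet_mesh()].
#' @return `TRUE` invisibly; stops with a diagnostic message on failure.
#' @export
validate_mesh <- function(mesh) {
  el <- mesh$elements
  if (anyNA(el) || any(el < 1L) || any(el > mesh$n_nodes))
    stop("element references a node index outside 1..", mesh$n_nodes)
  dup <- el[, 1] == el[, 2] | el[, 1] == el[, 3] | el[, 1] == el[, 4] |
         el[, 2] == el[, 3] | el[, 2] == el[, 4] | el[, 3] == el[, 4]
  if (any(dup))
    stop("element ", which(dup)[1], " repeats a node index")
  v <- tet_volumes(mesh)
  if (any(v <= 0))
    stop("element ", which(v <= 0)[1],
         " has nonpositive signed volume (", min(v), " mm^3)")
  ft <- face_table(mesh)
  cnt <- table(face_keys(ft$faces))
  if (any(cnt > 2L))
    stop("mesh is not conforming: a face is shared by ", max(cnt),
         " elements")
  invisible(TRUE)
}

#' Element shape quality
#'
#' Scale-invariant mean-ratio shape measure
#' `q = 12 (3V)^(2/3) / sum(edge lengths^2)`, equal to 1 for the regular
#' tetrahedron and tending to 0 for slivers.
#'
#' @param mesh a [tet_mesh()].
#' @return numeric vector of per-element qualities in (0, 1].
#' @export
tet_qualities <- function(mesh) {
  nd <- mesh$nodes
  el <- mesh$elements
  v <- abs(tet_volumes(mesh))
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  ssq <- 0
  for (r in seq_len(nrow(pairs))) {
    d <- nd[el[, pairs[r, 1]], , drop = FALSE] -
         nd[el[, pairs[r, 2]], , drop = FALSE]
    ssq <- ssq + rowSums(d * d)
  }
  12 * (3 * v)^(2 / 3) / ssq
}

#' Minimum element quality of a mesh
#'
#' @param mesh a [tet_mesh()].
#' @return scalar in (0, 1]; see [tet_qualities()].
#' @export
min_quality <- function(mesh) min(tet_qualities(mesh))

# Barycentric coordinates of `point` with respect to every element
# (n_elements x 4 matrix).  Used by brute-force location.
all_barycentric <- function(mesh, point) {
  nd <- mesh$nodes
  el <- mesh$elements
  p1 <- nd[el[, 1], , drop = FALSE]
  a <- nd[el[, 2], , drop = FALSE] - p1
  b <- nd[el[, 3], , drop = FALSE] - p1
  c <- nd[el[, 4], , drop = FALSE] - p1
  d6 <- (a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) +
         a[, 2] * (b[, 3] * c[, 1] - b[, 1] * c[, 3]) +
         a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1]))
  r <- cbind(point[1] - p1[, 1], point[2] - p1[, 2], point[3] - p1[, 3])
  # Cramer's rule on [a b c] lambda = r
  det3 <- function(x, y, z) {
    x[, 1] * (y[, 2] * z[, 3] - y[, 3] * z[, 2]) +
    x[, 2] * (y[, 3] * z[, 1] - y[, 1] * z[, 3]) +
    x[, 3] * (y[, 1] * z[, 2] - y[, 2] * z[, 1])
  }
  l2 <- det3(r, b, c) / d6
  l3 <- det3(a, r, c) / d6
  l4 <- det3(a, b, r) / d6
  cbind(1 - l2 - l3 - l4, l2, l3, l4)
}

barycentric_in_element <- function(mesh, elem, point) {
  idx <- mesh$elements[elem, ]
  p1 <- mesh$nodes[idx[1], ]
  M <- cbind(mesh$nodes[idx[2], ] - p1,
             mesh$nodes[idx[3], ] - p1,
             mesh$nodes[idx[4], ] - p1)
  l <- solve(M, point - p1)
  c(1 - sum(l), l)
}

#' Locate the element containing a point
#'
#' Walks from the element incident to the nearest node toward the point,
#' moving across the face with the most negative barycentric coordinate,
#' with a brute-force scan over all elements as fallback.  A point on a
#' shared face is assigned to the lowest-index incident element by the
#' brute-force path; the walk may return either incident element.
#'
#' @param mesh a [tet_mesh()].
#' @param point numeric length-3 position (mm).
#' @param tol barycentric slack: the point is inside an element when all
#'   four barycentric coordinates are `>= -tol`.
#' @return element index, or `NA_integer_` when the point is outside the
#'   mesh.
#' @export
locate_point <- function(mesh, point, tol = 1e-8) {
  point <- as.numeric(point)
  inc <- node_incidence_cached(mesh)
  d2 <- (mesh$nodes[, 1] - point[1])^2 + (mesh$nodes[, 2] - point[2])^2 +
        (mesh$nodes[, 3] - point[3])^2
  start_node <- which.min(d2)
  cur <- inc[[start_node]][1]
  visited <- integer(0)
  for (step in seq_len(mesh$n_elements)) {
    if (is.na(cur) || cur %in% visited) break
    visited <- c(visited, cur)
    l <- barycentric_in_element(mesh, cur, point)
    if (all(l >= -tol)) return(cur)
    worst <- which.min(l)
    nb <- element_neighbors_cached(mesh)[cur, worst]
    cur <- nb
  }
  # fallback: exhaustive scan (deterministic lowest-index tie-break)
  l <- all_barycentric(mesh, point)
  ok <- which(rowSums(l >= -tol) == 4L)
  if (length(ok)) ok[1] else NA_integer_
}

# per-mesh caches, keyed off environment attached to the mesh object are
# awkward with copy-on-modify; instead memoize on a content hash of the
# connectivity in a package-local environment (small meshes only).
.mesh_cache <- new.env(parent = emptyenv())

mesh_key <- function(mesh) {
  paste0(mesh$n_nodes, "_", mesh$n_elements, "_",
         sum(as.double(mesh$elements) * seq_along(mesh$elements)) %% 2^40,
         "_", sum(mesh$nodes))
}

element_neighbors_cached <- function(mesh) {
  key <- paste0("nb_", mesh_key(mesh))
  if (is.null(.mesh_cache[[key]])) {
    if (length(ls(.mesh_cache)) > 64L)
      rm(list = ls(.mesh_cache), envir = .mesh_cache)
    .mesh_cache[[key]] <- element_neighbors(mesh)
  }
  .mesh_cache[[key]]
}

node_incidence_cached <- function(mesh) {
  key <- paste0("inc_", mesh_key(mesh))
  if (is.null(.mesh_cache[[key]])) {
    if (length(ls(.mesh_cache)) > 64L)
      rm(list = ls(.mesh_cache), envir = .mesh_cache)
    .mesh_cache[[key]] <- node_incidence(mesh)
  }
  .mesh_cache[[key]]
}

#' Node-to-element incidence lists
#'
#' @param mesh a [tet_mesh()].
#' @return list of length `n_nodes`; entry `i` holds the indices of the
#'   elements incident to node `i` (possibly empty).
#' @export
node_incidence <- function(mesh) {
  el <- mesh$elements
  m <- nrow(el)
  split(rep.int(seq_len(m), 4L), factor(as.vector(el),
                                        levels = seq_len(mesh$n_nodes)))
}

#' Undirected edge set of a mesh
#'
#' Every undirected node pair appearing in at least one element, with the
#' complete list of incident elements per edge.
#'
#' @param mesh a [tet_mesh()].
#' @return list with `edges` (integer matrix e x 2, first column < second),
#'   `lengths` (numeric, mm) and `incident` (list of element index vectors).
#' @export
edge_set <- function(mesh) {
  el <- mesh$elements
  m <- nrow(el)
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  i <- as.vector(el[, pairs[, 1]])
  j <- as.vector(el[, pairs[, 2]])
  lo <- pmin(i, j); hi <- pmax(i, j)
  eid <- rep.int(seq_len(m), 6L)
  key <- paste0(lo, "_", hi)
  first <- !duplicated(key)
  edges <- cbind(lo[first], hi[first])
  incident <- split(eid, factor(key, levels = key[first]))
  lens <- sqrt(rowSums((mesh$nodes[edges[, 1], , drop = FALSE] -
                        mesh$nodes[edges[, 2], , drop = FALSE])^2))
  list(edges = edges, lengths = lens, incident = unname(incident))
}

#' Nodal volume shares
#'
#' One quarter of the total volume of the elements incident to each node --
#' the quadrature weight used to discretize volume integrals over the mesh.
#'
#' @param mesh a [tet_mesh()].
#' @return numeric vector of length `n_nodes` (mm^3); sums to the total
#'   mesh volume.
#' @export
node_volumes <- function(mesh) {
  v <- tet_volumes(mesh)
  el <- mesh$elements
  vn <- numeric(mesh$n_nodes)
  for (k in 1:4) {
    acc <- rowsum(v, group = el[, k])
    idx <- as.integer(rownames(acc))
    vn[idx] <- vn[idx] + acc[, 1]
  }
  vn / 4
}

#' Total mesh volume
#'
#' @param mesh a [tet_mesh()].
#' @return scalar mm^3.
#' @export
mesh_volume <- function(mesh) sum(tet_volumes(mesh))

# bounding-box diagonal, the package's reference length scale for tolerances
bbox_diagonal <- function(mesh) {
  bb <- apply(mesh$nodes, 2, range)
  sqrt(sum((bb[2, ] - bb[1, ])^2))
}
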