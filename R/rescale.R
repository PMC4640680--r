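#' Build the mesh-to-mesh transformation matrix
#'
#' Sparse operator `T` (input-mesh nodes x output-mesh nodes) that carries
#' nodal Jacobian values from `old_mesh` onto `new_mesh`.  Each output node
#' falls into one of three cases:
#'
#' 1. *carried*: an input node coincides with it (within `tol`); its column
#'    is a unit vector on that node.
#' 2. *interior*: it falls inside an input element; the element's four
#'    vertices are weighted inversely to their distance,
#'    `w_i = 1/d(x, x_i)`, normalized to sum to one.
#' 3. *exterior*: it lies outside the input mesh; the four nearest input
#'    nodes are weighted the same way.
#'
#' A zero distance in cases 2-3 degenerates to case 1.  Every column sums
#' to one, so constant fields are preserved exactly.
#'
#' @param old_mesh,new_mesh [tet_mesh()] objects.
#' @param tol coincidence tolerance (mm); default `1e-9` times the input
#'   mesh bounding-box diagonal.
#' @param method `"idw"` (inverse-distance weighting, the default and the
#'   method validated throughout the package) or `"barycentric"`, an
#'   opt-in comparison mode that replaces the interior-case weights with
#'   the linear shape-function (barycentric) coordinates of the output
#'   node; exterior and carried cases are unchanged.
#' @return an object of class `mesh_transformation`: sparse `matrix`
#'   (`Matrix::dgCMatrix`), per-column `cases`
#'   (`"carried"|"interior"|"exterior"`), and `tol`.
#' @export
build_transformation <- function(old_mesh, new_mesh, tol = NULL,
                                 method = c("idw", "barycentric")) {
  method <- match.arg(method)
  if (old_mesh$n_nodes < 1) stop("input mesh has no nodes")
  if (is.null(tol)) tol <- 1e-9 * bbox_diagonal(old_mesh)
  n_old <- old_mesh$n_nodes
  n_new <- new_mesh$n_nodes

  on <- old_mesh$nodes
  nn <- new_mesh$nodes

  tri_i <- vector("list", n_new)
  tri_x <- vector("list", n_new)
  cases <- character(n_new)

  {
    for (j in seq_len(n_new)) {
      p <- nn[j, ]
      # plain per-node distances so that exact ties resolve by the stable
      # lowest-index order, matching the documented tie-break
      dj <- (on[, 1] - p[1])^2 + (on[, 2] - p[2])^2 + (on[, 3] - p[3])^2
      nearest <- which.min(dj)
      if (sqrt(dj[nearest]) <= tol) {
        tri_i[[j]] <- nearest
        tri_x[[j]] <- 1
        cases[j] <- "carried"
        next
      }
      el <- locate_point(old_mesh, p)
      if (!is.na(el) &&
          min(barycentric_in_element(old_mesh, el, p)) < 1e-9) {
        # point sits on a shared face or edge: several elements contain it
        # and their inverse-distance weights differ, so break the tie
        # deterministically by the lowest containing element index
        bc <- all_barycentric(old_mesh, p)
        ok <- which(rowSums(bc >= -1e-8) == 4L)
        if (length(ok)) el <- ok[1]
      }
      if (!is.na(el)) {
        verts <- old_mesh$elements[el, ]
        cases[j] <- "interior"
      } else {
        verts <- order(dj)[1:4]
        cases[j] <- "exterior"
      }
      d <- sqrt(dj[verts])
      zero <- d <= .Machine$double.eps
      if (any(zero)) {           # degenerate: exact hit on an input node
        k <- verts[which(zero)[1]]
        tri_i[[j]] <- k
        tri_x[[j]] <- 1
        cases[j] <- "carried"
      } else if (method == "barycentric" && cases[j] == "interior") {
        lam <- barycentric_in_element(old_mesh, el, p)
        lam <- pmax(lam, 0)
        tri_i[[j]] <- as.integer(verts)
        tri_x[[j]] <- lam / sum(lam)
      } else {
        w <- 1 / d
        tri_i[[j]] <- as.integer(verts)
        tri_x[[j]] <- w / sum(w)
      }
    }
  }
  i <- unlist(tri_i)
  x <- unlist(tri_x)
  jcol <- rep.int(seq_len(n_new), vapply(tri_i, length, 1L))
  T <- Matrix::sparseMatrix(i = i, j = jcol, x = x,
                            dims = c(n_old, n_new))
  structure(list(matrix = T, cases = cases, tol = tol,
                 from_hash = mesh_hash(old_mesh),
                 to_hash = mesh_hash(new_mesh)),
            class = "mesh_transformation")
}

#' @export
print.mesh_transformation <- function(x, ...) {
  d <- dim(x$matrix)
  tab <- table(factor(x$cases, c("carried", "interior", "exterior")))
  cat(sprintf(
    "mesh_transformation: %d -> %d nodes (%d carried, %d interior, %d exterior)\n",
    d[1], d[2], tab[1], tab[2], tab[3]))
  invisible(x)
}

#' Compose two transformations
#'
#' `compose_transformations(t1, t2)` maps from `t1`'s input mesh to `t2`'s
#' output mesh; rescaling with the composition equals rescaling twice.
#'
#' @param t1,t2 `mesh_transformation` objects with compatible dimensions.
#' @return a `mesh_transformation`.
#' @export
compose_transformations <- function(t1, t2) {
  if (ncol(t1$matrix) != nrow(t2$matrix))
    stop("dimension mismatch: ", ncol(t1$matrix), " vs ", nrow(t2$matrix))
  structure(list(matrix = t1$matrix %*% t2$matrix,
                 cases = t2$cases, tol = t1$tol,
                 from_hash = t1$from_hash, to_hash = t2$to_hash),
            class = "mesh_transformation")
}

#' Rescale a Jacobian onto a new mesh
#'
#' Right-multiplies every (pair, gate) slice by the transformation matrix:
#' the new Jacobian is obtained analytically, with no new stochastic
#' simulation.
#'
#' @param jac a [jacobian()] (or a bare `n_gates x n_nodes` slice matrix).
#' @param transform a `mesh_transformation` built from the Jacobian's mesh.
#' @param new_mesh optional [tet_mesh()]; updates the provenance hash.
#' @return object of the same shape as `jac` on the new mesh.
#' @export
rescale_jacobian <- function(jac, transform, new_mesh = NULL) {
  T <- transform$matrix
  if (is.matrix(jac)) {
    if (ncol(jac) != nrow(T))
      stop("Jacobian has ", ncol(jac), " nodes; transformation expects ",
           nrow(T))
    return(as.matrix(jac %*% T))
  }
  stopifnot(inherits(jac, "jacobian"))
  d <- dim(jac$W)
  if (d[3] != nrow(T))
    stop("Jacobian has ", d[3], " nodes; transformation expects ", nrow(T))
  flat <- matrix(jac$W, nrow = d[1] * d[2], ncol = d[3])
  newW <- as.matrix(flat %*% T)
  out <- jac
  out$W <- array(newW, dim = c(d[1], d[2], ncol(T)))
  out$mesh_hash <- if (!is.null(new_mesh)) mesh_hash(new_mesh)
                   else transform$to_hash
  out
}

#' Persist a transformation matrix as a text container
#'
#' Coordinate-format sparse triplets (CSV) plus JSON metadata with the
#' per-column case tags.
#'
#' @param transform a `mesh_transformation`.
#' @param path output path (a `.json` and a `.csv` file are written using
#'   this stem).
#' @return `path` invisibly.
#' @export
write_transformation <- function(transform, path) {
  stem <- tools::file_path_sans_ext(path)
  tri <- Matrix::summary(transform$matrix)
  write.csv(data.frame(row = tri$i, col = tri$j, value = tri$x),
            paste0(stem, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(dims = dim(transform$matrix), cases = transform$cases,
         tol = transform$tol, from_hash = transform$from_hash,
         to_hash = transform$to_hash),
    paste0(stem, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a transformation written by [write_transformation()]
#'
#' @param path path used at write time.
#' @return a `mesh_transformation`.
#' @export
read_transformation <- function(path) {
  stem <- tools::file_path_sans_ext(path)
  tri <- read.csv(paste0(stem, ".csv"))
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  structure(list(
    matrix = Matrix::sparseMatrix(i = tri$row, j = tri$col, x = tri$value,
                                  dims = meta$dims),
    cases = meta$cases, tol = meta$tol,
    from_hash = meta$from_hash, to_hash = meta$to_hash),
    class = "mesh_transformation")
}
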