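#' Mesh adaptation configuration
#'
#' @param max_iterations cap on adaptation iterations (default 30).
#' @param volume_cutoff optional stopping criterion: stop at the first
#'   iteration whose maximum element volume reaches this value (mm^3).
#' @param collapse_ratio collapse trigger: an edge is a collapse candidate
#'   when its ratio of current to target length (`1 / size factor` for the
#'   relative size fields used here) falls below this value.  The default
#'   of 1 collapses any edge shorter than its target, subject to the
#'   validity guards; coarsening then proceeds gradually because each
#'   accepted operation freezes its neighborhood for the rest of the pass.
#' @param split_ratio split trigger: an edge is split when current/target
#'   exceeds this value (default `sqrt(2)`).
#' @param quality_floor minimum mean-ratio element quality an operation may
#'   leave behind (default 0.02).
#' @return an object of class `adapt_config`.
#' @export
adapt_config <- function(max_iterations = 30, volume_cutoff = NULL,
                         collapse_ratio = 1, split_ratio = sqrt(2),
                         quality_floor = 0.02) {
  if (max_iterations < 1) stop("max_iterations must be >= 1")
  if (!(collapse_ratio > 0 && collapse_ratio <= 1))
    stop("collapse_ratio must be in (0, 1]")
  if (split_ratio <= 1) stop("split_ratio must be > 1")
  if (!(quality_floor > 0 && quality_floor < 1))
    stop("quality_floor must be in (0, 1)")
  structure(list(max_iterations = as.integer(max_iterations),
                 volume_cutoff = volume_cutoff,
                 collapse_ratio = collapse_ratio,
                 split_ratio = split_ratio,
                 quality_floor = quality_floor),
            class = "adapt_config")
}

# ---------------------------------------------------------------------------
# incremental mesh editor: mutable environment holding nodes, elements,
# incidence lists and a face-count map, so that edge collapses and splits
# (with their validity guards) run in time proportional to the local cavity.
# ---------------------------------------------------------------------------

ed_face_keys_row <- function(row) {
  s <- sort.int(row)
  c(paste(s[2], s[3], s[4], sep = "_"),
    paste(s[1], s[3], s[4], sep = "_"),
    paste(s[1], s[2], s[4], sep = "_"),
    paste(s[1], s[2], s[3], sep = "_"))
}

ed_init <- function(mesh, factors = NULL, h_ref = NULL) {
  ed <- new.env(parent = emptyenv())
  ed$nodes <- mesh$nodes
  ed$elements <- mesh$elements
  ed$elem_alive <- rep(TRUE, mesh$n_elements)
  ed$node_alive <- rep(TRUE, mesh$n_nodes)
  ed$factors <- factors
  ed$h_ref <- h_ref
  ed$inc <- node_incidence(mesh)
  ed$volume0 <- sum(tet_volumes(mesh))
  ft <- face_table(mesh)
  keys <- face_keys(ft$faces)
  cnt <- table(keys)
  fm <- new.env(hash = TRUE, size = length(cnt), parent = emptyenv())
  nms <- names(cnt)
  vals <- as.integer(cnt)
  for (k in seq_along(nms)) assign(nms[k], vals[k], envir = fm)
  ed$fm <- fm
  ed$boundary <- boundary_nodes(mesh)
  ed
}

ed_face_count <- function(ed, key) {
  v <- ed$fm[[key]]
  if (is.null(v)) 0L else v
}

ed_vol_rows <- function(nodes, rows) {
  p1 <- nodes[rows[, 1], , drop = FALSE]
  a <- nodes[rows[, 2], , drop = FALSE] - p1
  b <- nodes[rows[, 3], , drop = FALSE] - p1
  c <- nodes[rows[, 4], , drop = FALSE] - p1
  (a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) +
   a[, 2] * (b[, 3] * c[, 1] - b[, 1] * c[, 3]) +
   a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

ed_quality_rows <- function(nodes, rows) {
  v <- abs(ed_vol_rows(nodes, rows))
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  ssq <- 0
  for (r in seq_len(nrow(pairs))) {
    d <- nodes[rows[, pairs[r, 1]], , drop = FALSE] -
         nodes[rows[, pairs[r, 2]], , drop = FALSE]
    ssq <- ssq + rowSums(d * d)
  }
  12 * (3 * v)^(2 / 3) / ssq
}

ed_edge_elems <- function(ed, a, b) {
  ee <- intersect(ed$inc[[a]], ed$inc[[b]])
  ee[ed$elem_alive[ee]]
}

# is (a, b) an edge of the current boundary surface?
ed_boundary_edge <- function(ed, a, b, ee) {
  for (e in ee) {
    row <- ed$elements[e, ]
    others <- row[row != a & row != b]
    for (o in others) {
      s <- sort.int(c(a, b, o))
      if (ed_face_count(ed, paste(s[1], s[2], s[3], sep = "_")) == 1L)
        return(TRUE)
    }
  }
  FALSE
}

# attempt collapse of edge (a, b), merging `removed` into `kept`;
# returns list(ok = TRUE, cavity_nodes = ...) or list(ok = FALSE, reason =)
# When the editor carries size factors and reference sizes, new edges at the
# kept node must stay within split_ratio of their own target length.
ed_try_collapse <- function(ed, a, b, kept, quality_floor,
                            split_ratio = NULL) {
  removed <- if (kept == a) b else a
  ee <- ed_edge_elems(ed, a, b)
  if (!length(ee)) return(list(ok = FALSE, reason = "no-edge"))
  cavity <- ed$inc[[removed]]
  cavity <- cavity[ed$elem_alive[cavity]]
  modified <- setdiff(cavity, ee)

  if (ed$boundary[removed]) {
    if (!ed$boundary[kept])
      return(list(ok = FALSE, reason = "boundary"))
    if (!ed_boundary_edge(ed, a, b, ee))
      return(list(ok = FALSE, reason = "boundary"))
  }

  old_rows <- ed$elements[modified, , drop = FALSE]
  new_rows <- old_rows
  new_rows[new_rows == removed] <- kept

  if (nrow(new_rows)) {
    vols <- ed_vol_rows(ed$nodes, new_rows)
    if (any(vols <= 0)) return(list(ok = FALSE, reason = "inversion"))
    if (any(ed_quality_rows(ed$nodes, new_rows) < quality_floor))
      return(list(ok = FALSE, reason = "quality"))
    # overshoot guard: edges gained by the kept node must not exceed
    # split_ratio times their target length
    if (!is.null(split_ratio) && !is.null(ed$factors) &&
        !is.null(ed$h_ref)) {
      ring <- setdiff(unique(as.vector(old_rows[rowSums(old_rows == removed)
                                                > 0, , drop = FALSE])),
                      c(removed, kept))
      if (length(ring)) {
        len <- sqrt(rowSums((ed$nodes[ring, , drop = FALSE] -
                             matrix(ed$nodes[kept, ], length(ring), 3,
                                    byrow = TRUE))^2))
        sf <- (ed$factors[ring] + ed$factors[kept]) / 2
        hr <- (ed$h_ref[ring] + ed$h_ref[kept]) / 2
        if (any(len > split_ratio * sf * hr))
          return(list(ok = FALSE, reason = "overshoot"))
      }
    }
    # duplicate-element guard within the modified cavity and against the
    # surviving elements already incident to the kept node
    keep_inc <- setdiff(ed$inc[[kept]][ed$elem_alive[ed$inc[[kept]]]], cavity)
    ex_keys <- if (length(keep_inc))
      apply(ed$elements[keep_inc, , drop = FALSE], 1L,
            function(r) paste(sort.int(r), collapse = "_")) else character(0)
    new_keys <- apply(new_rows, 1L,
                      function(r) paste(sort.int(r), collapse = "_"))
    if (anyDuplicated(c(new_keys, ex_keys)))
      return(list(ok = FALSE, reason = "duplicate"))
  } else {
    vols <- numeric(0)
  }

  # face-count bookkeeping (also the non-manifold guard)
  del_keys <- c(unlist(lapply(ee, function(e)
                  ed_face_keys_row(ed$elements[e, ]))),
                if (nrow(old_rows)) unlist(apply(old_rows, 1L,
                  ed_face_keys_row, simplify = FALSE)))
  add_keys <- if (nrow(new_rows))
    unlist(apply(new_rows, 1L, ed_face_keys_row, simplify = FALSE))
    else character(0)
  touched <- unique(c(del_keys, add_keys))
  delta <- integer(length(touched))
  names(delta) <- touched
  for (k in del_keys) delta[k] <- delta[k] - 1L
  for (k in add_keys) delta[k] <- delta[k] + 1L
  final <- vapply(touched, function(k) ed_face_count(ed, k), 1L) + delta
  if (any(final > 2L)) return(list(ok = FALSE, reason = "nonmanifold"))
  if (any(final < 0L)) return(list(ok = FALSE, reason = "nonmanifold"))

  # volume conservation: exact for interior collapses; boundary collapses
  # may only merge across (near-)coplanar surface patches
  v_old <- sum(abs(ed_vol_rows(ed$nodes, ed$elements[cavity, ,
                                                     drop = FALSE])))
  v_new <- sum(vols)
  dv <- abs(v_new - v_old)
  if (!ed$boundary[removed]) {
    if (dv > max(1e-7 * v_old, 1e-12))
      return(list(ok = FALSE, reason = "volume"))
  } else {
    if (dv > max(1e-9 * ed$volume0, 1e-12))
      return(list(ok = FALSE, reason = "volume-boundary"))
  }

  # ---- apply ----
  for (k in touched) {
    f <- ed_face_count(ed, k) + delta[[k]]
    assign(k, f, envir = ed$fm)
  }
  ed$elem_alive[ee] <- FALSE
  if (nrow(new_rows)) ed$elements[modified, ] <- new_rows
  cavity_nodes <- unique(as.vector(ed$elements[cavity, , drop = FALSE]))
  # incidence updates
  for (v in cavity_nodes) ed$inc[[v]] <- setdiff(ed$inc[[v]], ee)
  ed$inc[[kept]] <- union(ed$inc[[kept]], modified)
  ed$inc[[removed]] <- integer(0)
  ed$node_alive[removed] <- FALSE
  list(ok = TRUE, cavity_nodes = cavity_nodes)
}

# split edge (a, b) at its midpoint; returns the new node index
ed_split <- function(ed, a, b) {
  ee <- ed_edge_elems(ed, a, b)
  if (!length(ee)) stop("unknown edge (", a, ", ", b, ")")
  mid <- (ed$nodes[a, ] + ed$nodes[b, ]) / 2
  on_boundary <- ed_boundary_edge(ed, a, b, ee)
  ed$nodes <- rbind(ed$nodes, mid)
  nid <- nrow(ed$nodes)
  ed$node_alive <- c(ed$node_alive, TRUE)
  ed$boundary <- c(ed$boundary, on_boundary)
  if (!is.null(ed$factors))
    ed$factors <- c(ed$factors, (ed$factors[a] + ed$factors[b]) / 2)
  if (!is.null(ed$h_ref))
    ed$h_ref <- c(ed$h_ref, (ed$h_ref[a] + ed$h_ref[b]) / 2)
  ed$inc[[nid]] <- integer(0)

  for (e in ee) {
    old <- ed$elements[e, ]
    e1 <- old; e1[e1 == b] <- nid       # keeps a
    e2 <- old; e2[e2 == a] <- nid       # keeps b
    for (k in ed_face_keys_row(old))
      assign(k, ed_face_count(ed, k) - 1L, envir = ed$fm)
    for (k in c(ed_face_keys_row(e1), ed_face_keys_row(e2)))
      assign(k, ed_face_count(ed, k) + 1L, envir = ed$fm)
    ed$elements[e, ] <- e1
    ed$elements <- rbind(ed$elements, e2)
    ed$elem_alive <- c(ed$elem_alive, TRUE)
    id2 <- nrow(ed$elements)
    # incidence: slot e now holds e1 (contains a, not b)
    ed$inc[[b]] <- setdiff(ed$inc[[b]], e)
    for (v in old[old != a & old != b]) ed$inc[[v]] <- union(ed$inc[[v]], id2)
    ed$inc[[b]] <- union(ed$inc[[b]], id2)
    ed$inc[[nid]] <- union(ed$inc[[nid]], c(e, id2))
  }
  nid
}

# compact the editor state into a fresh validated mesh
ed_to_mesh <- function(ed, validate = TRUE) {
  live_nodes <- which(ed$node_alive)
  remap <- integer(nrow(ed$nodes))
  remap[live_nodes] <- seq_along(live_nodes)
  el <- ed$elements[ed$elem_alive, , drop = FALSE]
  el[] <- remap[el]
  mesh <- tet_mesh(ed$nodes[live_nodes, , drop = FALSE], el,
                   validate = validate)
  attr(mesh, "node_map") <- remap
  mesh
}

# ---------------------------------------------------------------------------
# public single-edge operations
# ---------------------------------------------------------------------------

check_edge <- function(mesh, edge) {
  edge <- as.integer(edge)
  if (length(edge) != 2 || anyNA(edge) || any(edge < 1) ||
      any(edge > mesh$n_nodes) || edge[1] == edge[2])
    stop("edge must be two distinct node indices in 1..", mesh$n_nodes)
  edge
}

#' Split a mesh edge at its midpoint
#'
#' Adds one node and replaces every element incident to the edge by two;
#' total volume of the affected elements is conserved exactly and the mesh
#' stays conforming.
#'
#' @param mesh a [tet_mesh()].
#' @param edge integer pair of node indices forming an existing edge.
#' @return the refined [tet_mesh()].
#' @export
split_edge <- function(mesh, edge) {
  edge <- check_edge(mesh, edge)
  ed <- ed_init(mesh)
  if (!length(ed_edge_elems(ed, edge[1], edge[2])))
    stop("nodes ", edge[1], " and ", edge[2], " do not form an edge")
  ed_split(ed, edge[1], edge[2])
  ed_to_mesh(ed)
}

#' Collapse a mesh edge
#'
#' Merges one endpoint into `kept_node`, removing the elements incident to
#' the edge.  The collapse is rejected (returning a `collapse_rejected`
#' object rather than a mesh) if any surviving element would invert or
#' fall below the quality floor, if the removed endpoint is on the
#' boundary while the kept one is interior (or the edge is not part of the
#' boundary surface), if it would create duplicate elements or
#' non-manifold faces, or if it would change the enclosed volume (boundary
#' collapses are restricted to coplanar surface patches).
#'
#' @param mesh a [tet_mesh()].
#' @param edge integer pair of node indices forming an existing edge.
#' @param kept_node one of the two endpoints; the other is removed.
#' @param quality_floor minimum surviving element quality.
#' @return the coarsened [tet_mesh()], or a `collapse_rejected` object
#'   whose `reason` field names the violated guard.
#' @export
collapse_edge <- function(mesh, edge, kept_node, quality_floor = 0.02) {
  edge <- check_edge(mesh, edge)
  if (!kept_node %in% edge)
    stop("kept_node must be one of the edge endpoints")
  ed <- ed_init(mesh)
  if (!length(ed_edge_elems(ed, edge[1], edge[2])))
    stop("nodes ", edge[1], " and ", edge[2], " do not form an edge")
  res <- ed_try_collapse(ed, edge[1], edge[2], kept_node, quality_floor)
  if (!res$ok)
    return(structure(list(reason = res$reason, edge = edge,
                          kept_node = kept_node),
                     class = "collapse_rejected"))
  ed_to_mesh(ed)
}

#' @export
print.collapse_rejected <- function(x, ...) {
  cat(sprintf("collapse of edge (%d, %d) into %d REJECTED: %s\n",
              x$edge[1], x$edge[2], x$kept_node, x$reason))
  invisible(x)
}

#' Test whether a collapse was rejected
#'
#' @param x result of [collapse_edge()].
#' @return logical.
#' @export
is_rejected <- function(x) inherits(x, "collapse_rejected")

# ---------------------------------------------------------------------------
# adaptation passes
# ---------------------------------------------------------------------------

# edge list of the editor's live elements
ed_live_edges <- function(ed) {
  el <- ed$elements[ed$elem_alive, , drop = FALSE]
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  i <- as.vector(el[, pairs[, 1]])
  j <- as.vector(el[, pairs[, 2]])
  lo <- pmin(i, j); hi <- pmax(i, j)
  key <- paste0(lo, "_", hi)
  first <- !duplicated(key)
  cbind(lo[first], hi[first])
}

#' Local edge-length scale at each node
#'
#' Mean length of the edges incident to each node -- the reference size
#' the adaptation loop measures size factors against.
#'
#' @param mesh a [tet_mesh()].
#' @return numeric vector of length `n_nodes` (mm).
#' @export
node_local_size <- function(mesh) {
  es <- edge_set(mesh)
  sums <- numeric(mesh$n_nodes)
  cnts <- numeric(mesh$n_nodes)
  for (k in 1:2) {
    acc <- rowsum(es$lengths, group = es$edges[, k])
    idx <- as.integer(rownames(acc))
    sums[idx] <- sums[idx] + acc[, 1]
    cnt <- rowsum(rep(1, nrow(es$edges)), group = es$edges[, k])
    cnts[idx] <- cnts[idx] + cnt[, 1]
  }
  out <- sums / pmax(cnts, 1)
  out[cnts == 0] <- NA_real_
  out
}

#' One mesh adaptation pass
#'
#' Every edge has a target length equal to the mean of its endpoint size
#' factors times its reference length scale (the mean of the endpoints'
#' `h_ref`, which defaults to the current local edge length so that one
#' pass applies the size factors once).  Edges whose current/target ratio
#' falls below `collapse_ratio` are collapsed (most undersized first),
#' then edges whose ratio exceeds `split_ratio` are split at their
#' midpoints (most oversized first).  Only edges whose mean size factor
#' exceeds 1 may collapse and only those below 1 may split, so a unit
#' size field leaves any mesh unchanged.  A collapse is additionally rejected
#' when an edge gained by the kept node would exceed `split_ratio` times
#' its own target.  Each accepted operation freezes the nodes of its
#' cavity for the remainder of the pass, keeping the pass local and
#' deterministic; candidate order is broken by ascending node indices.
#' When both endpoints lie on the boundary (or both are interior), the
#' merge direction keeping the lower node index is tried first, then the
#' other.
#'
#' @param mesh a [tet_mesh()].
#' @param size_field a `size_field` defined on the mesh nodes.
#' @param config an [adapt_config()].
#' @param h_ref per-node reference length scale (mm); defaults to
#'   [node_local_size()] of `mesh`.  [adapt_loop()] passes the initial
#'   mesh's scale through all iterations so the size field is always
#'   measured against the starting discretization.
#' @return list with `mesh` (the adapted [tet_mesh()]), `h_ref`
#'   (transferred onto the new mesh's nodes) and `record` (nodes,
#'   elements, max element volume, splits, collapses).
#' @export
adapt_once <- function(mesh, size_field, config = adapt_config(),
                       h_ref = NULL) {
  factors <- size_field$factors
  if (length(factors) != mesh$n_nodes)
    stop("size field has ", length(factors), " factors; mesh has ",
         mesh$n_nodes, " nodes")
  if (is.null(h_ref)) h_ref <- node_local_size(mesh)
  if (length(h_ref) != mesh$n_nodes)
    stop("h_ref has ", length(h_ref), " entries; mesh has ", mesh$n_nodes,
         " nodes")
  ed <- ed_init(mesh, factors = factors, h_ref = h_ref)
  frozen <- rep(FALSE, mesh$n_nodes)
  n_collapses <- 0L
  n_splits <- 0L

  edge_ratios <- function() {
    edges <- ed_live_edges(ed)
    len <- sqrt(rowSums((ed$nodes[edges[, 1], , drop = FALSE] -
                         ed$nodes[edges[, 2], , drop = FALSE])^2))
    sf_e <- (ed$factors[edges[, 1]] + ed$factors[edges[, 2]]) / 2
    hr_e <- (ed$h_ref[edges[, 1]] + ed$h_ref[edges[, 2]]) / 2
    list(edges = edges, sf = sf_e, ratio = len / (sf_e * hr_e))
  }

  # ---- collapse pass (most undersized edges first) ----
  # only edges whose size field actually requests coarsening are candidates,
  # so a unit size field is a fixed point even on irregular meshes
  er <- edge_ratios()
  cand <- which(er$sf > 1 + 1e-12 & er$ratio < config$collapse_ratio)
  cand <- cand[order(er$ratio[cand], er$edges[cand, 1], er$edges[cand, 2])]
  for (ci in cand) {
    a <- er$edges[ci, 1]; b <- er$edges[ci, 2]
    if (frozen[a] || frozen[b]) next
    if (!ed$node_alive[a] || !ed$node_alive[b]) next
    ba <- ed$boundary[a]; bb <- ed$boundary[b]
    tries <- if (ba && !bb) a
             else if (bb && !ba) b
             else c(min(a, b), max(a, b))
    for (kept in tries) {
      res <- ed_try_collapse(ed, a, b, kept, config$quality_floor,
                             split_ratio = config$split_ratio)
      if (res$ok) {
        n_collapses <- n_collapses + 1L
        frozen[res$cavity_nodes] <- TRUE
        break
      }
    }
  }

  # ---- split pass (most oversized edges first) ----
  er <- edge_ratios()
  cand <- which(er$sf < 1 - 1e-12 & er$ratio > config$split_ratio)
  cand <- cand[order(-er$ratio[cand], er$edges[cand, 1], er$edges[cand, 2])]
  for (ci in cand) {
    a <- er$edges[ci, 1]; b <- er$edges[ci, 2]
    if (frozen[a] || frozen[b]) next
    if (!ed$node_alive[a] || !ed$node_alive[b]) next
    ee <- ed_edge_elems(ed, a, b)
    if (!length(ee)) next
    affected <- unique(as.vector(ed$elements[ee, , drop = FALSE]))
    nid <- ed_split(ed, a, b)
    n_splits <- n_splits + 1L
    frozen <- c(frozen, rep(FALSE, nrow(ed$nodes) - length(frozen)))
    frozen[c(affected, nid)] <- TRUE
  }

  out <- ed_to_mesh(ed)
  live <- which(ed$node_alive)
  list(mesh = out,
       h_ref = ed$h_ref[live],
       record = list(nodes = out$n_nodes, elements = out$n_elements,
                     max_elem_vol_mm3 = max(tet_volumes(out)),
                     splits = n_splits, collapses = n_collapses))
}

#' Iterative size-field-driven mesh adaptation
#'
#' Repeats [adapt_once()]: at each iteration the solution field is
#' computed on the current mesh (for Jacobian-based recipes, from the
#' Jacobian analytically rescaled onto that mesh; geometry recipes are
#' recomputed from geometry), converted to a size field, and one
#' adaptation pass is applied.  After each pass the transformation matrix
#' from the previous mesh is built and the Jacobian (when present)
#' rescaled.  The loop stops at convergence (a pass leaves both node and
#' element counts unchanged), when the maximum element volume reaches
#' `config$volume_cutoff`, or after `config$max_iterations`.
#'
#' @param mesh starting [tet_mesh()].
#' @param field_recipe recipe name (see [compute_solution_field()]).
#' @param params a [size_field_params()].
#' @param config an [adapt_config()].
#' @param jacobian optional [jacobian()] on `mesh` (required for
#'   Jacobian-based recipes).
#' @param optodes,props,mu passed to geometry recipes.
#' @param size_field_fallback passed to [to_size_field()].
#' @param build_transforms build the per-iteration transformation matrices
#'   and their composition (default `TRUE`; required when a Jacobian is
#'   given).  Disable for geometry-recipe studies that only need the
#'   adapted mesh and report.
#' @return list with `mesh` (final), `report` (one data-frame row per
#'   iteration: nodes, elements, max element volume, splits, collapses),
#'   `transformation` (composed `mesh_transformation` from the initial to
#'   the final mesh), `transformations` (per-iteration list), `jacobian`
#'   (rescaled onto the final mesh, when given), `converged`, and
#'   `stopped_by` (`"convergence"`, `"volume_cutoff"` or
#'   `"max_iterations"`).
#' @export
adapt_loop <- function(mesh, field_recipe, params, config = adapt_config(),
                       jacobian = NULL, optodes = NULL, props = NULL,
                       mu = NULL, size_field_fallback = "error",
                       build_transforms = TRUE) {
  if (!build_transforms && !is.null(jacobian))
    stop("a Jacobian cannot be rescaled without transformation matrices")
  rows <- list()
  transforms <- list()
  t_total <- NULL
  jac <- jacobian
  cur <- mesh
  h_ref <- node_local_size(mesh)
  converged <- FALSE
  stopped_by <- "max_iterations"

  for (it in seq_len(config$max_iterations)) {
    field <- compute_solution_field(field_recipe, cur, jac = jac,
                                    optodes = optodes, mu = mu,
                                    props = props)
    sf <- to_size_field(field, params, fallback = size_field_fallback)
    step <- adapt_once(cur, sf, config, h_ref = h_ref)
    h_ref <- step$h_ref
    if (build_transforms) {
      tr <- build_transformation(cur, step$mesh)
      transforms[[it]] <- tr
      t_total <- if (is.null(t_total)) tr else
        compose_transformations(t_total, tr)
      if (!is.null(jac)) jac <- rescale_jacobian(jac, tr)
    }
    rows[[it]] <- data.frame(iteration = it,
                             nodes = step$record$nodes,
                             elements = step$record$elements,
                             max_elem_vol_mm3 = step$record$max_elem_vol_mm3,
                             splits = step$record$splits,
                             collapses = step$record$collapses)
    unchanged <- step$mesh$n_nodes == cur$n_nodes &&
                 step$mesh$n_elements == cur$n_elements
    cur <- step$mesh
    if (unchanged) {
      converged <- TRUE
      stopped_by <- "convergence"
      break
    }
    if (!is.null(config$volume_cutoff) &&
        step$record$max_elem_vol_mm3 >= config$volume_cutoff) {
      stopped_by <- "volume_cutoff"
      break
    }
  }
  list(mesh = cur, report = do.call(rbind, rows),
       transformation = t_total, transformations = transforms,
       jacobian = jac, converged = converged, stopped_by = stopped_by)
}

#' Write an adaptation report as CSV
#'
#' One row per iteration with node/element counts, the maximum element
#' volume and the numbers of splits and collapses.
#'
#' @param report the `report` data frame from [adapt_loop()].
#' @param path output CSV path.
#' @return `path` invisibly.
#' @export
write_adapt_report <- function(report, path) {
  write.csv(report, path, row.names = FALSE)
  invisible(path)
}
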