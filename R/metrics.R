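#' Per-node percent error against a reference
#'
#' `e(r) = |(v(r) - v_ref(r)) / v_ref(r)| * 100` for every node with a
#' nonzero reference value; nodes with `v_ref = 0` are excluded and
#' counted in the `excluded` attribute.
#'
#' @param v per-node values (e.g. a Jacobian at one gate).
#' @param v_ref per-node reference values of the same length.
#' @return numeric vector of percent errors (length = number of nodes with
#'   nonzero reference), with attributes `nodes` (their indices) and
#'   `excluded` (count of zero-reference nodes).
#' @export
nodal_error <- function(v, v_ref) {
  if (length(v) != length(v_ref))
    stop("v and v_ref must have the same length")
  if (all(v_ref == 0))
    stop("all reference values are zero; e(r) is undefined")
  keep <- which(v_ref != 0)
  e <- abs((v[keep] - v_ref[keep]) / v_ref[keep]) * 100
  attr(e, "nodes") <- keep
  attr(e, "excluded") <- length(v_ref) - length(keep)
  e
}

#' Mean error over a node set
#'
#' Arithmetic mean of per-node percent errors over a chosen node set
#' (typically the central nodes between a source-detector pair).
#'
#' @param e per-node errors from [nodal_error()] (carrying a `nodes`
#'   attribute), or a plain vector indexed directly by node.
#' @param node_set node indices to average over.
#' @return scalar percent.
#' @export
mean_central_error <- function(e, node_set) {
  if (length(node_set) < 1) stop("node_set must be nonempty")
  idx_map <- attr(e, "nodes")
  if (!is.null(idx_map)) {
    pos <- match(node_set, idx_map)
    pos <- pos[!is.na(pos)]
    if (!length(pos))
      stop("none of the requested nodes has a defined error")
    mean(e[pos])
  } else {
    mean(e[node_set])
  }
}

#' Per-gate percent error between two TPSFs
#'
#' `|(test - ref) / ref| * 100` per gate; gates with a zero reference are
#' excluded (returned as `NA`).
#'
#' @param tpsf_test,tpsf_ref per-gate values of the same length.
#' @return numeric vector of percent errors with `NA` at zero-reference
#'   gates.
#' @export
tpsf_error <- function(tpsf_test, tpsf_ref) {
  if (length(tpsf_test) != length(tpsf_ref))
    stop("TPSFs must share the same gating")
  out <- rep(NA_real_, length(tpsf_ref))
  keep <- tpsf_ref != 0
  out[keep] <- abs((tpsf_test[keep] - tpsf_ref[keep]) / tpsf_ref[keep]) * 100
  out
}

#' Central node set of a source-detector pair
#'
#' Nodes within `radius` of the midpoint between the source and detector
#' positions -- the region of worst photon statistics in transmission
#' geometry, used to evaluate the stochastic stability of the Jacobian.
#'
#' @param mesh a [tet_mesh()].
#' @param source,detector [optode()] objects.
#' @param radius inclusion radius (mm); default 15% of the
#'   source-detector separation.
#' @return integer node indices (at least the node nearest the midpoint;
#'   an empty radius result triggers a warning and returns that nearest
#'   node).
#' @export
central_node_set <- function(mesh, source, detector, radius = NULL) {
  mid <- (source$position + detector$position) / 2
  sep <- sqrt(sum((source$position - detector$position)^2))
  if (is.null(radius)) radius <- 0.15 * sep
  d2 <- (mesh$nodes[, 1] - mid[1])^2 + (mesh$nodes[, 2] - mid[2])^2 +
        (mesh$nodes[, 3] - mid[3])^2
  idx <- which(d2 <= radius^2)
  if (!length(idx)) {
    warning("no node within radius ", signif(radius, 4),
            " of the pair midpoint; returning the nearest node")
    idx <- which.min(d2)
  }
  idx
}

#' Assemble an error report
#'
#' @param tpsf_err per-gate percent errors ([tpsf_error()]).
#' @param nodal_err per-node percent errors ([nodal_error()]).
#' @param node_set central node indices the mean is taken over.
#' @param meta named list of run metadata (photon counts, seeds, meshes).
#' @return an object of class `error_report` with the per-gate table, the
#'   per-node table, the mean central error and the metadata.
#' @export
error_report <- function(tpsf_err, nodal_err, node_set, meta = list()) {
  structure(list(
    tpsf_error = tpsf_err,
    nodal_error = as.numeric(nodal_err),
    nodal_index = attr(nodal_err, "nodes"),
    excluded_nodes = attr(nodal_err, "excluded"),
    node_set = node_set,
    mean_central = mean_central_error(nodal_err, node_set),
    meta = meta),
    class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf(
    "error_report: max TPSF error %.3g%%, mean central e(r) %.3g%% over %d nodes\n",
    max(x$tpsf_error, na.rm = TRUE), x$mean_central, length(x$node_set)))
  invisible(x)
}

#' Write an error report (JSON + CSV)
#'
#' Writes `<stem>.json` with the full report and two CSV tables
#' (`<stem>_gates.csv`, `<stem>_nodes.csv`).
#'
#' @param report an [error_report()].
#' @param path output stem or `.json` path.
#' @return `path` invisibly.
#' @export
write_error_report <- function(report, path) {
  stem <- tools::file_path_sans_ext(path)
  jsonlite::write_json(unclass(report), paste0(stem, ".json"),
                       digits = NA, auto_unbox = TRUE)
  write.csv(data.frame(gate = seq_along(report$tpsf_error),
                       error_pct = report$tpsf_error),
            paste0(stem, "_gates.csv"), row.names = FALSE)
  write.csv(data.frame(node = report$nodal_index,
                       error_pct = report$nodal_error),
            paste0(stem, "_nodes.csv"), row.names = FALSE)
  invisible(path)
}
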