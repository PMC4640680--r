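#' Read a tetrahedral mesh from disk
#'
#' Supported formats: a TetGen `.node`/`.ele` pair (pass the path of either
#' file, or the common stem), and legacy ASCII VTK unstructured grids
#' containing tetrahedra (cell type 10).  TetGen files may be 0- or 1-based
#' on disk (detected from the first index); both are mapped to the 1-based
#' internal convention.
#'
#' @param path file path (for TetGen, the `.node`, `.ele` or stem path).
#' @param format `"tetgen"`, `"vtk"`, or `"auto"` (from the extension).
#' @return a [tet_mesh()].
#' @export
read_mesh <- function(path, format = c("auto", "tetgen", "vtk")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "vtk") "vtk" else "tetgen"
  }
  if (format == "vtk") read_vtk(path) else read_tetgen(path)
}

#' Write a tetrahedral mesh to disk
#'
#' @param mesh a [tet_mesh()].
#' @param path output path: stem or `.node`/`.ele` path for TetGen, `.vtk`
#'   path for VTK.
#' @param format `"tetgen"` or `"vtk"` (default from extension).
#' @param point_data optional named list of per-node numeric vectors,
#'   written as VTK `POINT_DATA` scalar fields (VTK format only).
#' @param digits significant digits for coordinates.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "tetgen", "vtk"),
                       point_data = NULL, digits = 12) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "vtk") "vtk" else "tetgen"
  }
  if (format == "vtk") write_vtk(mesh, path, point_data = point_data,
                                 digits = digits)
  else write_tetgen(mesh, path, digits = digits)
  invisible(path)
}

tetgen_stem <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("node", "ele")) tools::file_path_sans_ext(path) else path
}

# tokenized non-comment lines of a TetGen file
tetgen_lines <- function(path) {
  txt <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", txt)
  lines <- sub("#.*$", "", txt[keep])
  list(tokens = strsplit(trimws(lines), "\\s+"), lineno = which(keep))
}

read_tetgen <- function(path) {
  stem <- tetgen_stem(path)
  node_path <- paste0(stem, ".node")
  ele_path <- paste0(stem, ".ele")
  for (p in c(node_path, ele_path))
    if (!file.exists(p)) stop("missing TetGen file: ", p)

  nl <- tetgen_lines(node_path)
  hdr <- suppressWarnings(as.numeric(nl$tokens[[1]]))
  if (length(hdr) < 1 || is.na(hdr[1]))
    stop("malformed TetGen header in ", node_path, " at line ", nl$lineno[1])
  n <- as.integer(hdr[1])
  if (length(nl$tokens) < n + 1)
    stop(node_path, ": header announces ", n, " nodes but file has ",
         length(nl$tokens) - 1)
  ids <- integer(n)
  nodes <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    tok <- suppressWarnings(as.numeric(nl$tokens[[i + 1]]))
    if (length(tok) < 4 || anyNA(tok[1:4]))
      stop("malformed node record in ", node_path, " at line ",
           nl$lineno[i + 1])
    ids[i] <- as.integer(tok[1])
    nodes[i, ] <- tok[2:4]
  }
  offset <- ids[1]            # 0 or 1 on disk
  if (!offset %in% c(0L, 1L))
    stop(node_path, ": first node index must be 0 or 1, got ", offset)

  el <- tetgen_lines(ele_path)
  ehdr <- suppressWarnings(as.numeric(el$tokens[[1]]))
  if (length(ehdr) < 1 || is.na(ehdr[1]))
    stop("malformed TetGen header in ", ele_path, " at line ", el$lineno[1])
  m <- as.integer(ehdr[1])
  if (length(el$tokens) < m + 1)
    stop(ele_path, ": header announces ", m, " elements but file has ",
         length(el$tokens) - 1)
  elements <- matrix(NA_integer_, m, 4)
  for (i in seq_len(m)) {
    tok <- suppressWarnings(as.numeric(el$tokens[[i + 1]]))
    if (length(tok) < 5 || anyNA(tok[1:5]))
      stop("malformed element record in ", ele_path, " at line ",
           el$lineno[i + 1])
    elements[i, ] <- as.integer(tok[2:5])
  }
  elements <- elements - offset + 1L     # to 1-based internal
  if (any(elements < 1L) || any(elements > n))
    stop(ele_path, ": element references node index beyond the ", n,
         " nodes declared in ", node_path)
  tet_mesh(nodes, elements)
}

write_tetgen <- function(mesh, path, digits = 12) {
  stem <- tetgen_stem(path)
  fmt <- paste0("%d %.", digits, "g %.", digits, "g %.", digits, "g")
  node_lines <- c(
    sprintf("%d 3 0 0", mesh$n_nodes),
    sprintf(fmt, seq_len(mesh$n_nodes),
            mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]))
  writeLines(node_lines, paste0(stem, ".node"))
  ele_lines <- c(
    sprintf("%d 4 0", mesh$n_elements),
    sprintf("%d %d %d %d %d", seq_len(mesh$n_elements),
            mesh$elements[, 1], mesh$elements[, 2],
            mesh$elements[, 3], mesh$elements[, 4]))
  writeLines(ele_lines, paste0(stem, ".ele"))
  invisible(stem)
}

read_vtk <- function(path) {
  txt <- readLines(path, warn = FALSE)
  ip <- grep("^POINTS", txt)
  if (!length(ip)) stop(path, ": no POINTS section (line ", length(txt), ")")
  n <- as.integer(strsplit(trimws(txt[ip[1]]), "\\s+")[[1]][2])
  if (is.na(n)) stop(path, ": malformed POINTS header at line ", ip[1])
  vals <- numeric(0)
  i <- ip[1] + 1
  while (length(vals) < 3 * n && i <= length(txt)) {
    vals <- c(vals, suppressWarnings(
      as.numeric(strsplit(trimws(txt[i]), "\\s+")[[1]])))
    i <- i + 1
  }
  if (length(vals) < 3 * n || anyNA(vals[seq_len(3 * n)]))
    stop(path, ": POINTS section truncated or malformed near line ", i - 1)
  nodes <- matrix(vals[seq_len(3 * n)], ncol = 3, byrow = TRUE)

  ic <- grep("^CELLS", txt)
  if (!length(ic)) stop(path, ": no CELLS section")
  hdr <- as.integer(strsplit(trimws(txt[ic[1]]), "\\s+")[[1]][2:3])
  m <- hdr[1]
  cells <- matrix(NA_integer_, m, 4)
  for (k in seq_len(m)) {
    tok <- suppressWarnings(
      as.integer(strsplit(trimws(txt[ic[1] + k]), "\\s+")[[1]]))
    if (length(tok) < 1 || is.na(tok[1]))
      stop(path, ": malformed cell record at line ", ic[1] + k)
    if (tok[1] != 4)
      stop(path, ": cell at line ", ic[1] + k, " has ", tok[1],
           " points; only tetrahedra (4) supported")
    cells[k, ] <- tok[2:5]
  }
  it <- grep("^CELL_TYPES", txt)
  if (length(it)) {
    types <- suppressWarnings(as.integer(unlist(
      strsplit(trimws(txt[(it[1] + 1):min(length(txt), it[1] + m)]), "\\s+"))))
    if (any(types[seq_len(m)] != 10L, na.rm = TRUE))
      stop(path, ": contains non-tetrahedral cell types (expected type 10)")
  }
  if (any(cells < 0L) || any(cells >= n))
    stop(path, ": cell references point index beyond ", n, " points")
  tet_mesh(nodes, cells + 1L)   # VTK is 0-based on disk
}

write_vtk <- function(mesh, path, point_data = NULL, digits = 12) {
  fmt <- paste0("%.", digits, "g %.", digits, "g %.", digits, "g")
  out <- c(
    "# vtk DataFile Version 3.0",
    "tetrahedral mesh",
    "ASCII",
    "DATASET UNSTRUCTURED_GRID",
    sprintf("POINTS %d double", mesh$n_nodes),
    sprintf(fmt, mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]),
    sprintf("CELLS %d %d", mesh$n_elements, 5L * mesh$n_elements),
    sprintf("4 %d %d %d %d",
            mesh$elements[, 1] - 1L, mesh$elements[, 2] - 1L,
            mesh$elements[, 3] - 1L, mesh$elements[, 4] - 1L),
    sprintf("CELL_TYPES %d", mesh$n_elements),
    rep("10", mesh$n_elements))
  if (!is.null(point_data)) {
    out <- c(out, sprintf("POINT_DATA %d", mesh$n_nodes))
    for (nm in names(point_data)) {
      vals <- point_data[[nm]]
      stopifnot(length(vals) == mesh$n_nodes)
      out <- c(out,
               sprintf("SCALARS %s double 1", nm),
               "LOOKUP_TABLE default",
               sprintf(paste0("%.", digits, "g"), vals))
    }
  }
  writeLines(out, path)
  invisible(path)
}
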