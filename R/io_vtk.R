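#' Write a mesh (with optional fields) as a legacy-ASCII VTK unstructured grid
#'
#' Cell type 10 (tetrahedron), zero-based connectivity as VTK requires.
#' Per-element arrays go under `CELL_DATA`, per-node arrays under
#' `POINT_DATA`; this is the format contour-plotting tools (ParaView etc.)
#' consume.
#'
#' @param mesh a `tet_mesh`.
#' @param path output `.vtk` path.
#' @param cell_data named list of numeric vectors, one value per element.
#' @param point_data named list of numeric vectors, one value per node.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, cell_data = list(), point_data = list()) {
  n <- nrow(mesh$nodes); ne <- nrow(mesh$elements)
  for (nm in names(cell_data)) {
    if (length(cell_data[[nm]]) != ne) {
      stop("cell_data '", nm, "' must have one value per element")
    }
  }
  for (nm in names(point_data)) {
    if (length(point_data[[nm]]) != n) {
      stop("point_data '", nm, "' must have one value per node")
    }
  }
  out <- c("# vtk DataFile Version 3.0",
           "craniofem unstructured grid",
           "ASCII",
           "DATASET UNSTRUCTURED_GRID",
           paste("POINTS", n, "double"),
           sprintf("%.17g %.17g %.17g",
                   mesh$nodes[, 1L], mesh$nodes[, 2L], mesh$nodes[, 3L]),
           paste("CELLS", ne, 5L * ne),
           sprintf("4 %d %d %d %d",
                   mesh$elements[, 1L] - 1L, mesh$elements[, 2L] - 1L,
                   mesh$elements[, 3L] - 1L, mesh$elements[, 4L] - 1L),
           paste("CELL_TYPES", ne),
           rep("10", ne))
  emit_arrays <- function(arrays) {
    res <- character(0)
    for (nm in names(arrays)) {
      res <- c(res,
               paste("SCALARS", nm, "double 1"),
               "LOOKUP_TABLE default",
               sprintf("%.17g", as.numeric(arrays[[nm]])))
    }
    res
  }
  if (length(cell_data)) {
    out <- c(out, paste("CELL_DATA", ne), emit_arrays(cell_data))
  }
  if (length(point_data)) {
    out <- c(out, paste("POINT_DATA", n), emit_arrays(point_data))
  }
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("cannot write VTK file: ", path))
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Read back a legacy-ASCII VTK unstructured grid written by [write_vtk()]
#'
#' Minimal reader for round-trip verification of exported fields; not a
#' general VTK parser.
#'
#' @param path `.vtk` file path.
#' @return list with `nodes`, `elements` (1-based), `cell_data`,
#'   `point_data`.
#' @export
read_vtk <- function(path) {
  lines <- readLines(path, warn = FALSE)
  i_pts <- grep("^POINTS ", lines)[1L]
  n <- as.integer(strsplit(lines[i_pts], "\\s+")[[1]][2L])
  pts <- do.call(rbind, lapply(lines[i_pts + seq_len(n)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  i_cells <- grep("^CELLS ", lines)[1L]
  ne <- as.integer(strsplit(lines[i_cells], "\\s+")[[1]][2L])
  el <- do.call(rbind, lapply(lines[i_cells + seq_len(ne)], function(l) {
    as.integer(strsplit(trimws(l), "\\s+")[[1]][2:5]) + 1L
  }))
  read_arrays <- function(start, count) {
    arrays <- list()
    i <- start
    while (i <= length(lines) && !grepl("^(CELL_DATA|POINT_DATA) ", lines[i])) {
      if (grepl("^SCALARS ", lines[i])) {
        nm <- strsplit(lines[i], "\\s+")[[1]][2L]
        vals <- as.numeric(lines[(i + 2L):(i + 1L + count)])
        arrays[[nm]] <- vals
        i <- i + 2L + count
      } else i <- i + 1L
    }
    arrays
  }
  cell_data <- list(); point_data <- list()
  i_cd <- grep("^CELL_DATA ", lines)
  if (length(i_cd)) cell_data <- read_arrays(i_cd[1L] + 1L, ne)
  i_pd <- grep("^POINT_DATA ", lines)
  if (length(i_pd)) point_data <- read_arrays(i_pd[1L] + 1L, n)
  list(nodes = pts, elements = el,
       cell_data = cell_data, point_data = point_data)
}
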