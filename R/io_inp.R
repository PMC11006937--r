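#' Read a tetrahedral mesh
#'
#' Reads either the minimal Abaqus-INP dialect (`*NODE`, `*ELEMENT
#' TYPE=C3D4`, `*NSET`, `*ELSET` blocks, comma-separated data lines,
#' `**` comments) or the package's internal serialised format (an `.rds`
#' of a `tet_mesh`, runtime plumbing only).
#'
#' File node/element ids may be arbitrary positive integers; they are
#' remapped to contiguous 1-based internal indices in ascending id order.
#' Element sets named `MATERIAL-<label>` are interpreted as the material
#' assignment (the convention [write_mesh_inp()] emits); all other sets are
#' kept by name.
#'
#' @param path file path.
#' @param format `"inp"` or `"internal"`.
#' @return a validated `tet_mesh` with normalised element orientation.
#' @export
read_mesh <- function(path, format = c("inp", "internal")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("mesh file not found: ", path)
  if (format == "internal") {
    mesh <- readRDS(path)
    if (!inherits(mesh, "tet_mesh")) stop("not a serialised tet_mesh: ", path)
    return(mesh)
  }
  lines <- readLines(path, warn = FALSE)
  n_lines <- length(lines)
  nodes_id <- numeric(0); nodes_xyz <- list()
  elem_id <- integer(0); elem_conn <- list()
  nsets <- list(); elsets <- list()
  mode <- "none"; current_set <- NULL

  parse_numeric <- function(line, i, what, n_expected) {
    parts <- strsplit(line, ",")[[1]]
    parts <- trimws(parts)
    parts <- parts[parts != ""]
    vals <- suppressWarnings(as.numeric(parts))
    if (anyNA(vals)) {
      stop("parse error at line ", i, ": malformed ", what, " record: ", line)
    }
    if (!is.na(n_expected) && length(vals) != n_expected) {
      stop("parse error at line ", i, ": expected ", n_expected,
           " fields in ", what, " record, got ", length(vals))
    }
    vals
  }
  kw_option <- function(header, key) {
    m <- regmatches(header, regexec(paste0(key, "\\s*=\\s*([^,\\s]+)"),
                                    header, ignore.case = TRUE,
                                    perl = TRUE))[[1]]
    if (length(m) < 2L) NA_character_ else m[2L]
  }

  for (i in seq_len(n_lines)) {
    line <- trimws(lines[i])
    if (line == "" || startsWith(line, "**")) next
    if (startsWith(line, "*")) {
      header <- line
      up <- toupper(header)
      if (startsWith(up, "*NODE")) {
        mode <- "node"
      } else if (startsWith(up, "*ELEMENT")) {
        type <- kw_option(header, "TYPE")
        if (is.na(type) || toupper(type) != "C3D4") {
          stop("unsupported element type at line ", i, ": ",
               if (is.na(type)) "(missing TYPE)" else type,
               "; only C3D4 (tet4) is supported")
        }
        mode <- "element"
      } else if (startsWith(up, "*NSET")) {
        current_set <- kw_option(header, "NSET")
        if (is.na(current_set)) stop("*NSET without NSET= name at line ", i)
        if (is.null(nsets[[current_set]])) nsets[[current_set]] <- numeric(0)
        mode <- "nset"
      } else if (startsWith(up, "*ELSET")) {
        current_set <- kw_option(header, "ELSET")
        if (is.na(current_set)) stop("*ELSET without ELSET= name at line ", i)
        if (is.null(elsets[[current_set]])) elsets[[current_set]] <- numeric(0)
        mode <- "elset"
      } else {
        mode <- "skip"  # unrecognised keyword block: ignore its data lines
      }
      next
    }
    if (mode == "node") {
      vals <- parse_numeric(line, i, "*NODE", 4L)
      nodes_id <- c(nodes_id, vals[1L])
      nodes_xyz[[length(nodes_xyz) + 1L]] <- vals[2:4]
    } else if (mode == "element") {
      vals <- parse_numeric(line, i, "*ELEMENT", 5L)
      elem_id <- c(elem_id, as.integer(vals[1L]))
      elem_conn[[length(elem_conn) + 1L]] <- as.integer(vals[2:5])
    } else if (mode == "nset") {
      vals <- parse_numeric(line, i, "*NSET", NA)
      nsets[[current_set]] <- c(nsets[[current_set]], vals)
    } else if (mode == "elset") {
      vals <- parse_numeric(line, i, "*ELSET", NA)
      elsets[[current_set]] <- c(elsets[[current_set]], vals)
    } else if (mode == "none") {
      stop("parse error at line ", i, ": data before any keyword block")
    }
  }
  if (length(nodes_id) == 0L) stop("no *NODE records in ", path)
  if (anyDuplicated(nodes_id)) stop("duplicate node ids in ", path)

  ord <- order(nodes_id)
  nodes <- do.call(rbind, nodes_xyz)[ord, , drop = FALSE]
  id_map <- stats::setNames(seq_along(ord), as.character(nodes_id[ord]))
  remap_nodes <- function(ids, what) {
    m <- id_map[as.character(ids)]
    if (anyNA(m)) stop(what, " references unknown node id")
    as.integer(m)
  }
  eord <- order(elem_id)
  elements <- if (length(elem_conn)) {
    conn <- do.call(rbind, elem_conn)[eord, , drop = FALSE]
    matrix(remap_nodes(conn, "element"), ncol = 4L)
  } else matrix(integer(0), 0L, 4L)
  eid_map <- stats::setNames(seq_along(eord), as.character(elem_id[eord]))

  node_sets <- lapply(nsets, function(v) remap_nodes(v, "node set"))
  el_sets <- lapply(elsets, function(v) {
    m <- eid_map[as.character(as.integer(v))]
    if (anyNA(m)) stop("element set references unknown element id")
    as.integer(m)
  })

  element_material <- rep("bone", nrow(elements))
  mat_sets <- grep("^MATERIAL-", names(el_sets), value = TRUE)
  for (nm in mat_sets) {
    element_material[el_sets[[nm]]] <- sub("^MATERIAL-", "", nm)
  }
  el_sets <- el_sets[setdiff(names(el_sets), mat_sets)]

  tet_mesh(nodes, elements, element_material = element_material,
           node_sets = node_sets, element_sets = el_sets)
}

#' Write a mesh in the minimal Abaqus-INP dialect
#'
#' Emits `*NODE`, `*ELEMENT, TYPE=C3D4`, one `*NSET` per node set, one
#' `*ELSET` per element set, and one `*ELSET, ELSET=MATERIAL-<label>` per
#' distinct material label so that material assignment round-trips through
#' [read_mesh()]. Coordinates are written with 17 significant digits so the
#' round-trip is exact to double precision.
#'
#' @param mesh a `tet_mesh`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mesh_inp <- function(mesh, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  out <- c("*NODE",
           sprintf("%d, %.17g, %.17g, %.17g", seq_len(nrow(mesh$nodes)),
                   mesh$nodes[, 1L], mesh$nodes[, 2L], mesh$nodes[, 3L]),
           "*ELEMENT, TYPE=C3D4",
           sprintf("%d, %d, %d, %d, %d", seq_len(nrow(mesh$elements)),
                   mesh$elements[, 1L], mesh$elements[, 2L],
                   mesh$elements[, 3L], mesh$elements[, 4L]))
  chunk <- function(v) {
    # <= 16 ids per data line, Abaqus-style
    split(v, ceiling(seq_along(v) / 16))
  }
  for (nm in names(mesh$node_sets)) {
    out <- c(out, paste0("*NSET, NSET=", nm),
             vapply(chunk(mesh$node_sets[[nm]]),
                    function(x) paste(x, collapse = ", "), character(1)))
  }
  for (nm in names(mesh$element_sets)) {
    out <- c(out, paste0("*ELSET, ELSET=", nm),
             vapply(chunk(mesh$element_sets[[nm]]),
                    function(x) paste(x, collapse = ", "), character(1)))
  }
  for (lab in unique(mesh$element_material)) {
    idx <- which(mesh$element_material == lab)
    out <- c(out, paste0("*ELSET, ELSET=MATERIAL-", lab),
             vapply(chunk(idx),
                    function(x) paste(x, collapse = ", "), character(1)))
  }
  writeLines(out, con)
  invisible(path)
}

#' Write a mesh in the internal serialised format
#'
#' @param mesh a `tet_mesh`.
#' @param path output `.rds` path.
#' @return `path`, invisibly.
#' @export
write_mesh_internal <- function(mesh, path) {
  saveRDS(mesh, path)
  invisible(path)
}
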