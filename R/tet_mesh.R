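#' Tetrahedral mesh container
#'
#' Construct a `tet_mesh`, the geometric substrate of every load scenario:
#' node coordinates (mm), four-noded tetrahedral (tet4) connectivity,
#' per-element material labels, and named node/element sets (landmark
#' patches such as palate bite points, quadrate articular surfaces, the
#' occipital condyle, and jaw-adductor origin sites).
#'
#' Element orientation is normalised on construction: any element with
#' negative signed volume has two nodes swapped so that all signed volumes
#' are positive. Indices are 1-based throughout.
#'
#' @param nodes numeric matrix, one row per node, columns x/y/z in mm.
#' @param elements integer matrix, one row per tet4 element, 4 node indices.
#' @param element_material character vector of material labels, one per
#'   element (recycled if length 1). Default `"bone"`.
#' @param node_sets named list of integer vectors of node indices.
#' @param element_sets named list of integer vectors of element indices.
#' @param normalize_orientation swap nodes of inverted elements so all
#'   signed volumes are positive (default `TRUE`).
#' @return an object of class `tet_mesh`.
#' @export
tet_mesh <- function(nodes, elements, element_material = "bone",
                     node_sets = list(), element_sets = list(),
                     normalize_orientation = TRUE) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  if (ncol(nodes) != 3L) stop("nodes must have 3 columns (x, y, z)")
  elements <- as.matrix(elements)
  storage.mode(elements) <- "integer"
  if (ncol(elements) != 4L) stop("elements must have 4 columns (tet4)")
  n <- nrow(nodes)
  if (nrow(elements) > 0L &&
      (min(elements) < 1L || max(elements) > n)) {
    stop("element connectivity references node indices outside 1..", n)
  }
  element_material <- rep_len(as.character(element_material),
                              max(nrow(elements), 0L))
  for (nm in names(node_sets)) {
    idx <- as.integer(node_sets[[nm]])
    if (length(idx) && (min(idx) < 1L || max(idx) > n)) {
      stop("node set '", nm, "' references invalid node indices")
    }
    node_sets[[nm]] <- sort(unique(idx))
  }
  for (nm in names(element_sets)) {
    idx <- as.integer(element_sets[[nm]])
    if (length(idx) && (min(idx) < 1L || max(idx) > nrow(elements))) {
      stop("element set '", nm, "' references invalid element indices")
    }
    element_sets[[nm]] <- sort(unique(idx))
  }
  mesh <- structure(
    list(nodes = nodes, elements = elements,
         element_material = element_material,
         node_sets = node_sets, element_sets = element_sets),
    class = "tet_mesh")
  if (normalize_orientation && nrow(elements) > 0L) {
    v <- tet_signed_volumes(mesh)
    flip <- which(v < 0)
    if (length(flip)) {
      tmp <- mesh$elements[flip, 3L]
      mesh$elements[flip, 3L] <- mesh$elements[flip, 4L]
      mesh$elements[flip, 4L] <- tmp
    }
  }
  mesh
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat("tet_mesh:", nrow(x$nodes), "nodes,", nrow(x$elements),
      "tet4 elements,", length(unique(x$element_material)), "material(s)\n")
  if (length(x$node_sets)) {
    cat("  node sets:", paste(names(x$node_sets), collapse = ", "), "\n")
  }
  if (length(x$element_sets)) {
    cat("  element sets:", paste(names(x$element_sets), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Signed volumes of all elements
#'
#' Signed volume of each tet4 element, det of the edge matrix / 6, in mm^3.
#' All positive for an orientation-normalised mesh.
#'
#' @param mesh a `tet_mesh`.
#' @return numeric vector, one signed volume per element.
#' @export
tet_signed_volumes <- function(mesh) {
  el <- mesh$elements
  p1 <- mesh$nodes[el[, 1L], , drop = FALSE]
  a <- mesh$nodes[el[, 2L], , drop = FALSE] - p1
  b <- mesh$nodes[el[, 3L], , drop = FALSE] - p1
  c <- mesh$nodes[el[, 4L], , drop = FALSE] - p1
  # triple product a . (b x c), vectorised over elements
  (a[, 1L] * (b[, 2L] * c[, 3L] - b[, 3L] * c[, 2L]) +
   a[, 2L] * (b[, 3L] * c[, 1L] - b[, 1L] * c[, 3L]) +
   a[, 3L] * (b[, 1L] * c[, 2L] - b[, 2L] * c[, 1L])) / 6
}

#' Total mesh volume
#'
#' Sum of absolute signed tet volumes, mm^3. Strain energy scales with
#' volume for geometrically similar models, so this is the normaliser used
#' by the strain-energy size correction.
#'
#' @param mesh a `tet_mesh`.
#' @return total volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  if (nrow(mesh$elements) == 0L) stop("empty mesh has no volume")
  sum(abs(tet_signed_volumes(mesh)))
}

# The 4 faces of a tet, as rows of local node positions. Ordering gives
# outward-facing triangles for a positively oriented tet.
.tet_face_local <- rbind(c(1L, 3L, 2L), c(1L, 2L, 4L),
                         c(2L, 3L, 4L), c(1L, 4L, 3L))

# All element faces as a (4*ne) x 3 matrix of node indices plus owning element.
.all_faces <- function(mesh) {
  el <- mesh$elements
  ne <- nrow(el)
  faces <- rbind(el[, .tet_face_local[1L, ], drop = FALSE],
                 el[, .tet_face_local[2L, ], drop = FALSE],
                 el[, .tet_face_local[3L, ], drop = FALSE],
                 el[, .tet_face_local[4L, ], drop = FALSE])
  list(faces = faces, owner = rep.int(seq_len(ne), 4L))
}

# Key uniquely identifying an unordered face. Node counts here are far below
# the 2^53 double-precision integer limit for the cubic encoding.
.face_keys <- function(faces, n_nodes) {
  x <- as.numeric(faces[, 1L]); y <- as.numeric(faces[, 2L])
  z <- as.numeric(faces[, 3L])
  s1 <- pmin(x, y, z)
  s3 <- pmax(x, y, z)
  s2 <- x + y + z - s1 - s3
  (s1 * (n_nodes + 1) + s2) * (n_nodes + 1) + s3
}

#' Boundary surface triangles
#'
#' Triangular faces owned by exactly one element (the free boundary),
#' computed from face incidence rather than stored, so the surface can never
#' fall out of sync with the volume mesh.
#'
#' @param mesh a `tet_mesh`.
#' @return integer matrix of boundary triangles, 3 node indices per row,
#'   wound outward for an orientation-normalised mesh.
#' @export
boundary_triangles <- function(mesh) {
  if (nrow(mesh$elements) == 0L) stop("empty mesh has no boundary")
  af <- .all_faces(mesh)
  keys <- .face_keys(af$faces, nrow(mesh$nodes))
  single <- !(duplicated(keys) | duplicated(keys, fromLast = TRUE))
  af$faces[single, , drop = FALSE]
}

.triangle_areas <- function(nodes, tris) {
  a <- nodes[tris[, 2L], , drop = FALSE] - nodes[tris[, 1L], , drop = FALSE]
  b <- nodes[tris[, 3L], , drop = FALSE] - nodes[tris[, 1L], , drop = FALSE]
  cx <- a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L]
  cy <- a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L]
  cz <- a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Boundary surface area
#'
#' Sum of boundary-triangle areas in mm^2. This is the quantity the
#' comparative bending protocol scales loads by, so that stress (which
#' scales with area) is size-independent across models. By default every
#' boundary face counts, including internal cavity walls (pneumatic
#' spaces); `outer_only = TRUE` restricts to the outermost shell (the
#' boundary component containing the extremal vertex).
#'
#' @param mesh a `tet_mesh`.
#' @param outer_only count only the outermost boundary shell.
#' @return surface area in mm^2.
#' @export
surface_area <- function(mesh, outer_only = FALSE) {
  tris <- boundary_triangles(mesh)
  if (outer_only) {
    comp <- .triangle_components(tris, nrow(mesh$nodes))
    top_node <- which.max(mesh$nodes[, 3L] + mesh$nodes[, 1L])
    # shell containing the extremal vertex; fall back to the largest shell
    hit <- comp[apply(tris == top_node, 1L, any)]
    keep_comp <- if (length(hit)) hit[1L] else
      as.integer(names(which.max(table(comp))))
    tris <- tris[comp == keep_comp, , drop = FALSE]
  }
  sum(.triangle_areas(mesh$nodes, tris))
}

# Connected components of boundary triangles under shared-edge adjacency
# (union-find over triangle indices).
.triangle_components <- function(tris, n_nodes) {
  nt <- nrow(tris)
  parent <- seq_len(nt)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  edges <- rbind(tris[, c(1L, 2L)], tris[, c(2L, 3L)], tris[, c(3L, 1L)])
  lo <- pmin(edges[, 1L], edges[, 2L])
  hi <- pmax(edges[, 1L], edges[, 2L])
  key <- lo * (n_nodes + 1) + hi
  tri_of <- rep.int(seq_len(nt), 3L)
  for (grp in split(tri_of, key)) {
    if (length(grp) > 1L) {
      r <- find(grp[1L])
      for (t in grp[-1L]) {
        r2 <- find(t)
        if (r2 != r) parent[r2] <- r
      }
    }
  }
  vapply(seq_len(nt), find, integer(1))
}

#' Scale a mesh uniformly about its centroid
#'
#' Multiplies node coordinates by `s` about the mean node position.
#' Connectivity, materials, and all named sets are unchanged, so scaled
#' copies form a geometrically similar family sharing landmark sets.
#'
#' @param mesh a `tet_mesh`.
#' @param s positive scale factor.
#' @return the scaled `tet_mesh`.
#' @export
scale_mesh <- function(mesh, s) {
  if (!is.numeric(s) || length(s) != 1L || !is.finite(s) || s <= 0) {
    stop("scale factor must be a single positive number")
  }
  ctr <- colMeans(mesh$nodes)
  mesh$nodes <- sweep(sweep(mesh$nodes, 2L, ctr, "-") * s, 2L, ctr, "+")
  mesh
}

#' Validate a tetrahedral mesh
#'
#' Reports the defects that would invalidate a finite-element solve:
#' inverted (negative-volume) elements, degenerate (zero-volume) elements,
#' unreferenced nodes, non-manifold boundary edges (boundary edges shared by
#' a number of boundary triangles other than two), and node/element sets
#' referencing invalid indices. Degenerate tets are a failure, never
#' silently dropped: dropping them would change the stiffness.
#'
#' @param mesh a `tet_mesh`.
#' @return a list of class `mesh_validation` with counts per defect class
#'   and a logical `pass`.
#' @export
validate_mesh <- function(mesh) {
  v <- tet_signed_volumes(mesh)
  vol_tol <- 1e-12 * max(abs(v), 1e-300)
  inverted <- which(v < -vol_tol)
  degenerate <- which(abs(v) <= vol_tol)
  referenced <- unique(as.vector(mesh$elements))
  unreferenced <- setdiff(seq_len(nrow(mesh$nodes)), referenced)

  tris <- boundary_triangles(mesh)
  edges <- rbind(tris[, c(1L, 2L)], tris[, c(2L, 3L)], tris[, c(3L, 1L)])
  lo <- pmin(edges[, 1L], edges[, 2L])
  hi <- pmax(edges[, 1L], edges[, 2L])
  ekey <- lo * (nrow(mesh$nodes) + 1) + hi
  ecnt <- table(ekey)
  nonmanifold_edges <- sum(ecnt != 2L)

  dangling <- character(0)  # sets checked at construction; re-check defensively
  for (nm in names(mesh$node_sets)) {
    idx <- mesh$node_sets[[nm]]
    if (length(idx) && (min(idx) < 1L || max(idx) > nrow(mesh$nodes))) {
      dangling <- c(dangling, nm)
    }
  }
  report <- list(
    n_nodes = nrow(mesh$nodes), n_elements = nrow(mesh$elements),
    inverted_elements = inverted, degenerate_elements = degenerate,
    unreferenced_nodes = unreferenced,
    nonmanifold_edges = nonmanifold_edges,
    dangling_sets = dangling)
  report$pass <- length(inverted) == 0L && length(degenerate) == 0L &&
    length(unreferenced) == 0L && nonmanifold_edges == 0L &&
    length(dangling) == 0L
  class(report) <- "mesh_validation"
  report
}

#' @export
print.mesh_validation <- function(x, ...) {
  cat("mesh validation:", if (x$pass) "PASS" else "FAIL", "\n")
  cat("  nodes:", x$n_nodes, " elements:", x$n_elements, "\n")
  cat("  inverted elements:", length(x$inverted_elements),
      " degenerate:", length(x$degenerate_elements), "\n")
  cat("  unreferenced nodes:", length(x$unreferenced_nodes),
      " non-manifold boundary edges:", x$nonmanifold_edges, "\n")
  if (length(x$dangling_sets)) {
    cat("  dangling sets:", paste(x$dangling_sets, collapse = ", "), "\n")
  }
  invisible(x)
}
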