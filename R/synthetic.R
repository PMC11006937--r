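# Kuhn decomposition of a grid cell into 6 tets: one tet per monotone
# corner-to-corner path, i.e. per permutation of the three axes. `mirror_x`
# flips the decomposition about the cell's local x midplane, which keeps a
# bilaterally symmetric mesh exactly mirror-symmetric element-by-element.
.kuhn_tets <- function(mirror_x = FALSE) {
  perms <- list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  lapply(perms, function(p) {
    bits <- matrix(0L, 4L, 3L)
    bits[2L, p[1L]] <- 1L
    bits[3L, p[1L]] <- 1L; bits[3L, p[2L]] <- 1L
    bits[4L, ] <- 1L
    if (mirror_x) bits[, 1L] <- 1L - bits[, 1L]
    bits
  })
}

# Structured-grid tetrahedralisation over nx x ny x nz cells. `mirror_from`
# (an x cell index, 0-based) switches cells at or beyond it to the mirrored
# Kuhn split so the left and right halves are exact mirror images, with
# element (cell, k) on the right the mirror partner of (mirrored cell, k).
.grid_tets <- function(nx, ny, nz, mirror_from = NA_integer_) {
  gid <- function(ix, iy, iz) 1L + ix + (nx + 1L) * (iy + (ny + 1L) * iz)
  std <- .kuhn_tets(FALSE)
  mir <- .kuhn_tets(TRUE)
  elements <- matrix(0L, 6L * nx * ny * nz, 4L)
  e <- 0L
  for (iz in 0:(nz - 1L)) for (iy in 0:(ny - 1L)) for (ix in 0:(nx - 1L)) {
    tets <- if (!is.na(mirror_from) && ix >= mirror_from) mir else std
    for (k in 1:6) {
      b <- tets[[k]]
      elements[e + k, ] <- gid(ix + b[, 1L], iy + b[, 2L], iz + b[, 3L])
    }
    e <- e + 6L
  }
  elements
}

#' Structured cantilever beam mesh
#'
#' A box of dimensions `L x W x H` mm meshed as `nx x ny x nz` grid cells,
#' each split into 6 consistently oriented tets. The beam runs along x with
#' node sets `fixed_end` (all nodes at x = 0) and `free_end_tip` (all nodes
#' at x = L); with slender proportions it has the analytic Euler-Bernoulli
#' tip deflection P L^3 / (3 E I) used for solver validation.
#'
#' @param L,W,H beam length, width, height in mm.
#' @param nx,ny,nz cell counts per axis.
#' @return a `tet_mesh` with `6 * nx * ny * nz` elements.
#' @export
make_beam <- function(L, W, H, nx, ny, nz) {
  dims <- c(L, W, H); counts <- c(nx, ny, nz)
  if (any(!is.finite(dims)) || any(dims <= 0)) {
    stop("beam dimensions must be positive")
  }
  if (any(counts < 1L) || any(counts != round(counts))) {
    stop("cell counts must be positive integers")
  }
  xs <- seq(0, L, length.out = nx + 1L)
  ys <- seq(0, W, length.out = ny + 1L)
  zs <- seq(0, H, length.out = nz + 1L)
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  dimnames(nodes) <- NULL
  elements <- .grid_tets(nx, ny, nz)
  fixed <- which(nodes[, 1L] == 0)
  tip <- which(nodes[, 1L] == L)
  tet_mesh(nodes, elements,
           node_sets = list(fixed_end = fixed, free_end_tip = tip))
}

#' Toy-skull specification
#'
#' Parameters of the synthetic bilaterally symmetric "toy skull": a
#' rostrally tapering box carrying every landmark node set the load
#' protocols expect. Dimensions default to a small oviraptorid-like cranium
#' (60 mm long, 30 mm wide, 24 mm tall) with 50% rostral narrowing.
#'
#' @param length anteroposterior extent, mm (anterior at +y).
#' @param width mediolateral extent at the occiput, mm (midline at x = 0).
#' @param height dorsoventral extent, mm (ventral at z = 0).
#' @param taper fraction of width lost at the rostral tip, in [0, 0.9].
#' @param resolution grid cells per axis, `c(nx, ny, nz)`; `nx` must be
#'   even (so the midsagittal plane is a node plane) and at least 6, `ny`
#'   at least 6, `nz` at least 4 — coarser grids cannot furnish the
#'   required landmark set sizes.
#' @param seed integer seed for the optional node jitter.
#' @param jitter standard deviation of interior-node perturbation as a
#'   fraction of cell size (0 = exactly mirror-symmetric mesh).
#' @param regions list of toggles: `beak` and `tooth` element sets,
#'   `fenestra` (delete an interior block, producing an internal cavity /
#'   non-convex topology).
#' @return an object of class `toy_skull_spec`.
#' @export
toy_skull_spec <- function(length = 60, width = 30, height = 24,
                           taper = 0.5, resolution = c(8L, 12L, 6L),
                           seed = 1L, jitter = 0,
                           regions = list(beak = TRUE, tooth = TRUE,
                                          fenestra = FALSE)) {
  if (length <= 0 || width <= 0 || height <= 0) {
    stop("toy-skull dimensions must be positive")
  }
  if (taper < 0 || taper > 0.9) stop("taper must be in [0, 0.9]")
  resolution <- as.integer(rep_len(resolution, 3L))
  structure(list(length = length, width = width, height = height,
                 taper = taper, resolution = resolution,
                 seed = as.integer(seed), jitter = jitter,
                 regions = utils::modifyList(
                   list(beak = TRUE, tooth = TRUE, fenestra = FALSE),
                   regions)),
            class = "toy_skull_spec")
}

# Remove elements and prune nodes left unreferenced, remapping all sets.
.drop_elements <- function(mesh, drop_idx) {
  keep_e <- setdiff(seq_len(nrow(mesh$elements)), drop_idx)
  elements <- mesh$elements[keep_e, , drop = FALSE]
  keep_n <- sort(unique(as.vector(elements)))
  node_map <- integer(nrow(mesh$nodes))
  node_map[keep_n] <- seq_along(keep_n)
  elements <- matrix(node_map[elements], ncol = 4L)
  e_map <- integer(nrow(mesh$elements))
  e_map[keep_e] <- seq_along(keep_e)
  node_sets <- lapply(mesh$node_sets, function(s) {
    s <- node_map[intersect(s, keep_n)]
    s[s > 0L]
  })
  element_sets <- lapply(mesh$element_sets, function(s) {
    s <- e_map[intersect(s, keep_e)]
    s[s > 0L]
  })
  tet_mesh(mesh$nodes[keep_n, , drop = FALSE], elements,
           element_material = mesh$element_material[keep_e],
           node_sets = node_sets, element_sets = element_sets,
           normalize_orientation = FALSE)
}

#' Generate the toy-skull mesh
#'
#' A rostrally tapering box standing in for a cranium, with the landmark
#' node sets every scenario builder needs: `palate_{anterior,mid,posterior}_{L,R}`
#' on the ventral surface (anterior at the rostral tip, mid on the lateral
#' palate margin, posterior at the caudal palate), `quadrate_{L,R}` (4
#' posteroventral nodes each, the jaw-joint constraint patches), `occipital`
#' (3 caudal midline nodes), jaw-adductor origin patches
#' `m_AME_origin_{L,R}` and `m_AMP_origin_{L,R}` (8 dorsotemporal /
#' laterotemporal nodes each), and `beak_tip_{L,R}` for extrinsic loading.
#' Optional `beak` and `tooth` element sets mark the rostral regions used
#' by rhamphotheca overlays. With `jitter = 0` the mesh, its sets and its
#' element decomposition are exactly mirror-symmetric about x = 0.
#'
#' @param spec a `toy_skull_spec`.
#' @return a `tet_mesh` passing [validate_mesh()] and every scenario
#'   builder's preconditions.
#' @export
make_toy_skull <- function(spec = toy_skull_spec()) {
  stopifnot(inherits(spec, "toy_skull_spec"))
  res <- spec$resolution
  nx <- res[1L]; ny <- res[2L]; nz <- res[3L]
  if (nx < 6L || nx %% 2L != 0L || ny < 6L || nz < 4L) {
    stop("resolution too coarse: need even nx >= 6, ny >= 6, nz >= 4 ",
         "to furnish the required landmark node sets")
  }
  gid <- function(ix, iy, iz) 1L + ix + (nx + 1L) * (iy + (ny + 1L) * iz)
  grid <- expand.grid(ix = 0:nx, iy = 0:ny, iz = 0:nz)
  yfrac <- grid$iy / ny
  wfac <- 1 - spec$taper * yfrac           # rostral narrowing
  nodes <- cbind(
    x = (grid$ix / nx - 0.5) * spec$width * wfac,
    y = yfrac * spec$length,
    z = grid$iz / nz * spec$height)
  dimnames(nodes) <- NULL
  if (spec$jitter > 0) {
    set.seed(spec$seed)
    interior <- grid$ix > 0 & grid$ix < nx & grid$iy > 0 & grid$iy < ny &
      grid$iz > 0 & grid$iz < nz
    h <- c(spec$width / nx, spec$length / ny, spec$height / nz)
    nodes[interior, ] <- nodes[interior, ] +
      matrix(stats::rnorm(3L * sum(interior), sd = spec$jitter), ncol = 3L) %*%
      diag(h)
  }
  elements <- .grid_tets(nx, ny, nz, mirror_from = nx %/% 2L)

  half <- nx %/% 2L
  mirror_ix <- function(ix) nx - ix
  set_from <- function(ixs, iys, izs) {
    g <- expand.grid(ix = ixs, iy = iys, iz = izs)
    gid(g$ix, g$iy, g$iz)
  }
  lr <- function(ixs, iys, izs) {
    list(L = set_from(ixs, iys, izs),
         R = set_from(mirror_ix(ixs), iys, izs))
  }
  pal_ant <- lr(c(half - 2L, half - 1L), ny, 0L)
  pal_mid <- lr(c(0L, 1L), ny %/% 2L, 0L)
  pal_pos <- lr(c(half - 2L, half - 1L), ny %/% 4L, 0L)
  quad <- lr(c(0L, 1L), 0L, c(0L, 1L))
  occ_mid <- nz %/% 2L
  occipital <- set_from(half, 0L, (occ_mid - 1L):(occ_mid + 1L))
  ame <- lr(c(0L, 1L), 1:4, nz)
  amp <- lr(0L, 1:4, c(nz - 2L, nz - 1L))
  beak_tip <- lr(c(half - 2L, half - 1L), ny, c(0L, 1L))

  node_sets <- list(
    palate_anterior_L = pal_ant$L, palate_anterior_R = pal_ant$R,
    palate_mid_L = pal_mid$L, palate_mid_R = pal_mid$R,
    palate_posterior_L = pal_pos$L, palate_posterior_R = pal_pos$R,
    quadrate_L = quad$L, quadrate_R = quad$R,
    occipital = occipital,
    m_AME_origin_L = ame$L, m_AME_origin_R = ame$R,
    m_AMP_origin_L = amp$L, m_AMP_origin_R = amp$R,
    beak_tip_L = beak_tip$L, beak_tip_R = beak_tip$R)

  mesh <- tet_mesh(nodes, elements, node_sets = node_sets)

  cent <- (mesh$nodes[mesh$elements[, 1L], ] +
           mesh$nodes[mesh$elements[, 2L], ] +
           mesh$nodes[mesh$elements[, 3L], ] +
           mesh$nodes[mesh$elements[, 4L], ]) / 4
  if (isTRUE(spec$regions$beak)) {
    mesh$element_sets$beak <- which(cent[, 2L] > 0.75 * spec$length)
  }
  if (isTRUE(spec$regions$tooth)) {
    mesh$element_sets$tooth <- which(cent[, 2L] > 0.6 * spec$length &
                                     cent[, 3L] < spec$height / 3)
  }
  if (isTRUE(spec$regions$fenestra)) {
    # interior cavity: a pneumatisation stand-in giving non-convex topology
    drop <- which(cent[, 1L] > -0.2 * spec$width &
                  cent[, 1L] <  0.2 * spec$width &
                  cent[, 2L] > 0.35 * spec$length &
                  cent[, 2L] < 0.55 * spec$length &
                  cent[, 3L] > 0.4 * spec$height &
                  cent[, 3L] < 0.7 * spec$height)
    if (length(drop)) mesh <- .drop_elements(mesh, drop)
  }
  mesh
}

#' Geometrically similar family of meshes
#'
#' Scaled copies of one base mesh ([scale_mesh()] about the centroid), all
#' sharing connectivity and landmark sets: the substrate for the
#' size-independence tests of the area-scaled bending protocol.
#'
#' @param base a `tet_mesh` or a `toy_skull_spec` (generated first).
#' @param scales numeric vector of positive scale factors.
#' @return list of `tet_mesh`, one per scale, named by the scale.
#' @export
make_similar_family <- function(base, scales) {
  if (inherits(base, "toy_skull_spec")) base <- make_toy_skull(base)
  stopifnot(inherits(base, "tet_mesh"))
  if (length(scales) == 0L) stop("at least one scale factor is required")
  if (any(scales <= 0)) stop("scale factors must be positive")
  out <- lapply(scales, function(s) scale_mesh(base, s))
  names(out) <- as.character(scales)
  out
}

#' Default toy-muscle table for the toy skull
#'
#' A plausible bilateral jaw-adductor arrangement for the synthetic
#' cranium: two muscles per side (external and posterior adductor
#' analogues) originating on the temporal patches and inserting at a
#' mandible-like point below and behind the palate. Forces are arbitrary
#' but realistic for a small cranium; they exist so that bite scenarios on
#' synthetic geometry are fully specified out of the box.
#'
#' @param spec the `toy_skull_spec` the mesh was generated from (for
#'   dimensions).
#' @param force_per_muscle total contraction force per muscle per side, N.
#' @return list of `muscle_load` objects (2 muscles x 2 sides).
#' @export
toy_muscles <- function(spec = toy_skull_spec(), force_per_muscle = 40) {
  ins <- function(side) {
    sx <- if (side == "L") -1 else 1
    c(sx * spec$width * 0.25, spec$length * 0.25, -spec$height * 0.5)
  }
  out <- list()
  for (side in c("L", "R")) {
    out[[paste0("mAME_", side)]] <- muscle_load(
      "mAME", side, paste0("m_AME_origin_", side), ins(side),
      force_per_muscle)
    out[[paste0("mAMP_", side)]] <- muscle_load(
      "mAMP", side, paste0("m_AMP_origin_", side), ins(side),
      force_per_muscle)
  }
  out
}
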