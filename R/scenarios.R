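# Deterministic pick of k set members: the k nearest the set centroid,
# ties broken by node index. The comparative protocols fix the number of
# loaded/constrained nodes (8 per muscle origin, 4 per quadrate patch, 3 on
# the occipital condyle), so the pick must be reproducible.
.pick_nearest_centroid <- function(mesh, set_name, k) {
  idx <- mesh$node_sets[[set_name]]
  if (is.null(idx)) stop("mesh has no node set '", set_name, "'")
  if (length(idx) < k) {
    stop("node set '", set_name, "' has ", length(idx),
         " nodes; ", k, " required")
  }
  pts <- mesh$nodes[idx, , drop = FALSE]
  ctr <- colMeans(pts)
  d <- sqrt(rowSums(sweep(pts, 2L, ctr, "-")^2))
  idx[order(d, idx)][seq_len(k)]
}

# The standard posterior constraint block of every cranial protocol:
# 4 nodes on each quadrate articular surface and 3 on the occipital
# condyle, all fully constrained.
.posterior_constraints <- function(mesh) {
  nodes <- c(.pick_nearest_centroid(mesh, "quadrate_L", 4L),
             .pick_nearest_centroid(mesh, "quadrate_R", 4L),
             .pick_nearest_centroid(mesh, "occipital", 3L))
  data.frame(node = nodes, x = TRUE, y = TRUE, z = TRUE)
}

.new_scenario <- function(name, lc, position, laterality, kind,
                          total_applied_force, bite_nodes = integer(0)) {
  structure(list(name = name, load_case = lc, position = position,
                 laterality = laterality, kind = kind,
                 total_applied_force = total_applied_force,
                 bite_nodes = bite_nodes),
            class = "fea_scenario")
}

#' @export
print.fea_scenario <- function(x, ...) {
  cat("fea_scenario '", x$name, "': kind=", x$kind,
      " position=", x$position, " laterality=", x$laterality,
      " total |F| = ", format(x$total_applied_force), " N\n", sep = "")
  invisible(x)
}

#' Surface-area-scaled bending forces
#'
#' The comparative bending protocol removes size effects by scaling the
#' applied load with cranial surface area (stress scales with area): the
#' smallest cranium receives `base_force` (100 N by default, an arbitrary
#' but realistic bite-like load) and every other model receives
#' `base_force * A_i / A_min`, so all models experience the same relative
#' load.
#'
#' @param models list of `tet_mesh`.
#' @param base_force force on the smallest-area model, N.
#' @return numeric vector of per-model forces, N (named like `models`).
#' @export
scaled_bending_forces <- function(models, base_force = 100) {
  if (length(models) == 0L) stop("at least one model is required")
  areas <- vapply(models, surface_area, numeric(1))
  if (any(areas <= 0)) stop("all model surface areas must be positive")
  stats::setNames(base_force * areas / min(areas), names(models))
}

.palate_sets <- function(position, laterality) {
  position <- match.arg(position, c("anterior", "mid", "posterior"))
  laterality <- match.arg(laterality, c("bilateral", "unilateral_left"))
  sides <- if (laterality == "bilateral") c("L", "R") else "L"
  list(position = position, laterality = laterality,
       sets = paste0("palate_", position, "_", sides))
}

#' Build a comparative bending scenario
#'
#' Extrinsic loads perpendicular to the palate (+z, dorsally, with the
#' cranium in standard orientation), split equally over the palate nodes of
#' the chosen position — both sides if bilateral, left only if unilateral —
#' and summing to `total_force`. Constraints: 4 fully constrained nodes per
#' quadrate articular patch plus 3 on the occipital condyle.
#'
#' @param mesh a `tet_mesh` with the palate/quadrate/occipital node sets.
#' @param position `"anterior"`, `"mid"`, or `"posterior"` palate position.
#' @param laterality `"bilateral"` or `"unilateral_left"`.
#' @param total_force total applied force, N.
#' @return an `fea_scenario` of kind `"bending"`.
#' @export
build_bending_scenario <- function(mesh, position, laterality, total_force) {
  ps <- .palate_sets(position, laterality)
  load_nodes <- integer(0)
  for (s in ps$sets) {
    if (is.null(mesh$node_sets[[s]])) stop("mesh has no node set '", s, "'")
    if (length(mesh$node_sets[[s]]) == 0L) stop("node set '", s, "' is empty")
    load_nodes <- c(load_nodes, mesh$node_sets[[s]])
  }
  per_node <- total_force / length(load_nodes)
  pl <- data.frame(node = load_nodes, fx = 0, fy = 0, fz = per_node)
  lc <- load_case(pl, .posterior_constraints(mesh), nrow(mesh$nodes))
  .new_scenario(paste("bending", ps$position, ps$laterality, sep = "_"),
                lc, ps$position, ps$laterality, "bending", total_force)
}

#' Jaw-adductor muscle load
#'
#' One reconstructed jaw adductor on one side: its total contraction force
#' is divided across eight nodes of its origin node set, each nodal force
#' directed from the origin node toward the muscle's insertion point (a
#' point on the mandible, supplied — not computed — because force vectors
#' are inherited from volumetric muscle reconstructions).
#'
#' @param name muscle label (e.g. `"mAME"`).
#' @param side `"L"` or `"R"`.
#' @param origin_set name of the origin node set (at least 8 nodes).
#' @param insertion_point length-3 coordinate, mm.
#' @param force total contraction force, N (non-negative).
#' @return an object of class `muscle_load`.
#' @export
muscle_load <- function(name, side, origin_set, insertion_point, force) {
  side <- match.arg(side, c("L", "R"))
  insertion_point <- as.numeric(insertion_point)
  if (length(insertion_point) != 3L || any(!is.finite(insertion_point))) {
    stop("insertion_point must be a finite length-3 coordinate")
  }
  if (!is.finite(force) || force < 0) stop("muscle force must be >= 0")
  structure(list(name = name, side = side, origin_set = origin_set,
                 insertion_point = insertion_point, force = force),
            class = "muscle_load")
}

#' Nodal loads of one muscle
#'
#' Selects exactly 8 origin nodes (deterministically: the 8 set members
#' nearest the set centroid, ties by node index) and assigns each a force
#' of magnitude `force / 8` directed from the node toward the insertion
#' point, so the per-muscle magnitude sum equals the contraction force.
#'
#' @param muscle a `muscle_load`.
#' @param mesh a `tet_mesh` containing the origin set.
#' @return data frame with columns `node`, `fx`, `fy`, `fz`.
#' @export
muscle_nodal_loads <- function(muscle, mesh) {
  stopifnot(inherits(muscle, "muscle_load"))
  nodes <- .pick_nearest_centroid(mesh, muscle$origin_set, 8L)
  dirs <- sweep(-mesh$nodes[nodes, , drop = FALSE], 2L,
                muscle$insertion_point, "+")
  lens <- sqrt(rowSums(dirs^2))
  if (any(lens < 1e-12)) {
    stop("muscle '", muscle$name, "' (", muscle$side, "): an origin node ",
         "coincides with the insertion point (zero-length line of action)")
  }
  dirs <- dirs / lens
  mag <- muscle$force / 8
  data.frame(node = nodes, fx = mag * dirs[, 1L],
             fy = mag * dirs[, 2L], fz = mag * dirs[, 3L])
}

#' Build a muscle-driven bite scenario
#'
#' Loads are the union of all muscles' nodal loads (8 nodes per muscle per
#' side). Constraints: the standard posterior block (4 nodes per quadrate,
#' all axes; 3 occipital nodes, all axes) plus the bite-point constraints —
#' one node (unilateral, left) or two nodes (bilateral) on the chosen
#' palate position, constrained in the vertical (z) axis only. The vertical
#' reaction at the bite nodes is the modelled bite force
#' ([bite_reaction()]).
#'
#' @param mesh a `tet_mesh` with palate, quadrate, occipital and muscle
#'   origin sets.
#' @param muscles list of `muscle_load` (both sides).
#' @param position `"anterior"`, `"mid"`, or `"posterior"`.
#' @param laterality `"bilateral"` or `"unilateral_left"`.
#' @return an `fea_scenario` of kind `"bite"`.
#' @export
build_bite_scenario <- function(mesh, muscles, position, laterality) {
  ps <- .palate_sets(position, laterality)
  loads <- lapply(muscles, muscle_nodal_loads, mesh = mesh)
  pl <- if (length(loads)) do.call(rbind, loads) else
    data.frame(node = integer(0), fx = numeric(0), fy = numeric(0),
               fz = numeric(0))
  bite_nodes <- vapply(ps$sets, function(s) {
    .pick_nearest_centroid(mesh, s, 1L)
  }, integer(1))
  cons <- rbind(
    .posterior_constraints(mesh),
    data.frame(node = bite_nodes, x = FALSE, y = FALSE, z = TRUE))
  lc <- load_case(pl, cons, nrow(mesh$nodes))
  total <- sum(vapply(muscles, function(m) m$force, numeric(1)))
  .new_scenario(paste("bite", ps$position, ps$laterality, sep = "_"),
                lc, ps$position, ps$laterality, "bite", total,
                bite_nodes = unname(bite_nodes))
}

#' Bite-point reaction force
#'
#' The magnitude of the vertical (z) reaction summed over the bite-point
#' constrained nodes: the bite force the muscle-loaded cranium transmits at
#' the bite point.
#'
#' @param solution a `fem_solution` of a bite scenario.
#' @param scenario the `fea_scenario` it solved (kind `"bite"`).
#' @return bite reaction magnitude, N.
#' @export
bite_reaction <- function(solution, scenario) {
  stopifnot(inherits(scenario, "fea_scenario"))
  if (scenario$kind != "bite") {
    stop("bite_reaction requires a scenario of kind 'bite', got '",
         scenario$kind, "'")
  }
  r <- solution$reactions
  abs(sum(r$rz[r$node %in% scenario$bite_nodes]))
}

#' Build an extrinsic head-movement scenario
#'
#' Head-pull: posteriorly directed (-y) loads at the beak-tip nodes.
#' Head-shake: lateral (+x) loads at the beak-tip nodes. Head-twist: equal
#' and opposite vertical (z) loads on the left versus right beak-tip node
#' groups — a pure torsion couple, each side summing in magnitude to
#' `total_force` (so the net applied force vector is zero). Constraints are
#' the bending test's posterior block.
#'
#' @param mesh a `tet_mesh` with `beak_tip_L`/`beak_tip_R` sets.
#' @param kind `"pull"`, `"shake"`, or `"twist"`.
#' @param total_force force magnitude, N (per side for twist).
#' @return an `fea_scenario`.
#' @export
build_extrinsic_scenario <- function(mesh, kind = c("pull", "shake", "twist"),
                                     total_force) {
  kind <- match.arg(kind)
  for (s in c("beak_tip_L", "beak_tip_R")) {
    if (is.null(mesh$node_sets[[s]])) stop("mesh has no node set '", s, "'")
  }
  left <- mesh$node_sets$beak_tip_L
  right <- mesh$node_sets$beak_tip_R
  if (kind == "twist") {
    per_l <- total_force / length(left)
    per_r <- total_force / length(right)
    pl <- rbind(
      data.frame(node = left, fx = 0, fy = 0, fz = per_l),
      data.frame(node = right, fx = 0, fy = 0, fz = -per_r))
    total <- 2 * total_force
  } else {
    nodes <- c(left, right)
    per <- total_force / length(nodes)
    pl <- if (kind == "pull") {
      data.frame(node = nodes, fx = 0, fy = -per, fz = 0)
    } else {
      data.frame(node = nodes, fx = per, fy = 0, fz = 0)
    }
    total <- total_force
  }
  lc <- load_case(pl, .posterior_constraints(mesh), nrow(mesh$nodes))
  .new_scenario(paste0("extrinsic_", kind), lc, "none", "bilateral",
                kind, total)
}

#' Overlay a keratinous rhamphotheca
#'
#' Re-labels the elements of a beak region to a keratin material, geometry
#' unchanged — the standard way a keratinous beak sheath is represented in
#' cranial finite-element models. Supply the keratin `fem_material` in the
#' materials list when solving.
#'
#' @param mesh a `tet_mesh`.
#' @param region element indices, or the name of an element set (e.g.
#'   `"beak"`).
#' @param keratin a `fem_material` for the sheath.
#' @return a mesh copy with the region's `element_material` set to
#'   `keratin$name`.
#' @export
apply_rhamphotheca <- function(mesh, region, keratin) {
  stopifnot(inherits(keratin, "fem_material"))
  if (is.character(region) && length(region) == 1L) {
    idx <- mesh$element_sets[[region]]
    if (is.null(idx)) stop("mesh has no element set '", region, "'")
  } else {
    idx <- as.integer(region)
  }
  if (length(idx) == 0L) stop("rhamphotheca region covers no elements")
  if (min(idx) < 1L || max(idx) > nrow(mesh$elements)) {
    stop("rhamphotheca region references invalid element indices")
  }
  mesh$element_material[idx] <- keratin$name
  mesh
}
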