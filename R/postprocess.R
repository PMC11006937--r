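#' Exclude the top fraction of a stress multiset
#'
#' Point loads and constraints on small elements produce artificially high
#' local stresses; to make mean and peak stress useful comparative metrics
#' the top 5% of element-nodal von Mises values are excluded before
#' summarising. Exactly `floor(trim_fraction * n)` of the largest values
#' are removed (ties at the cut resolved by removing exactly that count),
#' so the retained count is `ceiling((1 - trim_fraction) * n)` and never
#' less than the stated fraction.
#'
#' @param values non-empty numeric multiset (MPa).
#' @param trim_fraction fraction to remove from the top, in [0, 1).
#' @return the retained values, sorted ascending.
#' @export
trim_top <- function(values, trim_fraction = 0.05) {
  if (length(values) == 0L) stop("cannot trim an empty multiset")
  if (!is.numeric(trim_fraction) || trim_fraction < 0 || trim_fraction >= 1) {
    stop("trim_fraction must be in [0, 1)")
  }
  n <- length(values)
  k <- floor(trim_fraction * n)
  s <- sort(values)
  if (k > 0L) s[seq_len(n - k)] else s
}

#' Comparative summary statistics of a solved scenario
#'
#' Trimmed mean, quartiles (linear interpolation between order statistics,
#' `stats::quantile` type 7) and peak (maximum of the retained values) of
#' the element-nodal von Mises multiset, plus raw and volume-corrected
#' total strain energy. The correction multiplies U by `v_ref / volume`:
#' with loads pre-scaled by surface area, strain energy scales with volume
#' for geometrically similar shapes, so this is the factor that makes U
#' comparable across sizes.
#'
#' @param solution a `fem_solution`.
#' @param mesh the `tet_mesh` it was solved on.
#' @param v_ref reference volume, mm^3 (conventionally the smallest model
#'   volume in the comparison; defaults to the mesh's own volume, i.e. no
#'   correction).
#' @param trim_fraction top fraction excluded, default 0.05.
#' @return an object of class `fea_summary`: `mean_vm`, `q1_vm`,
#'   `median_vm`, `q3_vm`, `peak_vm` (MPa), `strain_energy_raw`,
#'   `strain_energy_corrected` (N.mm), `n_values_total`,
#'   `n_values_retained`.
#' @export
summarize_solution <- function(solution, mesh, v_ref = NULL,
                               trim_fraction = 0.05) {
  stopifnot(inherits(solution, "fem_solution"))
  vol <- mesh_volume(mesh)
  if (is.null(v_ref)) v_ref <- vol
  if (!is.finite(v_ref) || v_ref <= 0) stop("v_ref must be positive")
  vals <- solution$element_nodal_vm
  kept <- trim_top(vals, trim_fraction)
  qs <- stats::quantile(kept, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  structure(list(
    mean_vm = mean(kept),
    q1_vm = qs[1L], median_vm = qs[2L], q3_vm = qs[3L],
    peak_vm = max(kept),
    strain_energy_raw = solution$strain_energy,
    strain_energy_corrected = solution$strain_energy * (v_ref / vol),
    n_values_total = length(vals),
    n_values_retained = length(kept)), class = "fea_summary")
}

#' @export
print.fea_summary <- function(x, ...) {
  cat(sprintf(
    "fea_summary: mean %.4g | Q1 %.4g | median %.4g | Q3 %.4g | peak %.4g MPa\n",
    x$mean_vm, x$q1_vm, x$median_vm, x$q3_vm, x$peak_vm))
  cat(sprintf("  U = %.6g N.mm (corrected %.6g); %d of %d values retained\n",
              x$strain_energy_raw, x$strain_energy_corrected,
              x$n_values_retained, x$n_values_total))
  invisible(x)
}

#' Long-format comparison table of model x scenario runs
#'
#' One row per run, with the model label, scenario metadata and every
#' summary field, in deterministic order (model, then scenario name) so
#' repeated runs produce byte-identical reports. Percent changes between
#' positions (e.g. the anterior-to-posterior mean-stress increase) are
#' derivable from pairs of rows.
#'
#' @param runs list of runs, each a list with elements `model` (character),
#'   `scenario` (an `fea_scenario`), and `stats` (an `fea_summary`).
#' @return a `data.frame`.
#' @export
comparison_table <- function(runs) {
  if (length(runs) == 0L) stop("at least one run is required")
  rows <- lapply(runs, function(r) {
    sc <- r$scenario; st <- r$stats
    data.frame(
      model = r$model, scenario = sc$name, kind = sc$kind,
      position = sc$position, laterality = sc$laterality,
      total_applied_force = sc$total_applied_force,
      mean_vm = st$mean_vm, q1_vm = st$q1_vm, median_vm = st$median_vm,
      q3_vm = st$q3_vm, peak_vm = st$peak_vm,
      strain_energy_raw = st$strain_energy_raw,
      strain_energy_corrected = st$strain_energy_corrected,
      n_values_total = st$n_values_total,
      n_values_retained = st$n_values_retained,
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$model, tab$scenario), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Export a solved field for contour plotting
#'
#' Writes a legacy-ASCII VTK unstructured grid carrying the per-element von
#' Mises stress, a per-node averaged von Mises field (for smooth contours
#' only), the displacement magnitude, and point-data flags marking loaded
#' and constrained nodes.
#'
#' @param mesh a `tet_mesh`.
#' @param solution a `fem_solution` on that mesh.
#' @param path output `.vtk` path.
#' @return `path`, invisibly.
#' @export
export_contour <- function(mesh, solution, path) {
  n <- nrow(mesh$nodes)
  loaded <- numeric(n)
  lc <- solution$load_case
  loaded[unique(lc$point_loads$node)] <- 1
  constrained <- numeric(n)
  constrained[unique(lc$constraints$node)] <- 1
  write_vtk(
    mesh, path,
    cell_data = list(von_mises = solution$element_vm),
    point_data = list(
      von_mises_avg = nodal_von_mises(mesh, solution),
      displacement_magnitude = sqrt(rowSums(solution$displacements^2)),
      load_flag = loaded,
      constraint_flag = constrained))
}
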