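# Shared driver: solve a list of (model, scenario) pairs, summarise, write
# the CSV table, one VTK contour per run, and a manifest echoing the full
# configuration (which suffices to reproduce the table exactly).
.run_suite <- function(cfg, suite_name, build_runs, out_dir = NULL) {
  out_dir <- out_dir %||% cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  models <- .resolve_models(cfg)
  v_ref <- .reference_volume(cfg, models)
  pairs <- build_runs(models)
  runs <- vector("list", length(pairs))
  for (k in seq_along(pairs)) {
    p <- pairs[[k]]
    sol <- tryCatch(
      solve_fem(models[[p$model]], cfg$materials, p$scenario$load_case),
      error = function(e) {
        stop("suite '", suite_name, "', model '", p$model, "', scenario '",
             p$scenario$name, "': ", conditionMessage(e))
      })
    st <- summarize_solution(sol, models[[p$model]], v_ref = v_ref,
                             trim_fraction = cfg$trim_fraction)
    export_contour(models[[p$model]], sol,
                   file.path(out_dir, paste0(suite_name, "_", p$model, "_",
                                             p$scenario$name, ".vtk")))
    runs[[k]] <- list(model = p$model, scenario = p$scenario, stats = st)
  }
  tab <- comparison_table(runs)
  csv <- file.path(out_dir, paste0(suite_name, "_summary.csv"))
  utils::write.csv(tab, csv, row.names = FALSE)
  manifest <- list(
    suite = suite_name,
    package_version = as.character(utils::packageVersion("craniofem")),
    v_ref_mm3 = v_ref,
    config = unclass(cfg)[setdiff(names(cfg), "materials")],
    materials = lapply(cfg$materials, function(m) {
      list(E_MPa = m$E, nu = m$nu)
    }),
    outputs = basename(csv))
  yaml::write_yaml(manifest,
                   file.path(out_dir, paste0(suite_name, "_manifest.yaml")))
  invisible(tab)
}

#' Validate every configured model
#'
#' @param cfg a `run_config`.
#' @return named list of `mesh_validation` reports, one per model.
#' @export
cmd_validate <- function(cfg) {
  models <- .resolve_models(cfg)
  lapply(models, validate_mesh)
}

#' Run the comparative bending suite
#'
#' For every configured model, builds the surface-area-scaled palatal
#' bending scenarios (`base_force` on the smallest-area model, scaled by
#' area ratio for the rest) at the configured positions and lateralities,
#' solves each, and writes the comparison table, contour files, and
#' manifest.
#'
#' @param cfg a `run_config`.
#' @param out_dir output directory (default `cfg$out_dir`).
#' @return the comparison table, invisibly.
#' @export
cmd_bending_suite <- function(cfg, out_dir = NULL) {
  sc <- cfg$scenarios$bending %||% list()
  positions <- unlist(sc$positions %||% c("anterior", "mid", "posterior"))
  lateralities <- unlist(sc$lateralities %||%
                           c("bilateral", "unilateral_left"))
  .run_suite(cfg, "bending", function(models) {
    forces <- scaled_bending_forces(models, cfg$base_force)
    pairs <- list()
    for (nm in names(models)) for (pos in positions) for (lat in lateralities) {
      pairs[[length(pairs) + 1L]] <- list(
        model = nm,
        scenario = build_bending_scenario(models[[nm]], pos, lat,
                                          forces[[nm]]))
    }
    pairs
  }, out_dir)
}

#' Run the muscle-driven bite suite
#'
#' @param cfg a `run_config` with a muscle table.
#' @param out_dir output directory (default `cfg$out_dir`).
#' @return the comparison table, invisibly.
#' @export
cmd_bite_suite <- function(cfg, out_dir = NULL) {
  sc <- cfg$scenarios$bite %||% list()
  positions <- unlist(sc$positions %||% c("anterior", "mid", "posterior"))
  lateralities <- unlist(sc$lateralities %||%
                           c("bilateral", "unilateral_left"))
  muscles <- .resolve_muscles(cfg)
  if (length(muscles) == 0L) stop("bite suite requires a muscle table")
  .run_suite(cfg, "bite", function(models) {
    pairs <- list()
    for (nm in names(models)) for (pos in positions) for (lat in lateralities) {
      pairs[[length(pairs) + 1L]] <- list(
        model = nm,
        scenario = build_bite_scenario(models[[nm]], muscles, pos, lat))
    }
    pairs
  }, out_dir)
}

#' Run the extrinsic head-movement suite
#'
#' @param cfg a `run_config`; `cfg$scenarios$extrinsic$kinds` (default
#'   pull/shake/twist) and `$total_force` (default `cfg$base_force`).
#' @param out_dir output directory (default `cfg$out_dir`).
#' @return the comparison table, invisibly.
#' @export
cmd_extrinsic_suite <- function(cfg, out_dir = NULL) {
  sc <- cfg$scenarios$extrinsic %||% list()
  kinds <- unlist(sc$kinds %||% c("pull", "shake", "twist"))
  total_force <- sc$total_force %||% cfg$base_force
  .run_suite(cfg, "extrinsic", function(models) {
    pairs <- list()
    for (nm in names(models)) for (k in kinds) {
      pairs[[length(pairs) + 1L]] <- list(
        model = nm,
        scenario = build_extrinsic_scenario(models[[nm]], k, total_force))
    }
    pairs
  }, out_dir)
}

#' Merge the suite tables of a run directory
#'
#' Reads every `*_summary.csv` a suite wrote into `run_dir` and returns the
#' row-bound comparison table (suite column prepended), in deterministic
#' order.
#'
#' @param run_dir directory containing suite outputs.
#' @return a `data.frame`.
#' @export
cmd_report <- function(run_dir) {
  files <- sort(list.files(run_dir, pattern = "_summary\\.csv$",
                           full.names = TRUE))
  if (length(files) == 0L) stop("no suite summaries found in ", run_dir)
  tabs <- lapply(files, function(f) {
    tab <- utils::read.csv(f, stringsAsFactors = FALSE)
    cbind(suite = sub("_summary\\.csv$", "", basename(f)), tab)
  })
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  out
}
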