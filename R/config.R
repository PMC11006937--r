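#' Read a run configuration
#'
#' A run configuration is a YAML file declaring materials (in GPa,
#' converted to MPa on load), models (mesh file paths or synthetic
#' toy-skull specs, optionally scaled), the muscle table, the scenario
#' suites to run, and the protocol constants (`trim_fraction`, default
#' 0.05; `base_force`, default 100 N; `v_ref` rule, default the smallest
#' model volume in the run), plus an output directory and seed.
#'
#' @param path YAML file path.
#' @return a validated object of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  as_run_config(raw)
}

#' Build a run configuration from a list
#'
#' @param raw a list with the structure documented in [read_run_config()].
#' @return a validated `run_config`.
#' @export
as_run_config <- function(raw) {
  defaults <- list(
    materials = list(bone = list(E_GPa = 20.49, nu = 0.40),
                     teeth = list(E_GPa = 60.40, nu = 0.31)),
    models = list(), muscles = list(), scenarios = list(),
    trim_fraction = 0.05, base_force = 100,
    v_ref = "smallest", out_dir = "runs", seed = 1L)
  cfg <- raw
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  cfg$materials <- lapply(stats::setNames(names(cfg$materials),
                                          names(cfg$materials)),
                          function(nm) {
    m <- cfg$materials[[nm]]
    E <- if (!is.null(m$E_GPa)) 1000 * m$E_GPa else m$E_MPa
    if (is.null(E)) stop("material '", nm, "' needs E_GPa or E_MPa")
    material(nm, E = E, nu = m$nu)
  })
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
  validate_run_config(structure(cfg, class = "run_config"))
}

#' Validate a run configuration
#'
#' @param cfg a `run_config`.
#' @return `cfg`, invisibly-checked (errors on any violation).
#' @export
validate_run_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (!is.numeric(cfg$trim_fraction) || cfg$trim_fraction < 0 ||
      cfg$trim_fraction >= 1) {
    stop("trim_fraction must be in [0, 1)")
  }
  if (!is.numeric(cfg$base_force) || cfg$base_force <= 0) {
    stop("base_force must be positive")
  }
  if (length(cfg$models) == 0L) stop("config declares no models")
  for (m in cfg$models) {
    if (is.null(m$name)) stop("every model needs a name")
    if (is.null(m$path) && is.null(m$synthetic)) {
      stop("model '", m$name, "' needs a path or a synthetic spec")
    }
    if (!is.null(m$path) && !file.exists(m$path)) {
      stop("model '", m$name, "': file not found: ", m$path)
    }
  }
  for (mu in cfg$muscles) {
    if (is.null(mu$name) || is.null(mu$side) || is.null(mu$origin_set) ||
        is.null(mu$insertion) || is.null(mu$force)) {
      stop("muscle entries need name, side, origin_set, insertion, force")
    }
  }
  invisible(cfg)
}

# Materialise the configured models as tet_mesh objects, in declared order.
.resolve_models <- function(cfg) {
  out <- list()
  for (m in cfg$models) {
    mesh <- if (!is.null(m$path)) {
      read_mesh(m$path, format = if (is.null(m$format)) "inp" else m$format)
    } else {
      s <- m$synthetic
      spec <- toy_skull_spec(
        length = s$length %||% 60, width = s$width %||% 30,
        height = s$height %||% 24, taper = s$taper %||% 0.5,
        resolution = unlist(s$resolution %||% c(8L, 12L, 6L)),
        seed = s$seed %||% cfg$seed, jitter = s$jitter %||% 0)
      make_toy_skull(spec)
    }
    if (!is.null(m$scale)) mesh <- scale_mesh(mesh, m$scale)
    out[[m$name]] <- mesh
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.resolve_muscles <- function(cfg) {
  lapply(cfg$muscles, function(mu) {
    muscle_load(mu$name, mu$side, mu$origin_set,
                as.numeric(unlist(mu$insertion)), mu$force)
  })
}

.reference_volume <- function(cfg, models) {
  if (identical(cfg$v_ref, "smallest")) {
    min(vapply(models, mesh_volume, numeric(1)))
  } else {
    as.numeric(cfg$v_ref)
  }
}
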