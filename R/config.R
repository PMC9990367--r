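## Run configuration: sectioned YAML, fail-closed validation, defaults.

config_schema <- list(
  top = c("seed", "log_level", "sensor", "protocol", "pipeline", "analysis",
          "cohort", "params", "scene", "noise", "paths"),
  sensor = c("type", "kd", "hill", "r_min", "r_max"),
  protocol = c("name"),
  pipeline = c("frame_rate", "smoothing_window", "register", "reference",
               "score_floor"),
  cohort = c("groups", "between_mouse_cv", "between_slice_cv"),
  group = c("name", "n_mice", "slices_per_mouse", "param_overrides",
            "mosaic_fraction"),
  scene = c("shape", "n_cells", "intensity", "background"),
  noise = c("shot", "read_sd", "bleach_num", "bleach_den", "drift_sd"),
  paths = c("outdir"))

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stopf("unknown config key(s) in %s: %s", where, paste(extra, collapse = ", "))
  invisible(x)
}

#' Load and validate a run configuration
#'
#' The configuration is a sectioned YAML document. Unknown keys anywhere are
#' errors (fail-closed), and defaults are filled from the acquisition
#' conventions: frame rate 5.94 Hz, smoothing window 11 frames for the
#' lactate sensor and 5 for the glucose sensor.
#'
#' @param path YAML file path, or a named list already parsed.
#' @return A `run_config` object with fully resolved components: `sensor`
#'   ([sensor_model()]), `protocol` ([protocol()]), `analysis`
#'   ([analysis_config()]), `params` ([kinetic_params()]), optional `cohort`
#'   ([cohort_spec()]), `pipeline`, `scene`, `noise`, `paths`, `seed`,
#'   `log_level` and the config `hash`.
#' @export
load_config <- function(path) {
  if (is.character(path)) {
    if (!file.exists(path)) stopf("config file not found: %s", path)
    raw <- yaml::read_yaml(path)
    hash <- unname(tools::md5sum(path))
  } else if (is.list(path)) {
    raw <- path
    tf <- tempfile(fileext = ".yaml")
    on.exit(unlink(tf))
    yaml::write_yaml(raw, tf)
    hash <- unname(tools::md5sum(tf))
  } else stopf("'path' must be a file path or a named list")

  check_keys(raw, config_schema$top, "top level")
  seed <- as.integer(raw$seed %||% 1L)

  ## sensor
  sc <- raw$sensor %||% list(type = "laconic")
  check_keys(sc, config_schema$sensor, "sensor")
  type <- match.arg(sc$type %||% "laconic", c("laconic", "fliip"))
  sensor_args <- sc[setdiff(names(sc), "type")]
  sensor <- do.call(if (type == "laconic") laconic_sensor else fliip_sensor,
                    sensor_args)

  ## protocol
  pc <- raw$protocol %||% list(name = "mct_block")
  check_keys(pc, config_schema$protocol, "protocol")
  protocol <- protocol_preset(pc$name %||% "mct_block")

  ## pipeline
  pl <- raw$pipeline %||% list()
  check_keys(pl, config_schema$pipeline, "pipeline")
  pipeline <- list(
    frame_rate = pl$frame_rate %||% 5.94,
    smoothing_window = pl$smoothing_window %||% (if (type == "laconic") 11L else 5L),
    register = pl$register %||% TRUE,
    reference = pl$reference %||% "first",
    score_floor = pl$score_floor %||% 0.3)
  check_number(pipeline$frame_rate, "pipeline.frame_rate", min = 0, strict_min = TRUE)
  check_number(pipeline$smoothing_window, "pipeline.smoothing_window", min = 1)
  if (pipeline$smoothing_window %% 2 == 0)
    stopf("invalid value for 'pipeline.smoothing_window': must be odd")

  ## analysis windows
  an <- raw$analysis %||% list()
  check_keys(an, names(formals(analysis_config)), "analysis")
  analysis <- do.call(analysis_config, an)

  ## kinetic base parameters
  pk <- raw$params %||% list()
  check_keys(pk, names(formals(kinetic_params)), "params")
  params <- do.call(kinetic_params, pk)

  ## cohort (optional; required only for simulation runs)
  cohort <- NULL
  if (!is.null(raw$cohort)) {
    cc <- raw$cohort
    check_keys(cc, config_schema$cohort, "cohort")
    if (is.null(cc$groups) || !length(cc$groups))
      stopf("cohort must define at least one group")
    groups <- lapply(cc$groups, function(g) {
      check_keys(g, config_schema$group, "cohort.groups")
      cohort_group(g$name, g$n_mice, g$slices_per_mouse,
                   param_overrides = g$param_overrides %||% list(),
                   mosaic_fraction = g$mosaic_fraction %||% 1)
    })
    cohort <- cohort_spec(groups,
                          between_mouse_cv = cc$between_mouse_cv %||% 0.05,
                          between_slice_cv = cc$between_slice_cv %||% 0.15,
                          seed = seed)
  }

  ## scene + noise (simulation runs)
  scn <- raw$scene %||% list()
  check_keys(scn, config_schema$scene, "scene")
  scene <- list(shape = unlist(scn$shape %||% c(64L, 64L)),
                n_cells = scn$n_cells %||% 12L,
                intensity = scn$intensity %||% 100,
                background = scn$background %||% 5)
  nz <- raw$noise %||% list()
  check_keys(nz, config_schema$noise, "noise")
  noise <- noise_model(shot = nz$shot %||% FALSE,
                       read_sd = nz$read_sd %||% 0,
                       bleach_num = nz$bleach_num %||% 0,
                       bleach_den = nz$bleach_den %||% 0,
                       drift_sd = nz$drift_sd %||% 0)

  pa <- raw$paths %||% list()
  check_keys(pa, config_schema$paths, "paths")

  structure(list(seed = seed,
                 log_level = raw$log_level %||% "info",
                 sensor = sensor, sensor_type = type,
                 protocol = protocol, pipeline = pipeline,
                 analysis = analysis, params = params, cohort = cohort,
                 scene = scene, noise = noise,
                 paths = list(outdir = pa$outdir %||% "fretflux_out"),
                 hash = hash),
            class = "run_config")
}

LOG_LEVELS <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

log_line <- function(cfg, level, stage, fmt, ...) {
  lv <- LOG_LEVELS[[level]]
  min_lv <- LOG_LEVELS[[cfg$log_level %||% "info"]]
  if (lv >= min_lv)
    message(sprintf("%s [%s] %s", toupper(level), stage, sprintf(fmt, ...)))
  invisible(NULL)
}
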