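## Hierarchical cohort generation: groups -> mice -> slices, with lognormal
## random effects on the transport/consumption Vmax parameters and
## Bernoulli cell-level mosaicism in knockout groups.

#' Describe one cohort group
#'
#' @param name Group name (unique within a cohort).
#' @param n_mice Number of mice.
#' @param slices_per_mouse Retinal slices imaged per mouse.
#' @param param_overrides Named list of [kinetic_params()] values replacing
#'   the cohort base parameters in knockout cells of this group.
#' @param mosaic_fraction Probability that a cell carries the knockout
#'   (mosaic Cre recombination); wild-type cells follow the base parameters.
#' @return A `cohort_group` list.
#' @export
cohort_group <- function(name, n_mice, slices_per_mouse,
                         param_overrides = list(), mosaic_fraction = 1) {
  if (!is.character(name) || length(name) != 1L) stopf("'name' must be a string")
  check_number(n_mice, "n_mice", min = 1)
  check_number(slices_per_mouse, "slices_per_mouse", min = 1)
  check_number(mosaic_fraction, "mosaic_fraction", min = 0, max = 1)
  structure(list(name = name, n_mice = as.integer(n_mice),
                 slices_per_mouse = as.integer(slices_per_mouse),
                 param_overrides = param_overrides,
                 mosaic_fraction = mosaic_fraction),
            class = "cohort_group")
}

#' Describe a simulated cohort
#'
#' Between-mouse and between-slice coefficients of variation act as
#' independent lognormal multipliers on the three Vmax parameters
#' (hexokinase, GLUT, MCT). The defaults put most biological variability at
#' the slice level, where slice preparation dominates.
#'
#' @param groups List of [cohort_group()] objects (unique names).
#' @param between_mouse_cv,between_slice_cv Lognormal CVs (>= 0).
#' @param seed Integer seed; the whole cohort (and any rendered movies) is a
#'   deterministic function of it.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(groups, between_mouse_cv = 0.05,
                        between_slice_cv = 0.15, seed = 1L) {
  if (!length(groups) || !all(vapply(groups, inherits, TRUE, "cohort_group")))
    stopf("'groups' must be a list of cohort_group objects")
  nms <- vapply(groups, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stopf("group names must be unique")
  check_number(between_mouse_cv, "between_mouse_cv", min = 0)
  check_number(between_slice_cv, "between_slice_cv", min = 0)
  structure(list(groups = groups, between_mouse_cv = between_mouse_cv,
                 between_slice_cv = between_slice_cv, seed = as.integer(seed)),
            class = "cohort_spec")
}

lognormal_mult <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)  # unit mean
}

apply_vmax_mult <- function(params, mult) {
  params$j_hk_vmax <- params$j_hk_vmax * mult[1]
  params$glut_vmax <- params$glut_vmax * mult[2]
  params$mct_vmax <- params$mct_vmax * mult[3]
  params
}

#' Generate a synthetic cohort with ground truth
#'
#' One observation per slice. Per-slice kinetic parameters are the group
#' parameters (base parameters plus overrides) times lognormal mouse and
#' slice effects; in mosaic groups each of `n_cells` cells is knockout with
#' probability `mosaic_fraction`, and the whole-frame ratio is the
#' intensity-weighted mixture of knockout and wild-type sensor ratios.
#'
#' With `output = "traces"` (the fast path used for cohort statistics) the
#' sensor ratio trace is produced directly from the simulated concentrations,
#' with optional Gaussian trace noise and the sensor-appropriate smoothing;
#' with `output = "movies"` full two-channel stacks are rendered with
#' [render_movie()] and must be processed through the image pipeline.
#'
#' @param spec A [cohort_spec()].
#' @param protocol A [protocol()] (or preset name).
#' @param base_params Cohort base [kinetic_params()].
#' @param sensor A [sensor_model()].
#' @param output `"traces"` or `"movies"`.
#' @param dt Simulation output step, s (trace time base in trace mode).
#' @param trace_noise_sd Gaussian noise SD on the ratio trace (trace mode).
#' @param n_cells Cells per field (mosaic sampling denominator).
#' @param smooth_window Smoothing window for trace mode; `NULL` picks 11
#'   (lactate) or 5 (glucose) frames.
#' @param scene_shape,cell_intensity,background Scene geometry (movie mode).
#' @param noise A [noise_model()] template for movie mode (its seed is
#'   replaced by per-slice derived seeds).
#' @param frame_rate Acquisition rate for movie mode, Hz.
#' @return List with `traces` (or `movies`), named by trace id, and `truth`
#'   (data.frame of every sampled parameter, one row per slice).
#' @export
generate_cohort <- function(spec, protocol,
                            base_params = kinetic_params(),
                            sensor = laconic_sensor(),
                            output = c("traces", "movies"),
                            dt = 1, trace_noise_sd = 0.005, n_cells = 60,
                            smooth_window = NULL,
                            scene_shape = c(64, 64), cell_intensity = 100,
                            background = 5, noise = noise_model(),
                            frame_rate = 5.94) {
  if (!inherits(spec, "cohort_spec")) stopf("'spec' must be a cohort_spec")
  if (is.character(protocol)) protocol <- protocol_preset(protocol)
  output <- match.arg(output)
  if (is.null(smooth_window))
    smooth_window <- if (sensor$analyte == "lactate") 11L else 5L

  n_slices_total <- sum(vapply(spec$groups, function(g)
    g$n_mice * g$slices_per_mouse, numeric(1)))
  seeds <- derive_seeds(spec$seed, n_slices_total + 1L)
  truth <- NULL
  out_objs <- list()
  si <- 0L

  for (g in spec$groups) {
    ko_params <- modifyList(base_params, g$param_overrides)
    mouse_mults <- with_seed(seeds[n_slices_total + 1L] + match(g$name, vapply(
      spec$groups, `[[`, character(1), "name")), {
      lapply(seq_len(g$n_mice), function(i)
        lognormal_mult(3, spec$between_mouse_cv))
    })
    for (m in seq_len(g$n_mice)) {
      for (s in seq_len(g$slices_per_mouse)) {
        si <- si + 1L
        slice_seed <- seeds[si]
        res <- with_seed(slice_seed, {
          slice_mult <- lognormal_mult(3, spec$between_slice_cv)
          mult <- mouse_mults[[m]] * slice_mult
          p_ko <- do.call(kinetic_params, apply_vmax_mult(ko_params, mult))
          p_wt <- do.call(kinetic_params,
                          apply_vmax_mult(unclass(base_params), mult))
          f_real <- if (g$mosaic_fraction >= 1) 1 else if (g$mosaic_fraction <= 0) 0 else
            rbinom(1, n_cells, g$mosaic_fraction) / n_cells
          ser_ko <- simulate_concentrations(p_ko, protocol, dt = dt)
          mixed_needed <- f_real < 1 && !identical(p_ko, p_wt)
          ser_wt <- if (mixed_needed) simulate_concentrations(p_wt, protocol, dt = dt) else NULL
          list(p_ko = p_ko, p_wt = p_wt, f_real = f_real,
               ser_ko = ser_ko, ser_wt = ser_wt)
        })
        id <- sprintf("%s_m%02d_s%02d", g$name, m, s)
        basal <- steady_state(res$p_ko)

        if (output == "traces") {
          obj <- with_seed(slice_seed + 1L, {
            col <- if (sensor$analyte == "lactate") "lac_in" else "glc_in"
            r_ko <- sensor_forward(res$ser_ko[[col]], sensor)
            r <- if (is.null(res$ser_wt)) r_ko else
              res$f_real * r_ko +
                (1 - res$f_real) * sensor_forward(res$ser_wt[[col]], sensor)
            if (trace_noise_sd > 0)
              r <- pmax(r + rnorm(length(r), 0, trace_noise_sd), 1e-6)
            ratio_trace(res$ser_ko$t, temporal_smooth(r, smooth_window),
                        frame_rate = 1 / dt, window = smooth_window,
                        metadata = list(protocol = protocol$name,
                                        sensor = sensor$analyte,
                                        group = g$name, mouse = m, slice = s))
          })
        } else {
          scene <- random_scene(n_cells = n_cells, shape = scene_shape,
                                mosaic_fraction = g$mosaic_fraction,
                                intensity = cell_intensity,
                                background = background,
                                seed = slice_seed + 2L)
          nm <- noise; nm$seed <- slice_seed + 3L
          obj <- render_movie(res$ser_ko, sensor, scene, nm,
                              frame_rate = frame_rate,
                              control_series = res$ser_wt %||% res$ser_ko)
          obj$metadata$group <- g$name
          obj$metadata$mouse <- m
          obj$metadata$slice <- s
          obj$metadata$id <- id
        }
        out_objs[[id]] <- obj

        truth <- rbind(truth, data.frame(
          id = id, group = g$name, mouse = m, slice = s, seed = slice_seed,
          mosaic_fraction = g$mosaic_fraction,
          mosaic_fraction_realized = res$f_real,
          j_hk_vmax = res$p_ko$j_hk_vmax, glut_vmax = res$p_ko$glut_vmax,
          mct_vmax = res$p_ko$mct_vmax,
          lac_prod_frac = res$p_ko$lac_prod_frac,
          mct4_frac = res$p_ko$mct4_frac,
          basal_glc = basal[["glc_in"]], basal_lac = basal[["lac_in"]],
          j_hk_basal = res$p_ko$j_hk_vmax * basal[["glc_in"]] /
            (res$p_ko$k_hk_km + basal[["glc_in"]]),
          stringsAsFactors = FALSE))
      }
    }
  }
  structure(list(traces = if (output == "traces") out_objs,
                 movies = if (output == "movies") out_objs,
                 truth = truth, protocol = protocol, sensor = sensor),
            class = "cohort")
}
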