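## End-to-end drivers chaining simulate -> register -> mask -> extract ->
## normalize -> estimate -> compare. Each stage writes plain-text outputs
## stamped with the config hash so runs cannot be mixed accidentally.

#' Simulate a cohort of movies to disk
#'
#' Renders one two-channel TIFF stack per slice of the configured cohort and
#' writes `manifest.csv` (file, id, group, mouse, slice, protocol, seed,
#' config_hash) and `truth.csv` (every sampled generative parameter).
#'
#' @param cfg A [load_config()] result with a cohort section.
#' @param outdir Output directory (created if missing); defaults to the
#'   configured path.
#' @return The manifest data.frame, invisibly.
#' @export
run_simulate <- function(cfg, outdir = NULL) {
  if (!inherits(cfg, "run_config")) stopf("'cfg' must be a run_config")
  if (is.null(cfg$cohort)) stopf("config has no cohort section: nothing to simulate")
  outdir <- outdir %||% cfg$paths$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stopf("cannot create output directory: %s", outdir)

  log_line(cfg, "info", "simulate", "generating cohort (seed %d)", cfg$seed)
  coh <- generate_cohort(cfg$cohort, cfg$protocol,
                         base_params = cfg$params, sensor = cfg$sensor,
                         output = "movies",
                         n_cells = cfg$scene$n_cells,
                         scene_shape = cfg$scene$shape,
                         cell_intensity = cfg$scene$intensity,
                         background = cfg$scene$background,
                         noise = cfg$noise,
                         frame_rate = cfg$pipeline$frame_rate)
  rows <- list()
  for (id in names(coh$movies)) {
    file <- file.path(outdir, paste0(id, ".tif"))
    write_movie_tiff(coh$movies[[id]], file)
    md <- coh$movies[[id]]$metadata
    rows[[id]] <- data.frame(file = basename(file), id = id,
                             group = md$group, mouse = md$mouse,
                             slice = md$slice, protocol = cfg$protocol$name,
                             seed = cfg$seed, config_hash = cfg$hash,
                             stringsAsFactors = FALSE)
    log_line(cfg, "debug", "simulate", "wrote %s", file)
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(outdir, "manifest.csv"), row.names = FALSE)
  truth <- coh$truth
  truth$config_hash <- cfg$hash
  write.csv(truth, file.path(outdir, "truth.csv"), row.names = FALSE)
  log_line(cfg, "info", "simulate", "%d stacks written to %s", nrow(manifest), outdir)
  invisible(manifest)
}

## process one stack; errors propagate to run_process which isolates them
process_one <- function(cfg, path) {
  movie <- read_movie_tiff(path)
  drift <- NULL
  if (isTRUE(cfg$pipeline$register) && n_frames(movie) >= 2L) {
    reg <- register_stack(movie, reference = cfg$pipeline$reference,
                          score_floor = cfg$pipeline$score_floor)
    movie <- reg$movie
    drift <- reg$drift
  }
  mask <- build_mask(movie)
  trace <- extract_ratio_trace(movie, mask, window = cfg$pipeline$smoothing_window)
  est <- analyze_trace(trace, cfg$protocol, cfg$analysis, sensor = cfg$sensor)
  list(trace = trace, est = est, mask = mask, drift = drift)
}

#' Process a manifest of stacks into a per-trace results table
#'
#' Runs the image pipeline and flux analysis on every stack listed in the
#' manifest. A failure on one stack is recorded as a failed row and never
#' affects the others. Results are written to `results.csv`; each extracted
#' trace goes to `traces/<id>.csv` and its drift path to `drift/<id>.csv`.
#'
#' @param cfg A [load_config()] result.
#' @param manifest Manifest data.frame (or path to `manifest.csv`).
#' @param outdir Directory holding the stacks and receiving the outputs.
#' @return The results data.frame, invisibly.
#' @export
run_process <- function(cfg, manifest, outdir = NULL) {
  if (!inherits(cfg, "run_config")) stopf("'cfg' must be a run_config")
  outdir <- outdir %||% cfg$paths$outdir
  if (is.character(manifest)) manifest <- read.csv(manifest)
  if (!nrow(manifest)) stopf("empty manifest")
  dir.create(file.path(outdir, "traces"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "drift"), recursive = TRUE, showWarnings = FALSE)

  rows <- list()
  for (i in seq_len(nrow(manifest))) {
    mrow <- manifest[i, ]
    row <- data.frame(id = mrow$id, group = mrow$group, mouse = mrow$mouse,
                      slice = mrow$slice, protocol = mrow$protocol,
                      basal = NA_real_, amplitude = NA_real_,
                      slope = NA_real_, r2 = NA_real_, n_fit = NA_integer_,
                      mask_fraction = NA_real_, max_drift_px = NA_real_,
                      flags = "", failed = FALSE, error = "",
                      config_hash = cfg$hash, stringsAsFactors = FALSE)
    res <- tryCatch(
      process_one(cfg, file.path(outdir, mrow$file)),
      error = function(e) e)
    if (inherits(res, "error")) {
      row$failed <- TRUE
      row$error <- conditionMessage(res)
      log_line(cfg, "error", "process", "%s failed: %s", mrow$id, row$error)
    } else {
      est <- res$est
      row$basal <- est$basal; row$amplitude <- est$amplitude
      row$slope <- est$slope; row$r2 <- est$r2
      row$n_fit <- est$n
      row$mask_fraction <- res$mask$fraction
      if (!is.null(res$drift))
        row$max_drift_px <- max(abs(c(res$drift$dy, res$drift$dx)))
      row$flags <- paste(est$flags, collapse = ";")
      if (nzchar(row$flags))
        log_line(cfg, "warn", "process", "%s flagged: %s", mrow$id, row$flags)
      write_ratio_trace(res$trace, file.path(outdir, "traces",
                                             paste0(mrow$id, ".csv")))
      if (!is.null(res$drift))
        write.csv(res$drift, file.path(outdir, "drift",
                                       paste0(mrow$id, ".csv")),
                  row.names = FALSE)
      log_line(cfg, "debug", "process", "%s done", mrow$id)
    }
    rows[[i]] <- row
  }
  results <- do.call(rbind, rows)
  write.csv(results, file.path(outdir, "results.csv"), row.names = FALSE)
  log_line(cfg, "info", "process", "%d/%d stacks processed",
           sum(!results$failed), nrow(results))
  invisible(results)
}

#' Compare groups on the processed readouts
#'
#' Runs [summarize_cohort()] on every readout the protocol defines, writes
#' `summary.csv`, `comparisons.csv`, a JSON run summary and a short
#' human-readable report. Refuses tables whose `config_hash` does not match
#' the configuration (outputs of different runs must not be mixed).
#'
#' @param cfg A [load_config()] result.
#' @param results Results data.frame (or path to `results.csv`).
#' @param outdir Output directory.
#' @param reference Reference group for many-to-one post hoc tests.
#' @param posthoc `"dunn"` or `"dunnett"`.
#' @return List with `summary` and `comparisons`, invisibly.
#' @export
run_compare <- function(cfg, results, outdir = NULL, reference = NULL,
                        posthoc = c("dunn", "dunnett")) {
  if (!inherits(cfg, "run_config")) stopf("'cfg' must be a run_config")
  posthoc <- match.arg(posthoc)
  outdir <- outdir %||% cfg$paths$outdir
  if (is.character(results)) results <- read.csv(results)
  if (!nrow(results)) stopf("empty results table")
  if ("config_hash" %in% names(results) &&
      !all(results$config_hash == cfg$hash))
    stopf("results were produced under a different config hash")
  ok <- !results$failed
  if (length(unique(results$group[ok])) < 2L)
    stopf("need at least two groups to compare")

  readouts <- intersect(c("basal", "amplitude", "slope"), names(results))
  readouts <- readouts[vapply(readouts, function(r)
    any(is.finite(results[[r]][ok])), logical(1))]
  cmp <- summarize_cohort(results[ok, ], readouts, reference = reference,
                          posthoc = posthoc)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write.csv(cmp$summary, file.path(outdir, "summary.csv"), row.names = FALSE)
  write.csv(cmp$comparisons, file.path(outdir, "comparisons.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(config_hash = cfg$hash, seed = cfg$seed,
         protocol = cfg$protocol$name, n_traces = nrow(results),
         n_failed = sum(results$failed), readouts = readouts),
    file.path(outdir, "run_summary.json"), auto_unbox = TRUE, digits = NA)

  rep_path <- file.path(outdir, "report.txt")
  con <- file(rep_path, "w"); on.exit(close(con))
  writeLines(sprintf("fretflux comparison report (protocol %s, seed %d)",
                     cfg$protocol$name, cfg$seed), con)
  writeLines(sprintf("config hash %s", cfg$hash), con)
  for (i in seq_len(nrow(cmp$comparisons))) {
    r <- cmp$comparisons[i, ]
    writeLines(sprintf("  %-10s %-12s vs %-12s %-14s p=%.4g %s",
                       r$readout, r$group_a, r$group_b, r$method,
                       if (is.finite(r$adjusted_p)) r$adjusted_p else r$p,
                       r$stars), con)
  }
  log_line(cfg, "info", "compare", "report written to %s", rep_path)
  invisible(cmp)
}

#' Run the whole pipeline: simulate, process, compare
#'
#' @param cfg A [load_config()] result with a cohort section.
#' @param outdir Output directory.
#' @inheritParams run_compare
#' @return The comparison list, invisibly.
#' @export
run_all <- function(cfg, outdir = NULL, reference = NULL,
                    posthoc = c("dunn", "dunnett")) {
  outdir <- outdir %||% cfg$paths$outdir
  manifest <- run_simulate(cfg, outdir)
  results <- run_process(cfg, manifest, outdir)
  run_compare(cfg, results, outdir, reference = reference, posthoc = posthoc)
}
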