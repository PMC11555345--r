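#' Pipeline configuration
#'
#' Collects every stage's parameters with the module-level defaults.
#'
#' @param mode `"im_domain"` (cube is already Im\[chi3\]) or
#'   `"chi3_domain"` (raw CARS intensity; phase retrieval runs first).
#' @param layout A [phantom_layout()] for the simulation stage.
#' @param axis Wavenumber axis of the simulated cube.
#' @param noise A [noise_config()].
#' @param seed Integer seed used for every stochastic stage.
#' @param pole_fraction MEM pole fraction (chi3_domain only).
#' @param error_phase_order Polynomial order of the error-phase fit.
#' @param arpls_lam,arpls_tol arPLS penalty and tolerance.
#' @param use_arpls Apply per-pixel arPLS (stage 2) after the
#'   outside-cell subtraction.
#' @param water_mode `"off"` (default; the generator omits water unless
#'   asked) or `"component_subtract"`.
#' @param fit_mode `"fixed_shape"` or `"bounded_nonlinear"`.
#' @param mask_threshold Ratio-map invalidity threshold.
#' @param masks `"truth"` (phantom labels) or `"auto"` (segmentation of
#'   the 2933 cm-1 image).
#' @param stat_design `"ttest_scheme"` or `"dunnett_scheme"`.
#' @param out_dir Output directory (`NULL`: nothing written).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("im_domain", "chi3_domain"),
                            layout = phantom_layout(),
                            axis = seq(1500, 1800, by = 2.5),
                            noise = noise_config(sd = 0.002,
                                                 baseline_amplitude = 0.01),
                            seed = 1,
                            pole_fraction = 0.45,
                            error_phase_order = 0,
                            arpls_lam = 1e5, arpls_tol = 1e-6,
                            use_arpls = TRUE,
                            water_mode = "off",
                            fit_mode = "fixed_shape",
                            mask_threshold = 1e-19,
                            masks = c("truth", "auto"),
                            stat_design = c("ttest_scheme", "dunnett_scheme"),
                            out_dir = NULL) {
  structure(list(mode = match.arg(mode), layout = layout, axis = axis,
                 noise = noise, seed = seed, pole_fraction = pole_fraction,
                 error_phase_order = error_phase_order,
                 arpls_lam = arpls_lam, arpls_tol = arpls_tol,
                 use_arpls = use_arpls, water_mode = water_mode,
                 fit_mode = fit_mode, mask_threshold = mask_threshold,
                 masks = match.arg(masks),
                 stat_design = match.arg(stat_design), out_dir = out_dir),
            class = "pipeline_config")
}

# per-pixel MEM retrieval of a raw-intensity cube
retrieve_cube <- function(cube, pole_fraction = 0.45, error_phase_order = 0) {
  stopifnot(inherits(cube, "cars_cube"), cube$mode == "chi3_domain")
  d <- dim(cube$values)
  flat <- matrix(cube$values, d[1] * d[2], d[3])
  out <- matrix(0, d[1] * d[2], d[3])
  for (i in seq_len(nrow(flat))) {
    raw <- tibble::tibble(wavenumber = cube$axis, intensity = flat[i, ])
    ch <- correct_error_phase(mem_retrieve(raw, pole_fraction),
                              order = error_phase_order)
    out[i, ] <- ch$im
  }
  cars_cube(array(out, d), cube$axis, pixel_size = cube$pixel_size,
            mode = "im_domain", meta = cube$meta)
}

#' Run the end-to-end senescence analysis pipeline
#'
#' Simulate -> (retrieve, chi3_domain only) -> preprocess (outside-cell
#' subtraction, optional arPLS) -> per-pixel amide I fit -> indicator
#' maps -> per-cell records and classification -> group statistics and
#' size-ratio regression. Deterministic for a fixed config seed. When
#' `out_dir` is set, writes `records.csv`, `summary.json`, the cube,
#' the indicator maps and a plain-text log.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `pipeline_result`: list with `records`
#'   (classified cell tibble), `comparison` (a [group_comparison()] on
#'   nucleolar mean ratios, control vs senescent, when both groups have
#'   n >= 3), `regression` (a [size_ratio_regression()] over
#'   mononuclear cells, when feasible), `maps`, `fitmaps`, `phantom`,
#'   `summary` (named list of headline numbers), and `log`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  log <- character()
  say <- function(...) {
    msg <- sprintf("[%5.1fs] %s", as.numeric(Sys.time() - t0, units = "secs"),
                   sprintf(...))
    log <<- c(log, msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  say("simulate: %d+%d cells, %dx%d px, mode %s",
      config$layout$n_control, config$layout$n_senescent,
      config$layout$dim[1], config$layout$dim[2], config$mode)
  phantom <- stage("simulate", make_phantom(config$layout, seed = config$seed))
  sim <- stage("simulate",
               synthesize_cube(phantom, axis = config$axis,
                               noise = config$noise, mode = config$mode,
                               seed = config$seed + 1))
  cube <- sim$cube
  if (config$mode == "chi3_domain") {
    say("retrieve: MEM phase retrieval, pole fraction %.2f", config$pole_fraction)
    cube <- stage("retrieve",
                  retrieve_cube(cube, config$pole_fraction,
                                config$error_phase_order))
  }
  say("preprocess: outside-cell subtraction%s",
      if (config$use_arpls) " + per-pixel arPLS" else "")
  outside <- phantom$cell_id == 0
  cube <- stage("preprocess", subtract_outside_baseline(cube, outside))
  if (config$use_arpls) {
    cube <- stage("preprocess",
                  arpls_cube(cube, lam = config$arpls_lam,
                             ratio_tol = config$arpls_tol))
  }
  say("fit: per-pixel amide I decomposition (%s)", config$fit_mode)
  fitmaps <- stage("fit", fit_cube(cube, mode = config$fit_mode,
                                   progress_log = function(m) say("%s", m)))
  say("maps: indicator maps, mask threshold %g", config$mask_threshold)
  masks <- if (config$masks == "truth") phantom else {
    stage("maps", segment_regions(sim$intensity_2933))
  }
  label_img <- if (inherits(masks, "cars_phantom")) masks$label else masks$region
  maps <- stage("maps", indicator_maps(fitmaps, label_img,
                                       mask_threshold = config$mask_threshold))
  say("quantify: per-cell nucleolar records")
  records <- stage("quantify",
                   extract_cell_records(masks, maps,
                                        pixel_size = phantom$pixel_size))
  records <- classify_cells(records)
  usable <- records[records$has_nucleus &
                      is.finite(records$largest_nucleolus_mean_ratio), ]
  grp <- table(factor(usable$phenotype_class %in% "binucleate",
                      levels = c(FALSE, TRUE)))
  comparison <- NULL
  if (all(grp >= 3) && length(unique(usable$phenotype_class)) >= 2) {
    say("stats: %s on nucleolar mean ratios", config$stat_design)
    dat <- data.frame(
      value = usable$largest_nucleolus_mean_ratio,
      group = ifelse(usable$phenotype_class == "binucleate",
                     "senescent", "control"))
    comparison <- stage("stats",
                        group_comparison(dat, design = config$stat_design,
                                         control = "control"))
  }
  mono <- usable[usable$nuclei_count == 1, ]
  regression <- NULL
  if (nrow(mono) >= 3 && stats::var(mono$largest_nucleolus_size) > 0) {
    regression <- stage("stats", size_ratio_regression(mono))
  }
  means <- tapply(usable$largest_nucleolus_mean_ratio,
                  ifelse(usable$phenotype_class == "binucleate",
                         "senescent", "control"), mean)
  summary <- list(
    n_cells = nrow(records),
    mean_ratio_control = unname(means["control"]),
    mean_ratio_senescent = unname(means["senescent"]),
    location_p = if (!is.null(comparison)) min(comparison$location$p_value) else NA,
    regression_slope = if (!is.null(regression)) regression$slope else NA,
    regression_p = if (!is.null(regression)) regression$p_value else NA,
    nonconverged_pixels = sum(!fitmaps$converged),
    seed = config$seed)
  say("done: control mean ratio %.3f, senescent %.3f",
      summary$mean_ratio_control %||% NA, summary$mean_ratio_senescent %||% NA)
  res <- structure(list(records = records, comparison = comparison,
                        regression = regression, maps = maps,
                        fitmaps = fitmaps, phantom = phantom, cube = cube,
                        summary = summary, log = log),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(res, sim, config)
  res
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

write_pipeline_outputs <- function(res, sim, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(config$out_dir, ...)
  readr::write_csv(res$records, p("records.csv"))
  summ <- res$summary
  summ$config_hash <- rlang::hash(config[setdiff(names(config), "out_dir")])
  jsonlite::write_json(summ, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  write_cube(res$cube, p("corrected_cube.bin"))
  if (requireNamespace("png", quietly = TRUE)) {
    write_image(ifelse(is.na(res$maps$ratio), 0, res$maps$ratio),
                p("ratio_map.png"))
    write_image(res$maps$subtraction, p("subtraction_map.png"))
    write_image(res$phantom$label / 3, p("labels.png"))
  }
  writeLines(res$log, p("pipeline.log"))
  invisible(config$out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<pipeline_result> %d cells; mean nucleolar ratio control %.3f, senescent %.3f\n",
              s$n_cells, s$mean_ratio_control %||% NA,
              s$mean_ratio_senescent %||% NA))
  if (!is.null(x$comparison)) {
    cat(sprintf("  location test p = %.4g\n", s$location_p))
  }
  if (!is.null(x$regression)) {
    cat(sprintf("  size-ratio regression: slope %.3g, p = %.4g\n",
                s$regression_slope, s$regression_p))
  }
  invisible(x)
}
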