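# End-to-end orchestration: enhance -> slab -> segment -> quantify, with
# every intermediate written to disk and one serialized config per run.

#' Pipeline configuration
#'
#' One record governing a full run. Input is either a volume file (with a
#' surfaces CSV) or a phantom specification; all stage parameters are
#' echoed into the run log.
#'
#' @param input Path to a volume (`.nii`/`.tif`), or a [phantom_spec()].
#' @param surfaces Path to a surfaces CSV, `"phantom-truth"` (use the
#'   phantom's ground-truth surfaces) or `"detect"` (gradient detection,
#'   phantoms only).
#' @param out_dir Output directory (created if missing); `NULL` disables
#'   writing.
#' @param enhance An [enhance_config()].
#' @param params A [threshold_params()].
#' @param grid An [etdrs_grid()].
#' @param extent,dz Geometry forwarded to [read_volume()].
#' @param seed Seed forwarded to phantom generation.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input, surfaces = "phantom-truth", out_dir = NULL,
                            enhance = enhance_config(),
                            params = threshold_params(),
                            grid = etdrs_grid(), extent = NULL, dz = NULL,
                            seed = 1L) {
  structure(list(input = input, surfaces = surfaces, out_dir = out_dir,
                 enhance = enhance, params = params, grid = grid,
                 extent = extent, dz = dz, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full quantification pipeline
#'
#' Executes enhancement, slab extraction, composite segmentation and ETDRS
#' quantification. Identical configuration and inputs give identical
#' outputs: every stage is deterministic and the only randomness (phantom
#' speckle) is seeded from the config.
#'
#' @param config A [pipeline_config()].
#' @param verbose Log one line per stage.
#' @return A list of class `pipeline_result` with `metrics` (tibble),
#'   `vessel` mask, `maps` (vessel/choroid [en_face_map()]s), `surfaces`,
#'   `truth` (phantom runs only), `log` (tibble of stage timings) and
#'   `paths` of written artifacts.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  t_all <- proc.time()[3]
  log <- list()
  mark <- function(name, t0) {
    log[[length(log) + 1]] <<- tibble::tibble(
      stage = name, seconds = round(proc.time()[3] - t0, 3))
    if (verbose) message(sprintf("[%s] %.2fs", name, proc.time()[3] - t0))
  }
  paths <- list()
  outd <- config$out_dir
  if (!is.null(outd) && !dir.exists(outd))
    dir.create(outd, recursive = TRUE)
  save_to <- function(name) if (is.null(outd)) NULL else file.path(outd, name)

  # --- input
  t0 <- proc.time()[3]
  truth <- NULL
  if (inherits(config$input, "phantom_spec")) {
    spec <- config$input
    spec$seed <- config$seed
    truth <- make_phantom(spec)
    vol <- truth$volume
  } else {
    vol <- read_volume(config$input, extent = config$extent, dz = config$dz)
  }
  mark("input", t0)

  # --- surfaces
  t0 <- proc.time()[3]
  surfaces <- if (inherits(config$surfaces, "surface_pair")) {
    config$surfaces
  } else if (identical(config$surfaces, "phantom-truth")) {
    if (is.null(truth))
      stop("surfaces = 'phantom-truth' requires a phantom input", call. = FALSE)
    truth$surfaces
  } else if (identical(config$surfaces, "detect")) {
    detect_surfaces_phantom(vol)
  } else {
    read_surfaces(config$surfaces)
  }
  mark("surfaces", t0)

  # --- enhance
  t0 <- proc.time()[3]
  enh <- enhance_pipeline(vol, config$enhance)
  if (!is.null(outd)) {
    paths$enhanced <- save_to("enhanced.nii.gz")
    write_volume(enh, paths$enhanced)
  }
  mark("enhance", t0)

  # --- segment
  t0 <- proc.time()[3]
  seg <- segment_choroid(enh, surfaces, config$params)
  if (!is.null(outd)) {
    paths$mask <- save_to("vessel_mask.nii.gz")
    write_mask(seg$vessel, paths$mask)
    paths$surfaces <- save_to("surfaces.csv")
    write_surfaces(surfaces, paths$surfaces)
  }
  mark("segment", t0)

  # --- quantify
  t0 <- proc.time()[3]
  vmap <- vessel_volume_map(seg$vessel)
  cmap <- choroid_volume_map(surfaces, vol$spacing)
  metrics <- region_metrics(vmap, cmap, config$grid)
  if (!is.null(outd)) {
    paths$vessel_map <- save_to("vessel_volume_map.csv")
    write_map(vmap, paths$vessel_map)
    paths$choroid_map <- save_to("choroid_volume_map.csv")
    write_map(cmap, paths$choroid_map)
    paths$metrics <- save_to("metrics.csv")
    write.csv(metrics, paths$metrics, row.names = FALSE)
    paths$vessel_png <- save_to("vessel_volume_map.png")
    render_map(vmap, paths$vessel_png, colormap = "warm")
  }
  mark("quantify", t0)
  mark("total", t_all)

  structure(list(metrics = metrics, vessel = seg$vessel,
                 views = seg[c("bscan", "cscan", "global")],
                 global_threshold = seg$global_threshold,
                 maps = list(vessel = vmap, choroid = cmap),
                 surfaces = surfaces, truth = truth,
                 log = do.call(rbind, log), paths = paths,
                 config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$metrics, n = 11)
  invisible(x)
}

#' Human-readable markdown report
#'
#' Tables of per-region choroidal metrics plus, optionally, ROC analyses,
#' with a parameter echo for reproducibility. Regions appear in a fixed
#' deterministic order.
#'
#' @param metrics Tibble from [region_metrics()].
#' @param roc Optional named list of `choro_roc` or `cohort_sim` objects.
#' @param params Optional [threshold_params()] echoed into the report.
#' @return A single markdown string.
#' @export
report_markdown <- function(metrics, roc = NULL, params = NULL) {
  fmt <- function(x) formatC(x, digits = 4, format = "fg")
  lines <- c("# Choroidal quantification report", "",
             "## Regional metrics (ETDRS)", "",
             "| region | Vc (mm3) | Vv (mm3) | VI (%) |",
             "|---|---|---|---|")
  for (i in seq_len(nrow(metrics)))
    lines <- c(lines, sprintf("| %s | %s | %s | %s |",
                              metrics$region[i], fmt(metrics$Vc_mm3[i]),
                              fmt(metrics$Vv_mm3[i]),
                              ifelse(is.na(metrics$VI_percent[i]), "NA",
                                     fmt(metrics$VI_percent[i]))))
  if (!is.null(roc) && length(roc)) {
    lines <- c(lines, "", "## Diagnostic statistics", "",
               "| comparison | AUC | cutoff | sensitivity | specificity |",
               "|---|---|---|---|---|")
    for (nm in names(roc)) {
      r <- roc[[nm]]
      if (inherits(r, "cohort_sim")) {
        gl <- glance(r)
        lines <- c(lines, sprintf("| %s | %.3f | %s | %s | %s |", nm,
                                  gl$auc_mc_mean,
                                  ifelse(is.na(gl$cutoff), "-", fmt(gl$cutoff)),
                                  ifelse(is.na(gl$sensitivity), "-",
                                         sprintf("%.1f%%", 100 * gl$sensitivity)),
                                  ifelse(is.na(gl$specificity), "-",
                                         sprintf("%.1f%%", 100 * gl$specificity))))
      } else {
        lines <- c(lines, sprintf("| %s | %.3f | %s | %.1f%% | %.1f%% |", nm,
                                  r$auc, fmt(r$cutoff), 100 * r$sensitivity,
                                  100 * r$specificity))
      }
    }
  }
  if (!is.null(params)) {
    lines <- c(lines, "", "## Parameters", "",
               sprintf("- Niblack k: %g", params$k),
               sprintf("- B-scan window: %s mm",
                       paste(params$window_bscan_mm, collapse = " x ")),
               sprintf("- C-scan window: %s mm",
                       paste(params$window_cscan_mm, collapse = " x ")),
               sprintf("- combine rule: %s", params$combine_rule),
               sprintf("- min component: %d voxels", params$min_component))
  }
  paste(lines, collapse = "\n")
}
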