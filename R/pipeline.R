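## End-to-end orchestration: for every manifest entry, align the four
## bands, clip the AOI, segment the plant on NDVI, summarize the eleven
## vegetation indices over the mask and compute the twelve shape
## descriptors; collect everything into one long-format trial table and
## write artifacts with provenance sidecars.

#' Pipeline configuration
#'
#' @param shifts a [shift_profile()] (or named list of [shift_factor()]s).
#' @param roi an [aoi()], or NULL to skip clipping (frames smaller than
#'   the sensor's native 960 x 1280 are typically processed unclipped).
#' @param seg a [segmentation_params()].
#' @param indices index names to summarize; default all eleven.
#' @param variables stats-layer variables; default the seven growth
#'   features.
#' @param alpha significance level for the stats layer.
#' @param write_masks,write_indices write per-image artifacts (PNG masks /
#'   float TIFF index rasters).
#' @param seed integer seed recorded in provenance.
#' @export
pipeline_config <- function(shifts = shift_profile("0.7m"),
                            roi = aoi(),
                            seg = segmentation_params(),
                            indices = INDEX_NAMES,
                            variables = names(growth_models()),
                            alpha = 0.01,
                            write_masks = TRUE,
                            write_indices = FALSE,
                            seed = 1L) {
  indices <- match.arg(indices, INDEX_NAMES, several.ok = TRUE)
  if (!is.null(roi) && !inherits(roi, "aoi")) stop_arg("roi must be an aoi")
  if (!inherits(seg, "segmentation_params"))
    stop_arg("seg must be segmentation_params")
  structure(list(shifts = shifts, roi = roi, seg = seg, indices = indices,
                 variables = variables, alpha = alpha,
                 write_masks = write_masks, write_indices = write_indices,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

## stable hash of the configuration for provenance sidecars
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  ser <- list(shifts = lapply(config$shifts, function(s)
                c(dx = s$dx, dy = s$dy)),
              roi = if (is.null(config$roi)) NULL
                    else list(x = config$roi$x, y = config$roi$y),
              seg = unclass(config$seg), indices = config$indices,
              variables = config$variables, alpha = config$alpha,
              seed = config$seed)
  jsonlite::write_json(ser, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

## process one manifest entry -> data.frame of variable rows (value = NA
## for every variable when the mask comes out empty)
.process_entry <- function(entry, config, out_dir) {
  bands <- lapply(BANDS, function(b)
    read_band_tiff(entry$band_paths[[b]], b))
  names(bands) <- BANDS
  frame <- align_bands(bands, config$shifts,
                       metadata = entry[c("plant_id", "treatment", "week")])
  if (!is.null(config$roi)) frame <- clip_aoi(frame, config$roi)
  mask <- withCallingHandlers(
    segment_plant(frame, config$seg),
    warning = function(w) invokeRestart("muffleWarning"))
  tag <- sprintf("%s_w%s", entry$plant_id, entry$week)
  if (config$write_masks && !is.null(out_dir))
    write_mask(mask, file.path(out_dir, paste0("mask_", tag, ".png")))
  empty <- sum(mask$pixels) == 0L
  vals <- c()
  for (ix in config$indices) {
    img <- compute_index(frame, ix)
    if (config$write_indices && !is.null(out_dir))
      write_index_tiff(img, file.path(out_dir,
                                      sprintf("index_%s_%s.tif", ix, tag)))
    vals[ix] <- if (empty) NA_real_ else
      tryCatch(masked_mean(img, mask), error = function(e) NA_real_)
  }
  morpho <- if (empty) stats::setNames(rep(NA_real_,
                                           length(MORPHO_VARIABLES)),
                                       MORPHO_VARIABLES)
  else {
    f <- compute_features(mask)
    vapply(MORPHO_VARIABLES, function(v) as.numeric(f[[v]]), numeric(1))
  }
  vals <- c(vals, morpho)
  data.frame(plant_id = entry$plant_id, treatment = entry$treatment,
             week = as.integer(entry$week), variable = names(vals),
             value = unname(vals), stringsAsFactors = FALSE)
}

#' Run the full pipeline over a session manifest
#'
#' Stage order per plant-week: align, clip, NDVI, segment, masked index
#' means, morphology. A failure on one image is logged and skipped, not
#' fatal (its rows are simply absent); an image whose mask comes out empty
#' keeps its rows with NA values so degradation is visible. Re-running
#' with unchanged inputs and configuration produces byte-identical tables.
#'
#' @param manifest list of manifest entries (see [read_manifest()]) or the
#'   path of a manifest JSON.
#' @param config a [pipeline_config()].
#' @param out_dir artifact directory, or NULL to produce no files.
#' @return object of class `pipeline_result`: `table` (trial table),
#'   `stats` (per-week Tukey comparisons for the configured variables),
#'   `failures` (per-entry error messages), `config_hash`.
#' @export
run_pipeline <- function(manifest, config = pipeline_config(),
                         out_dir = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (!length(manifest)) stop_arg("empty manifest")
  lapply(manifest, validate_manifest_entry)
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  rows <- list(); failures <- list()
  for (i in seq_along(manifest)) {
    entry <- manifest[[i]]
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(.process_entry(entry, config, out_dir),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[[sprintf("%s_w%s", entry$plant_id, entry$week)]] <-
        conditionMessage(res)
      message(sprintf("[%s w%s] FAILED: %s", entry$plant_id, entry$week,
                      conditionMessage(res)))
    } else {
      rows[[length(rows) + 1L]] <- res
      message(sprintf("[%s w%s] ok (%.2fs)", entry$plant_id, entry$week,
                      proc.time()[["elapsed"]] - t0))
    }
  }
  if (!length(rows)) stop_arg("every manifest entry failed")
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  ## per-week comparisons for the configured variables, where testable
  stats_out <- list()
  for (v in intersect(config$variables, unique(table$variable))) {
    cmp <- tryCatch(weekly_comparisons(table, v, config$alpha),
                    error = function(e) NULL)
    if (!is.null(cmp)) stats_out[[v]] <- cmp
  }
  if (!is.null(out_dir)) {
    write_feature_table(table, file.path(out_dir, "features.csv"))
    sidecar <- list(config_hash = hash,
                    n_entries = length(manifest),
                    n_failures = length(failures),
                    failures = failures)
    jsonlite::write_json(sidecar, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  structure(list(table = table, stats = stats_out, failures = failures,
                 config_hash = hash), class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d rows, %d failed entries, config %s\n",
              nrow(x$table), length(x$failures), x$config_hash))
  invisible(x)
}
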