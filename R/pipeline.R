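#' Pipeline run configuration
#'
#' Bundles everything the batch driver needs: input/output folders, the
#' per-image traced paths, optional quality-control crops (applied to the
#' straightened images), detection parameters (or a preset name), and the
#' discard-handling flags.
#'
#' @param input_dir folder of input TIFFs (stacks or single-page).
#' @param output_dir output folder (created if missing).
#' @param path_file CSV of traced paths, see [read_paths_csv()].
#' @param crop_file optional CSV `image_id, row0, col0, height, width, keep`
#'   (0-based; `keep = 0` excludes the image; rows apply to the straightened
#'   image).
#' @param params a [detection_params], or a preset name for
#'   [detection_preset()].
#' @param replace_discarded replace misfit FWHM by ROI width.
#' @param include_discarded_in_density count discarded puncta in density.
#' @param log_level `"info"` or `"quiet"`.
#' @return A `run_config` object.
#' @export
run_config <- function(input_dir, output_dir, path_file,
                       crop_file = NULL, params = "nuIs24",
                       replace_discarded = FALSE,
                       include_discarded_in_density = TRUE,
                       log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  if (is.character(params)) params <- detection_preset(params)
  stopifnot(inherits(params, "detection_params"))
  if (!dir.exists(input_dir)) stop("input_dir does not exist: ", input_dir)
  if (!file.exists(path_file)) stop("path_file does not exist: ", path_file)
  if (!is.null(crop_file) && !file.exists(crop_file))
    stop("crop_file does not exist: ", crop_file)
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 path_file = path_file, crop_file = crop_file,
                 params = params, replace_discarded = replace_discarded,
                 include_discarded_in_density = include_discarded_in_density,
                 log_level = log_level),
            class = "run_config")
}

#' Load a run configuration from JSON
#'
#' Accepts the [run_config()] fields plus either `preset` (name) or a
#' `params` object with [detection_params()] fields.
#'
#' @param path JSON file.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- if (!is.null(j$preset)) detection_preset(j$preset)
            else if (!is.null(j$params)) do.call(detection_params, j$params)
            else detection_params()
  run_config(input_dir = j$input_dir, output_dir = j$output_dir,
             path_file = j$path_file, crop_file = j$crop_file,
             params = params,
             replace_discarded = isTRUE(j$replace_discarded),
             include_discarded_in_density =
               !isFALSE(j$include_discarded_in_density),
             log_level = if (is.null(j$log_level)) "info" else j$log_level)
}

read_crops_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "keep")
  if (!all(need %in% names(df)))
    stop("crop file '", path, "' must have columns image_id, keep ",
         "(plus row0, col0, height, width for kept crops)")
  out <- list()
  for (i in seq_len(nrow(df))) {
    keep <- as.logical(df$keep[i])
    rect <- if (keep) c(df$row0[i], df$col0[i], df$height[i], df$width[i])
            else NULL
    out[[df$image_id[i]]] <- crop_spec(df$image_id[i], rect, keep)
  }
  out
}

#' Run the full analysis pipeline over a folder
#'
#' For every TIFF in the input folder (processed in file-name order):
#' maximum-intensity projection, straightening along the image's traced
#' path, optional quality crop/exclusion, punctum detection, per-punctum
#' measurement. Writes per-image straightened TIFFs, mask TIFFs and ROI
#' CSVs, a combined per-punctum CSV, a density CSV, a JSON run manifest and
#' a log. Per-image failures are logged and skipped, never fatal; the
#' failure count is returned.
#'
#' @param config a [run_config].
#' @return Invisibly, a list: `puncta` (combined data.frame), `density`,
#'   `n_failed`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$output_dir, "run.log")
  loglines <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    loglines <<- c(loglines, msg)
    if (config$log_level == "info") message(msg)
  }

  files <- sort(list.files(config$input_dir, pattern = "\\.tiff?$",
                           ignore.case = TRUE, full.names = TRUE))
  paths <- read_paths_csv(config$path_file)
  crops <- if (is.null(config$crop_file)) list()
           else read_crops_csv(config$crop_file)

  if (length(files) == 0L)
    warning("no TIFF images found in ", config$input_dir)

  puncta <- list()
  lengths <- list()
  status <- list()
  for (f in files) {
    id <- sub("\\.[^.]*$", "", basename(f))
    res <- tryCatch({
      stack <- read_image(f, image_id = id)
      proj <- max_project(stack)
      if (is.null(paths[[id]]))
        stop("no traced path for image '", id, "'")
      straight <- straighten(proj, paths[[id]])
      excluded <- FALSE
      if (!is.null(crops[[id]])) {
        straight <- apply_crop(straight, crops[[id]])
        excluded <- is_excluded(straight)
      }
      if (excluded) {
        note("excluded by quality check: ", id)
        status[[id]] <- "excluded"
      } else {
      write_projected(straight,
                      file.path(config$output_dir,
                                paste0(id, "_straight.tif")))
      rois <- detect_puncta(straight, config$params)
      mask <- attr(rois, "mask")
      tiff_write(list(mask * 255), file.path(config$output_dir,
                                             paste0(id, "_mask.tif")),
                 bits = 8L)
      write_rois_csv(rois, id, file.path(config$output_dir,
                                         paste0(id, "_rois.csv")))
      rec <- measure_puncta(straight, rois, config$replace_discarded)
      puncta[[id]] <- rec
      lengths[[id]] <- straightened_lengths(list(straight))
      note(sprintf("processed %s: %d puncta", id, nrow(rec)))
      status[[id]] <- "ok"
      }
      TRUE
    }, error = function(e) {
      note("FAILED ", id, ": ", conditionMessage(e))
      status[[id]] <<- paste0("failed: ", conditionMessage(e))
      FALSE
    })
  }

  empty_puncta <- measure_puncta(
    straightened_image(matrix(0, 1, 1)), list())
  combined <- if (length(puncta)) do.call(rbind, unname(puncta))
              else empty_puncta
  rownames(combined) <- NULL
  length_tab <- if (length(lengths)) do.call(rbind, unname(lengths))
                else data.frame(image_id = character(0), length = numeric(0),
                                units = character(0))
  density <- if (nrow(length_tab))
    compute_density(combined, length_tab,
                    config$include_discarded_in_density)
  else data.frame(image_id = character(0), n_puncta = integer(0),
                  length = numeric(0), density = numeric(0),
                  units = character(0))

  write_csv6(combined, file.path(config$output_dir, "puncta.csv"))
  write_csv6(density, file.path(config$output_dir, "density.csv"))
  write_csv6(length_tab, file.path(config$output_dir, "lengths.csv"))

  n_failed <- sum(grepl("^failed", unlist(status)))
  manifest <- list(
    package_version = as.character(utils::packageVersion("punctaline")),
    params = unclass(config$params),
    replace_discarded = config$replace_discarded,
    include_discarded_in_density = config$include_discarded_in_density,
    n_images = length(files), n_processed = sum(unlist(status) == "ok"),
    n_excluded = sum(unlist(status) == "excluded"), n_failed = n_failed,
    images = status)
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(loglines, logf)
  invisible(list(puncta = combined, density = density,
                 n_failed = n_failed, manifest = manifest))
}

#' Per-image (per-animal) summary
#'
#' Collapses the combined per-punctum table by image: punctum count (with or
#' without discarded rows), mean and median maximum intensity, and median
#' FWHM. Discarded rows are always excluded from the FWHM statistic (their
#' FWHM is a misfit); images where every punctum was discarded get `NA`
#' there.
#'
#' @param puncta combined data.frame from [run_pipeline()] /
#'   [measure_puncta()].
#' @param include_discarded count discarded puncta in `n_puncta`.
#' @return data.frame `image_id, n_puncta, mean_intensity, median_intensity,
#'   median_fwhm`, one row per image, sorted by `image_id`.
#' @export
aggregate_by_image <- function(puncta, include_discarded = TRUE) {
  ids <- sort(unique(puncta$image_id))
  do.call(rbind, lapply(ids, function(id) {
    d <- puncta[puncta$image_id == id, , drop = FALSE]
    counted <- if (include_discarded) d else d[d$discard == 0L, , drop = FALSE]
    good <- d[d$discard == 0L, , drop = FALSE]
    data.frame(image_id = id, n_puncta = nrow(counted),
               mean_intensity = if (nrow(counted)) mean(counted$max_intensity) else NA_real_,
               median_intensity = if (nrow(counted)) stats::median(counted$max_intensity) else NA_real_,
               median_fwhm = if (nrow(good)) stats::median(good$fwhm) else NA_real_)
  }))
}
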