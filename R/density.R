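#' Per-image puncta density
#'
#' Density = number of detected ROIs divided by the length of the
#' straightened image, per image. By default discarded (misfit) puncta still
#' count — they are regions of interest that exist before the FWHM check —
#' but `include_discarded = FALSE` matches the filtered reading.
#'
#' @param records per-punctum data.frame from [measure_puncta()] (or the
#'   combined multi-image table); needs columns `image_id` and `discard`.
#' @param lengths data.frame `image_id, length, units`: one row per image,
#'   straightened-image length (um when calibrated, else px), all > 0.
#'   Images with no detected puncta get density 0.
#' @param include_discarded count discarded puncta (default `TRUE`).
#' @return data.frame `image_id, n_puncta, length, density, units`, sorted
#'   by `image_id`.
#' @export
compute_density <- function(records, lengths, include_discarded = TRUE) {
  stopifnot(all(c("image_id", "discard") %in% names(records)),
            all(c("image_id", "length") %in% names(lengths)))
  if (any(lengths$length <= 0)) stop("straightened-image lengths must be > 0")
  missing <- setdiff(unique(records$image_id), lengths$image_id)
  if (length(missing))
    stop("no straightened length for image(s): ",
         paste(missing, collapse = ", "))
  kept <- if (include_discarded) records else records[records$discard == 0L, ]
  counts <- table(factor(kept$image_id, levels = sort(unique(lengths$image_id))))
  lengths <- lengths[order(lengths$image_id), , drop = FALSE]
  data.frame(image_id = lengths$image_id,
             n_puncta = as.integer(counts[lengths$image_id]),
             length = lengths$length,
             density = as.integer(counts[lengths$image_id]) / lengths$length,
             units = if ("units" %in% names(lengths)) lengths$units else "px",
             row.names = NULL)
}

#' Straightened-image length table
#'
#' Length = column count times pixel size (um) when calibrated, else column
#' count (px) — the literal length of the straightened image, which is the
#' density denominator.
#'
#' @param imgs list of [straightened_image] objects.
#' @return data.frame `image_id, length, units`.
#' @export
straightened_lengths <- function(imgs) {
  do.call(rbind, lapply(imgs, function(im) {
    ps <- im$pixel_size
    data.frame(image_id = im$image_id,
               length = ncol(im$pixels) * (if (is.null(ps)) 1 else ps),
               units = if (is.null(ps)) "px" else "um")
  }))
}

# CSV writer used for every tabular output: RFC-4180 with header, numerics
# at 6 significant digits, deterministic bytes for identical input.
write_csv6 <- function(df, path) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- signif(df[[j]], 6)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}
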