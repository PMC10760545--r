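#' Punctum detection parameters
#'
#' The four tunable settings of the detection stage, plus the Phansalkar
#' constants. `min_size` is interpreted as a calibrated area (um^2) when the
#' image carries a pixel size, else as px^2; `min_size_units` can force
#' either reading.
#'
#' @param min_size minimum accepted punctum area (um^2 if calibrated,
#'   else px^2).
#' @param sigma Gaussian blur standard deviation in pixels (0 = no blur).
#' @param radius local-threshold window radius in pixels.
#' @param method `"phansalkar"` (local adaptive) or `"otsu"` (global
#'   baseline).
#' @param phansalkar_k,phansalkar_r,phansalkar_p,phansalkar_q method
#'   constants; defaults are the ImageJ Auto Local Threshold plugin defaults.
#' @param connectivity 8 (default) or 4, for connected components.
#' @param min_size_units `"auto"` (um^2 when calibrated, px^2 otherwise),
#'   `"um2"`, or `"px2"`.
#' @return A `detection_params` object.
#' @export
detection_params <- function(min_size = 0.2, sigma = 1, radius = 6,
                             method = c("phansalkar", "otsu"),
                             phansalkar_k = 0.25, phansalkar_r = 0.5,
                             phansalkar_p = 2, phansalkar_q = 10,
                             connectivity = 8L,
                             min_size_units = c("auto", "um2", "px2")) {
  method <- match.arg(method)
  min_size_units <- match.arg(min_size_units)
  stopifnot(min_size >= 0, sigma >= 0, radius >= 1, connectivity %in% c(4L, 8L))
  structure(list(min_size = min_size, sigma = sigma, radius = radius,
                 method = method, phansalkar_k = phansalkar_k,
                 phansalkar_r = phansalkar_r, phansalkar_p = phansalkar_p,
                 phansalkar_q = phansalkar_q,
                 connectivity = as.integer(connectivity),
                 min_size_units = min_size_units),
            class = "detection_params")
}

#' Shipped detection presets
#'
#' Parameter sets tuned for two C. elegans reporters: `"nuIs24"`
#' (GLR-1::GFP, ventral cord: min size 0.2, sigma 1, radius 6, Phansalkar)
#' and `"nuIs152"` (GFP::SNB-1, dorsal cord: min size 0.3, sigma 0.75,
#' radius 1, Phansalkar). `"synthetic"` is the setting calibrated for the
#' package's standard synthetic fixture via the settings-grid preview
#' procedure (see the methods vignette): min size 0.35 um^2, sigma 3,
#' radius 15, Phansalkar.
#'
#' @param name preset name.
#' @return A [detection_params] object.
#' @export
detection_preset <- function(name = c("nuIs24", "nuIs152", "synthetic")) {
  name <- match.arg(name)
  switch(name,
    nuIs24 = detection_params(min_size = 0.2, sigma = 1, radius = 6,
                              method = "phansalkar"),
    nuIs152 = detection_params(min_size = 0.3, sigma = 0.75, radius = 1,
                               method = "phansalkar"),
    synthetic = detection_params(min_size = 0.35, sigma = 3, radius = 15,
                                 method = "phansalkar"))
}

# 1-px-step reflected padding indices (edge-inclusive: dcba|abcd|dcba)
reflect_idx <- function(n, pad) {
  if (pad == 0L) return(seq_len(n))
  left <- pmin(pmax(pad:1, 1L), n)
  right <- pmin(pmax(n:(n - pad + 1L), 1L), n)
  c(left, seq_len(n), right)
}

gaussian_kernel <- function(sigma) {
  rad <- max(1L, ceiling(4 * sigma))
  x <- (-rad):rad
  g <- exp(-x^2 / (2 * sigma^2))
  g / sum(g)
}

#' Gaussian blur
#'
#' Separable 2D Gaussian convolution with a normalized sampled kernel
#' (truncated at 4 sigma) and reflective boundary handling. `sigma = 0`
#' returns the image unchanged.
#'
#' @param img a 2D image.
#' @param sigma standard deviation in pixels, >= 0.
#' @return A blurred image of the same class and metadata.
#' @export
gaussian_blur <- function(img, sigma) {
  stopifnot(inherits(img, "image2d"))
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(img)
  g <- gaussian_kernel(sigma)
  pad <- (length(g) - 1L) %/% 2L
  m <- img$pixels
  # columns (blur along x)
  mp <- m[, reflect_idx(ncol(m), pad), drop = FALSE]
  out <- matrix(0, nrow(m), ncol(m))
  for (k in seq_along(g))
    out <- out + g[k] * mp[, k:(k + ncol(m) - 1L), drop = FALSE]
  # rows (blur along y)
  mp <- out[reflect_idx(nrow(m), pad), , drop = FALSE]
  out <- matrix(0, nrow(m), ncol(m))
  for (k in seq_along(g))
    out <- out + g[k] * mp[k:(k + nrow(m) - 1L), , drop = FALSE]
  img$pixels <- out
  img
}

disk_offsets <- function(radius) {
  d <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  d[d$dy^2 + d$dx^2 <= radius^2, , drop = FALSE]
}

#' Phansalkar local adaptive threshold
#'
#' Binarizes an image with the Phansalkar rule, designed for low-contrast
#' fluorescent/stained images. Intensities are first normalized to `[0, 1]`
#' by the bit-depth maximum; a pixel is foreground iff its normalized value
#' `t` exceeds
#' \deqn{\mu (1 + p e^{-q \mu} + k(\sigma/r - 1))}
#' where `mu` and `sigma` are the mean and population standard deviation of
#' normalized intensities over the circular window of the stated radius,
#' truncated to in-image pixels at the borders.
#'
#' @param img a 2D image (its `bit_depth` sets the normalization maximum).
#' @param radius window radius in pixels (>= 1).
#' @param k,r,p,q Phansalkar constants (ImageJ plugin defaults).
#' @return A logical matrix, `TRUE` = foreground.
#' @export
phansalkar_threshold <- function(img, radius = 6, k = 0.25, r = 0.5,
                                 p = 2, q = 10) {
  stopifnot(inherits(img, "image2d"), radius >= 1)
  tn <- img$pixels / norm_max(img$bit_depth)
  st <- local_stats(tn, radius)
  thr <- st$mean * (1 + p * exp(-q * st$mean) + k * (st$sd / r - 1))
  tn > thr
}

# Local mean and population SD over a truncated disk, by shift-accumulation.
local_stats <- function(tn, radius) {
  nr <- nrow(tn); nc <- ncol(tn)
  offs <- disk_offsets(radius)
  S <- matrix(0, nr, nc)
  S2 <- matrix(0, nr, nc)
  C <- matrix(0, nr, nc)
  tn2 <- tn^2
  for (i in seq_len(nrow(offs))) {
    dy <- offs$dy[i]; dx <- offs$dx[i]
    r_lo <- max(1L, 1L - dy); r_hi <- min(nr, nr - dy)
    c_lo <- max(1L, 1L - dx); c_hi <- min(nc, nc - dx)
    if (r_lo > r_hi || c_lo > c_hi) next
    rt <- r_lo:r_hi
    ct <- c_lo:c_hi
    S[rt, ct] <- S[rt, ct] + tn[rt + dy, ct + dx, drop = FALSE]
    S2[rt, ct] <- S2[rt, ct] + tn2[rt + dy, ct + dx, drop = FALSE]
    C[rt, ct] <- C[rt, ct] + 1
  }
  mu <- S / C
  list(mean = mu, sd = sqrt(pmax(S2 / C - mu^2, 0)))
}

#' Global Otsu threshold (baseline)
#'
#' Sanity-check alternative to local thresholding: one global cutoff chosen
#' to maximize between-class variance on a 256-bin histogram of normalized
#' intensities.
#'
#' @inheritParams phansalkar_threshold
#' @return A logical matrix, `TRUE` = foreground.
#' @export
otsu_threshold <- function(img) {
  stopifnot(inherits(img, "image2d"))
  tn <- img$pixels / norm_max(img$bit_depth)
  h <- tabulate(pmin(floor(tn * 256) + 1L, 256L), nbins = 256L)
  w <- h / sum(h)
  lev <- (seq_len(256L) - 0.5) / 256
  cw <- cumsum(w)
  cm <- cumsum(w * lev)
  mt <- cm[256]
  between <- (mt * cw - cm)^2 / (cw * (1 - cw))
  between[!is.finite(between)] <- 0
  thr <- lev[which.max(between)]
  tn > thr
}

# Run-based connected-component labelling with union-find.
label_components <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  parent <- integer(0)
  uf_find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  slack <- if (connectivity == 8L) 1L else 0L
  prev <- NULL  # matrix: start col, end col, label of previous row's runs
  for (rw in seq_len(nr)) {
    row <- mask[rw, ]
    if (!any(row)) { prev <- NULL; next }
    d <- diff(c(FALSE, row, FALSE))
    starts <- which(d == 1L)
    ends <- which(d == -1L) - 1L
    labs <- integer(length(starts))
    for (i in seq_along(starts)) {
      lab <- 0L
      if (!is.null(prev)) {
        hit <- which(prev[, 1] <= ends[i] + slack &
                     prev[, 2] >= starts[i] - slack)
        for (h in hit) {
          rt <- uf_find(prev[h, 3])
          if (lab == 0L) lab <- rt
          else if (rt != lab) parent[rt] <- lab
        }
      }
      if (lab == 0L) {
        parent[length(parent) + 1L] <- length(parent) + 1L
        lab <- length(parent)
      }
      labs[i] <- lab
      labels[rw, starts[i]:ends[i]] <- lab
    }
    prev <- cbind(starts, ends, labs)
  }
  if (length(parent)) {
    roots <- vapply(seq_along(parent), uf_find, integer(1))
    labels[labels > 0L] <- roots[labels[labels > 0L]]
  }
  labels
}

#' Extract punctum ROIs from a binary mask
#'
#' Labels connected foreground components, drops those below the minimum
#' area, and numbers the survivors left to right along the cord axis (by
#' bounding-box left edge; ties by top edge, then by first pixel in
#' row-major order).
#'
#' @param mask logical matrix from a thresholding step.
#' @param min_size minimum area; um^2 when `pixel_size` is given, else px^2.
#' @param pixel_size micrometres per pixel, or `NULL`.
#' @param connectivity 8 (default) or 4.
#' @return List of `punctum_roi` objects with fields `roi_id`, `pixel_set`
#'   (m x 2, 0-based row/col), `bbox` (`row0, col0, height, width`,
#'   half-open), `area`, `area_units`, `n_px`.
#' @export
find_puncta <- function(mask, min_size = 0, pixel_size = NULL,
                        connectivity = 8L) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  mask <- mask > 0
  labels <- label_components(mask, connectivity)
  ids <- setdiff(unique(as.vector(labels)), 0L)
  if (length(ids) == 0L) return(list())
  px_area <- if (is.null(pixel_size)) 1 else pixel_size^2
  area_units <- if (is.null(pixel_size)) "px2" else "um2"
  rois <- list()
  for (id in ids) {
    w <- which(labels == id, arr.ind = TRUE)  # 1-based (row, col)
    area <- nrow(w) * px_area
    if (area < min_size) next
    row0 <- min(w[, 1]) - 1L; col0 <- min(w[, 2]) - 1L
    h <- max(w[, 1]) - min(w[, 1]) + 1L
    wd <- max(w[, 2]) - min(w[, 2]) + 1L
    # first pixel in row-major order, for deterministic tie-breaking
    ord <- order(w[, 1], w[, 2])
    rois[[length(rois) + 1L]] <- structure(
      list(roi_id = NA_integer_,
           pixel_set = unname(w[ord, , drop = FALSE] - 1L),
           bbox = c(row0 = row0, col0 = col0, height = h, width = wd),
           area = area, area_units = area_units, n_px = nrow(w)),
      class = "punctum_roi")
  }
  if (length(rois) == 0L) return(list())
  key <- vapply(rois, function(r)
    r$bbox[["col0"]] * 1e12 + r$bbox[["row0"]] * 1e6 +
      r$pixel_set[1, 1] * 1e3 + r$pixel_set[1, 2], numeric(1))
  rois <- rois[order(key)]
  for (i in seq_along(rois)) rois[[i]]$roi_id <- i
  rois
}

#' Detect puncta in a straightened image
#'
#' The full detection stage: Gaussian blur (for threshold computation only),
#' local adaptive thresholding, connected components, minimum-size filter.
#' Deterministic for fixed inputs.
#'
#' @param img a [straightened_image].
#' @param params a [detection_params] (e.g. from [detection_preset()]).
#' @return List of punctum ROIs (see [find_puncta()]); the binary mask is
#'   attached as attribute `"mask"`.
#' @export
detect_puncta <- function(img, params = detection_params()) {
  stopifnot(inherits(img, "image2d"), inherits(params, "detection_params"))
  blurred <- gaussian_blur(img, params$sigma)
  mask <- switch(params$method,
    phansalkar = phansalkar_threshold(blurred, params$radius,
                                      params$phansalkar_k, params$phansalkar_r,
                                      params$phansalkar_p, params$phansalkar_q),
    otsu = otsu_threshold(blurred))
  ps <- switch(params$min_size_units,
    auto = img$pixel_size,
    um2 = { if (is.null(img$pixel_size)) stop("min_size in um2 needs a calibrated image"); img$pixel_size },
    px2 = NULL)
  rois <- find_puncta(mask, params$min_size, ps, params$connectivity)
  attr(rois, "mask") <- mask
  rois
}

#' Preview a grid of detection settings
#'
#' Runs detection under each parameter set and returns the masks and ROI
#' counts, for visual/tabular tuning before batch analysis. Optionally
#' writes the masks as pages of a contact-sheet TIFF (0/255).
#'
#' @param img a [straightened_image].
#' @param grid non-empty list of [detection_params].
#' @param contact_sheet optional path for a multi-page 8-bit mask TIFF.
#' @return List with `table` (data.frame of settings and ROI counts) and
#'   `masks` (list of logical matrices).
#' @export
preview_settings <- function(img, grid, contact_sheet = NULL) {
  stopifnot(length(grid) >= 1L)
  masks <- list()
  rows <- list()
  for (i in seq_along(grid)) {
    p <- grid[[i]]
    rois <- detect_puncta(img, p)
    masks[[i]] <- attr(rois, "mask")
    rows[[i]] <- data.frame(setting = i, min_size = p$min_size,
                            sigma = p$sigma, radius = p$radius,
                            method = p$method, n_rois = length(rois))
  }
  if (!is.null(contact_sheet))
    tiff_write(lapply(masks, function(m) m * 255), contact_sheet, bits = 8L)
  list(table = do.call(rbind, rows), masks = masks)
}

#' Write ROI list as CSV
#'
#' Columns: `image_id, roi_id, row0, col0, height, width, area, area_units`
#' (0-based half-open bounding boxes).
#'
#' @param rois list from [find_puncta()] or [detect_puncta()].
#' @param image_id image identifier for the first column.
#' @param path output CSV path.
#' @return The data.frame written, invisibly.
#' @export
write_rois_csv <- function(rois, image_id, path) {
  df <- rois_to_df(rois, image_id)
  write_csv6(df, path)
  invisible(df)
}

rois_to_df <- function(rois, image_id) {
  if (length(rois) == 0L)
    return(data.frame(image_id = character(0), roi_id = integer(0),
                      row0 = integer(0), col0 = integer(0),
                      height = integer(0), width = integer(0),
                      area = numeric(0), area_units = character(0)))
  do.call(rbind, lapply(rois, function(r) data.frame(
    image_id = image_id, roi_id = r$roi_id,
    row0 = r$bbox[["row0"]], col0 = r$bbox[["col0"]],
    height = r$bbox[["height"]], width = r$bbox[["width"]],
    area = r$area, area_units = r$area_units)))
}
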