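#' @keywords internal
"_PACKAGE"

norm_max <- function(bit_depth) {
  if (identical(bit_depth, "float")) 1 else 2^bit_depth - 1
}

#' Multi-plane grayscale image stack
#'
#' Container for a z-stack: a `planes x rows x cols` array of non-negative
#' intensities plus bit depth and optional spatial calibration.
#'
#' @param pixels 3D numeric array (planes, rows, cols) or a list of equal-size
#'   matrices (each a plane).
#' @param bit_depth 8, 16, or `"float"`.
#' @param pixel_size physical pixel size in micrometres per pixel, or `NULL`
#'   when uncalibrated (all downstream lengths and areas are then reported in
#'   pixels with a `"px"` units tag).
#' @param source_id identifier of the originating file.
#' @return An `image_stack` object.
#' @export
image_stack <- function(pixels, bit_depth = 16, pixel_size = NULL,
                        source_id = "") {
  if (is.list(pixels)) {
    dims <- vapply(pixels, dim, integer(2))
    stopifnot(all(dims == dims[, 1]))
    arr <- array(0, dim = c(length(pixels), dims[1, 1], dims[2, 1]))
    for (i in seq_along(pixels)) arr[i, , ] <- pixels[[i]]
    pixels <- arr
  }
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L)
  if (any(dim(pixels) < 1L)) stop("no planes")
  if (any(pixels < 0)) stop("image intensities must be non-negative")
  if (!identical(bit_depth, "float") && any(pixels > norm_max(bit_depth)))
    stop("intensities exceed ", bit_depth, "-bit range")
  if (!is.null(pixel_size) && pixel_size <= 0) stop("pixel_size must be > 0")
  structure(list(pixels = pixels, bit_depth = bit_depth,
                 pixel_size = pixel_size, source_id = source_id),
            class = "image_stack")
}

new_image2d <- function(pixels, bit_depth, pixel_size, image_id, class) {
  structure(list(pixels = pixels, bit_depth = bit_depth,
                 pixel_size = pixel_size, image_id = image_id),
            class = c(class, "image2d"))
}

#' 2D projected image
#'
#' @param pixels numeric matrix of intensities.
#' @inheritParams image_stack
#' @param image_id image identifier carried into all output tables.
#' @return A `projected_image` object.
#' @export
projected_image <- function(pixels, bit_depth = 16, pixel_size = NULL,
                            image_id = "") {
  stopifnot(is.matrix(pixels))
  new_image2d(pixels, bit_depth, pixel_size, image_id, "projected_image")
}

#' Straightened linescan image
#'
#' A 2D image whose horizontal axis is arc length along a traced path; rows
#' span the sampled width perpendicular to the path.
#'
#' @inheritParams projected_image
#' @return A `straightened_image` object.
#' @export
straightened_image <- function(pixels, bit_depth = 16, pixel_size = NULL,
                               image_id = "") {
  stopifnot(is.matrix(pixels), nrow(pixels) >= 1L, ncol(pixels) >= 1L)
  new_image2d(pixels, bit_depth, pixel_size, image_id, "straightened_image")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_stack '%s': %d plane(s), %d x %d, %s-bit%s>\n",
              x$source_id, d[1], d[2], d[3], x$bit_depth,
              if (is.null(x$pixel_size)) "" else
                sprintf(", %g um/px", x$pixel_size)))
  invisible(x)
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("<%s '%s': %d x %d, %s-bit%s>\n", class(x)[1], x$image_id,
              nrow(x$pixels), ncol(x$pixels), x$bit_depth,
              if (is.null(x$pixel_size)) "" else
                sprintf(", %g um/px", x$pixel_size)))
  invisible(x)
}

#' Maximum-intensity projection
#'
#' Collapses a z-stack to a 2D image by taking, at every (row, col), the
#' maximum intensity across planes. Bit depth and calibration are preserved;
#' a single-plane stack projects to itself.
#'
#' @param stack an [image_stack].
#' @return A [projected_image].
#' @export
max_project <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$pixels)
  if (d[1] < 1L) stop("no planes")
  out <- stack$pixels[1, , , drop = TRUE]
  if (!is.matrix(out)) out <- matrix(out, d[2], d[3])
  if (d[1] > 1L) {
    for (z in 2:d[1]) out <- pmax(out, matrix(stack$pixels[z, , ], d[2], d[3]))
  }
  projected_image(out, stack$bit_depth, stack$pixel_size, stack$source_id)
}

#' Read a grayscale TIFF into an image stack
#'
#' Reads single- or multi-page uncompressed grayscale 8/16-bit TIFF. Pixel
#' size is recovered from the XResolution/ResolutionUnit tags when present
#' (unit "none" is interpreted as pixels per micrometre, inch and cm per the
#' standard). Proprietary formats (.lif) must be exported to TIFF upstream.
#'
#' @param path path to a TIFF file.
#' @param image_id identifier; defaults to the file name without extension.
#' @return An [image_stack] with one plane per TIFF page.
#' @export
read_image <- function(path, image_id = NULL) {
  t <- tiff_read(path)
  if (is.null(image_id))
    image_id <- sub("\\.[^.]*$", "", basename(path))
  image_stack(t$pages, bit_depth = t$bits, pixel_size = t$pixel_size,
              source_id = image_id)
}

#' Write a 2D image as a single-page TIFF
#'
#' Writes an uncompressed grayscale baseline TIFF at the image's bit depth,
#' embedding resolution metadata when the image is calibrated. Reading the
#' file back recovers the pixels bit-exactly.
#'
#' @param img a [projected_image] or [straightened_image].
#' @param path output file path (parent directory must exist).
#' @return `path`, invisibly.
#' @export
write_projected <- function(img, path) {
  stopifnot(inherits(img, "image2d"))
  bits <- if (identical(img$bit_depth, "float")) 16L else as.integer(img$bit_depth)
  tiff_write(list(img$pixels), path, bits = bits, pixel_size = img$pixel_size)
}

#' Quality-control crop specification
#'
#' Non-interactive stand-in for manual image review: each image either passes
#' unchanged, is cropped to a stated rectangle, or is excluded from all
#' downstream tables.
#'
#' @param image_id image this spec applies to.
#' @param rectangle `c(row0, col0, height, width)` in pixels, 0-based,
#'   half-open; ignored when `keep = FALSE`.
#' @param keep `FALSE` excludes the image entirely.
#' @return A `crop_spec` object.
#' @export
crop_spec <- function(image_id, rectangle = NULL, keep = TRUE) {
  if (keep) {
    stopifnot(length(rectangle) == 4L, rectangle[3] >= 1, rectangle[4] >= 1,
              rectangle[1] >= 0, rectangle[2] >= 0)
  }
  structure(list(image_id = image_id, rectangle = rectangle, keep = keep),
            class = "crop_spec")
}

#' Apply a quality-control crop
#'
#' @param img a 2D image.
#' @param spec a [crop_spec] whose `image_id` matches the image.
#' @return The cropped image, or an object of class `excluded_image` when
#'   `spec$keep` is `FALSE`.
#' @export
apply_crop <- function(img, spec) {
  stopifnot(inherits(img, "image2d"), inherits(spec, "crop_spec"))
  if (!identical(spec$image_id, img$image_id))
    stop("crop spec for '", spec$image_id, "' applied to image '",
         img$image_id, "'")
  if (!spec$keep)
    return(structure(list(image_id = img$image_id), class = "excluded_image"))
  r <- spec$rectangle
  if (r[1] + r[3] > nrow(img$pixels) || r[2] + r[4] > ncol(img$pixels))
    stop("crop rectangle extends outside image '", img$image_id, "'")
  img$pixels <- img$pixels[(r[1] + 1):(r[1] + r[3]),
                           (r[2] + 1):(r[2] + r[4]), drop = FALSE]
  img
}

#' @export
is_excluded <- function(x) inherits(x, "excluded_image")
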