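#' Traced polyline path
#'
#' An ordered polyline tracing a linear structure (e.g. a nerve cord) across
#' a 2D image, together with the perpendicular width to sample when
#' straightening.
#'
#' @param image_id image the path belongs to.
#' @param vertices numeric matrix with columns `row`, `col` (0-based pixel
#'   coordinates, fractional allowed), at least two rows, consecutive
#'   vertices distinct.
#' @param width_px odd positive integer: number of samples taken
#'   perpendicular to the path, centred on it.
#' @return A `line_path` object.
#' @export
line_path <- function(image_id, vertices, width_px = 1L) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2L)
  if (nrow(vertices) < 2L) stop("a path needs at least 2 vertices")
  seg <- diff(vertices)
  seglen <- sqrt(rowSums(seg^2))
  if (any(seglen == 0)) stop("consecutive path vertices must be distinct")
  if (width_px < 1L || width_px %% 2L == 0L)
    stop("width_px must be an odd positive integer")
  structure(list(image_id = image_id, vertices = unname(vertices),
                 width_px = as.integer(width_px)),
            class = "line_path")
}

#' @export
print.line_path <- function(x, ...) {
  cat(sprintf("<line_path '%s': %d vertices, length %.2f px, width %d px>\n",
              x$image_id, nrow(x$vertices), path_length_px(x), x$width_px))
  invisible(x)
}

path_length_px <- function(path) {
  sum(sqrt(rowSums(diff(path$vertices)^2)))
}

#' Physical path length
#'
#' Sum of Euclidean vertex-to-vertex distances, converted to micrometres when
#' a pixel size is supplied; otherwise the pixel length is returned with a
#' `"px"` units attribute.
#'
#' @param path a [line_path].
#' @param pixel_size micrometres per pixel, or `NULL`.
#' @return Length in um (or px when uncalibrated), with a `units` attribute.
#' @export
path_length_um <- function(path, pixel_size = NULL) {
  l <- path_length_px(path)
  if (is.null(pixel_size)) return(structure(l, units = "px"))
  stopifnot(pixel_size > 0)
  structure(l * pixel_size, units = "um")
}

# Bilinear interpolation at 0-based fractional (r, c); out-of-bounds -> 0.
bilinear_sample <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  oob <- r < 0 | r > nr - 1 | c < 0 | c > nc - 1
  r0 <- pmax(pmin(floor(r), nr - 1), 0)
  c0 <- pmax(pmin(floor(c), nc - 1), 0)
  r1 <- pmin(r0 + 1, nr - 1)
  c1 <- pmin(c0 + 1, nc - 1)
  fr <- r - r0
  fc <- c - c0
  # incremental form: exact for constant neighborhoods and integer coords
  v00 <- m[cbind(r0 + 1, c0 + 1)]
  v01 <- m[cbind(r0 + 1, c1 + 1)]
  v10 <- m[cbind(r1 + 1, c0 + 1)]
  v11 <- m[cbind(r1 + 1, c1 + 1)]
  v <- v00 + fc * (v01 - v00) + fr * (v10 - v00) +
       fr * fc * (v00 + v11 - v01 - v10)
  v[oob] <- 0
  list(values = v, oob = oob)
}

#' Straighten an image along a traced path
#'
#' Resamples the image so that column `j` of the output is the perpendicular
#' cross-section of the source at arc length `j` pixels along the path
#' (bilinear interpolation, 1-px steps), producing a linescan whose
#' horizontal axis is distance along the traced structure. The output has
#' `width_px` rows and `round(total arc length)` columns. The perpendicular
#' at a sample is its segment's normal; samples falling exactly on an
#' interior vertex use the normalized bisector of the two adjacent segment
#' normals. Samples outside the image are filled with 0 (a warning is
#' issued once per call).
#'
#' @param img a [projected_image] (or any 2D image).
#' @param path a [line_path] in this image's coordinates.
#' @return A [straightened_image] inheriting bit depth and calibration.
#' @export
straighten <- function(img, path) {
  stopifnot(inherits(img, "image2d"), inherits(path, "line_path"))
  v <- path$vertices
  seg <- diff(v)
  seglen <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seglen))
  total <- cum[length(cum)]
  if (total <= 0) stop("path has zero length")
  n_cols <- max(1L, as.integer(round(total)))
  s <- seq_len(n_cols) - 1  # arc-length positions

  # segment index per sample (last sample of a closed interval stays in the
  # final segment)
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx[idx >= nrow(v)] <- nrow(v) - 1L
  t <- (s - cum[idx]) / seglen[idx]
  centre_r <- v[idx, 1] + t * seg[idx, 1]
  centre_c <- v[idx, 2] + t * seg[idx, 2]

  # unit normals per segment: rotate unit tangent (dr, dc) -> (dc, -dr), so
  # negative offsets (row 0) lie to the left of the direction of travel and a
  # left-to-right path keeps its rows in natural image order (crop identity)
  tan_r <- seg[, 1] / seglen
  tan_c <- seg[, 2] / seglen
  nrm_r <- tan_c
  nrm_c <- -tan_r
  smp_nr <- nrm_r[idx]
  smp_nc <- nrm_c[idx]
  # samples landing exactly on an interior vertex: bisector of adjacent normals
  if (nrow(v) > 2L) {
    for (k in 2:(nrow(v) - 1L)) {
      at <- which(abs(s - cum[k]) < 1e-9)
      if (length(at)) {
        b <- c(nrm_r[k - 1] + nrm_r[k], nrm_c[k - 1] + nrm_c[k])
        bl <- sqrt(sum(b^2))
        if (bl > 1e-12) {
          smp_nr[at] <- b[1] / bl
          smp_nc[at] <- b[2] / bl
        }
      }
    }
  }

  w <- path$width_px
  offsets <- seq_len(w) - 1 - (w - 1) / 2   # row 0 at -(w-1)/2 along normal
  rr <- outer(offsets, smp_nr) + matrix(centre_r, w, n_cols, byrow = TRUE)
  cc <- outer(offsets, smp_nc) + matrix(centre_c, w, n_cols, byrow = TRUE)
  smp <- bilinear_sample(img$pixels, as.vector(rr), as.vector(cc))
  if (all(smp$oob)) stop("path lies entirely outside image '",
                         img$image_id, "'")
  if (any(smp$oob))
    warning("straighten: some samples fell outside image '", img$image_id,
            "' and were zero-filled")
  out <- matrix(smp$values, w, n_cols)
  straightened_image(out, img$bit_depth, img$pixel_size, img$image_id)
}

#' Read polyline paths from CSV
#'
#' Expects columns `image_id, vertex_index, row, col, width_px` (0-based
#' coordinates), one row per vertex; multiple images may share a file.
#'
#' @param path CSV file path.
#' @return Named list of [line_path] objects, keyed by `image_id`.
#' @export
read_paths_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "vertex_index", "row", "col", "width_px")
  if (!all(need %in% names(df)))
    stop("path file '", path, "' must have columns: ",
         paste(need, collapse = ", "))
  out <- lapply(split(df, df$image_id), function(d) {
    d <- d[order(d$vertex_index), ]
    line_path(d$image_id[1], cbind(d$row, d$col), d$width_px[1])
  })
  out
}
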