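# Minimal baseline TIFF codec.
#
# Scope: uncompressed, strip-based, grayscale, 8- or 16-bit, single- or
# multi-page. Written files are little-endian with one strip per page and
# resolution stored as pixels/cm (ResolutionUnit = 3); the reader accepts both
# byte orders, multiple strips, and ResolutionUnit 1 (interpreted as
# pixels/um), 2 (inch) or 3 (cm). Anything else (compression, RGB, palettes,
# tiles, float samples) is rejected with an informative error rather than
# guessed at.

.TIFF_TYPE_SIZE <- c(1L, 1L, 2L, 4L, 8L, 1L, 1L, 2L, 4L, 8L, 4L, 8L)

.u_int <- function(raw, off, size, endian) {
  # off is a 0-based byte offset into raw
  v <- readBin(raw[(off + 1L):(off + size)], "integer",
               size = size, signed = size == 4L, endian = endian)
  if (size == 4L && v < 0) v <- v + 2^32
  if (size < 4L) {
    v <- readBin(raw[(off + 1L):(off + size)], "integer",
                 size = size, signed = FALSE, endian = endian)
  }
  v
}

.tiff_tag_values <- function(raw, entry_off, endian) {
  tag <- .u_int(raw, entry_off, 2L, endian)
  type <- .u_int(raw, entry_off + 2L, 2L, endian)
  count <- .u_int(raw, entry_off + 4L, 4L, endian)
  if (type < 1L || type > 12L) return(list(tag = tag, values = NULL))
  tsize <- .TIFF_TYPE_SIZE[type]
  total <- tsize * count
  voff <- if (total <= 4L) entry_off + 8L else .u_int(raw, entry_off + 8L, 4L, endian)
  vals <- switch(as.character(type),
    "1" = vapply(seq_len(count) - 1L, function(i) .u_int(raw, voff + i, 1L, endian), numeric(1)),
    "3" = vapply(seq_len(count) - 1L, function(i) .u_int(raw, voff + 2L * i, 2L, endian), numeric(1)),
    "4" = vapply(seq_len(count) - 1L, function(i) .u_int(raw, voff + 4L * i, 4L, endian), numeric(1)),
    "5" = vapply(seq_len(count) - 1L, function(i) {
      num <- .u_int(raw, voff + 8L * i, 4L, endian)
      den <- .u_int(raw, voff + 8L * i + 4L, 4L, endian)
      if (den == 0) NA_real_ else num / den
    }, numeric(1)),
    NULL)
  list(tag = tag, values = vals)
}

# Returns list(pages = list of numeric matrices, bits, pixel_size or NULL)
tiff_read <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': file does not exist")
  n <- file.info(path)$size
  raw <- readBin(path, "raw", n = n)
  if (length(raw) < 8L) stop("cannot read '", path, "': not a TIFF (too short)")
  order <- rawToChar(raw[1:2])
  endian <- if (order == "II") "little" else if (order == "MM") "big" else
    stop("cannot read '", path, "': not a TIFF (bad byte-order mark)")
  if (.u_int(raw, 2L, 2L, endian) != 42L)
    stop("cannot read '", path, "': not a TIFF (magic != 42)")

  pages <- list()
  bits_all <- integer(0)
  pixel_size <- NULL
  ifd_off <- .u_int(raw, 4L, 4L, endian)
  while (ifd_off != 0) {
    n_entries <- .u_int(raw, ifd_off, 2L, endian)
    tags <- list()
    for (i in seq_len(n_entries)) {
      ent <- .tiff_tag_values(raw, ifd_off + 2L + 12L * (i - 1L), endian)
      tags[[as.character(ent$tag)]] <- ent$values
    }
    g <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) default else v
    }
    width <- g(256); height <- g(257)
    if (is.null(width) || is.null(height))
      stop("cannot read '", path, "': TIFF page missing dimensions")
    bits <- g(258, 1)[1]
    if (!bits %in% c(8, 16))
      stop("cannot read '", path, "': unsupported bit depth ", bits,
           " (only 8- and 16-bit grayscale TIFF is supported)")
    if (g(259, 1) != 1)
      stop("cannot read '", path, "': compressed TIFF is not supported")
    photometric <- g(262, 1)
    if (!photometric %in% c(0, 1))
      stop("cannot read '", path, "': non-grayscale TIFF (photometric ",
           photometric, "), e.g. RGB, is not supported")
    if (g(277, 1) != 1)
      stop("cannot read '", path, "': multi-sample (RGB) TIFF is not supported")
    sample_format <- g(339, 1)[1]
    if (sample_format != 1)
      stop("cannot read '", path, "': non-integer sample format is not supported")

    strip_offsets <- g(273)
    strip_counts <- g(279)
    if (is.null(strip_offsets))
      stop("cannot read '", path, "': TIFF page has no pixel data strips")
    if (is.null(strip_counts))
      strip_counts <- rep(width * height * bits / 8 / length(strip_offsets),
                          length(strip_offsets))
    bytes <- raw(0)
    for (s in seq_along(strip_offsets)) {
      o <- strip_offsets[s]
      bytes <- c(bytes, raw[(o + 1L):(o + strip_counts[s])])
    }
    vals <- readBin(bytes, "integer", n = width * height,
                    size = bits / 8L, signed = FALSE, endian = endian)
    pages[[length(pages) + 1L]] <- matrix(as.numeric(vals), nrow = height,
                                          ncol = width, byrow = TRUE)
    bits_all <- c(bits_all, bits)

    xres <- g(282)
    if (!is.null(xres) && is.finite(xres) && xres > 0 && is.null(pixel_size)) {
      unit <- g(296, 2)
      per_um <- switch(as.character(unit),
        "1" = xres,            # unitless: pixels per micron by convention here
        "2" = xres / 25400,    # pixels per inch
        "3" = xres / 10000,    # pixels per cm
        NULL)
      if (!is.null(per_um) && per_um > 0) pixel_size <- 1 / per_um
    }
    ifd_off <- .u_int(raw, ifd_off + 2L + 12L * n_entries, 4L, endian)
  }
  if (length(pages) == 0L) stop("cannot read '", path, "': TIFF has no pages")
  if (length(unique(bits_all)) > 1L)
    stop("cannot read '", path, "': pages with mixed bit depths")
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("cannot read '", path, "': pages with mixed dimensions")
  list(pages = pages, bits = bits_all[1], pixel_size = pixel_size)
}

.w16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
.w32 <- function(x) {
  x <- as.numeric(x)
  lo <- x %% 65536
  hi <- (x - lo) / 65536
  c(.w16(lo), .w16(hi))
}
.tiff_entry <- function(tag, type, count, value) {
  # value: already-encoded 4 raw bytes, or a number encoded per type
  if (is.raw(value)) {
    v <- value
  } else if (type == 3L) {
    v <- c(.w16(value), as.raw(c(0, 0)))
  } else {
    v <- .w32(value)
  }
  c(.w16(tag), .w16(type), .w32(count), v)
}

tiff_write <- function(pages, path, bits = 16L, pixel_size = NULL) {
  stopifnot(is.list(pages), length(pages) >= 1L, bits %in% c(8L, 16L))
  vmax <- 2^bits - 1
  for (p in pages) {
    if (any(p < 0 | p > vmax))
      stop("pixel values out of range for ", bits, "-bit TIFF")
  }
  has_res <- !is.null(pixel_size)
  n_tags <- if (has_res) 12L else 9L
  ifd_size <- 2L + 12L * n_tags + 4L
  rat_size <- if (has_res) 16L else 0L

  # precompute per-page block offsets; layout per page: IFD | rationals | data
  offs <- vector("list", length(pages))
  cur <- 8L
  for (i in seq_along(pages)) {
    h <- nrow(pages[[i]]); w <- ncol(pages[[i]])
    dlen <- h * w * bits / 8L
    offs[[i]] <- list(ifd = cur, rat = cur + ifd_size,
                      data = cur + ifd_size + rat_size, dlen = dlen)
    cur <- cur + ifd_size + rat_size + dlen + dlen %% 2L
  }

  out <- list(charToRaw("II"), .w16(42L), .w32(offs[[1]]$ifd))
  if (has_res) {
    # pixels per cm, stored to 1e-4 precision
    res_num <- round(1e4 / pixel_size * 1e4)
    res_den <- 1e4
  }
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    h <- nrow(p); w <- ncol(p)
    o <- offs[[i]]
    next_ifd <- if (i < length(pages)) offs[[i + 1L]]$ifd else 0L
    entries <- c(
      .tiff_entry(256L, 4L, 1L, w),
      .tiff_entry(257L, 4L, 1L, h),
      .tiff_entry(258L, 3L, 1L, bits),
      .tiff_entry(259L, 3L, 1L, 1L),      # no compression
      .tiff_entry(262L, 3L, 1L, 1L),      # black is zero
      .tiff_entry(273L, 4L, 1L, o$data),
      .tiff_entry(277L, 3L, 1L, 1L),
      .tiff_entry(278L, 4L, 1L, h),
      .tiff_entry(279L, 4L, 1L, o$dlen))
    if (has_res) {
      entries <- c(entries,
        .tiff_entry(282L, 5L, 1L, o$rat),
        .tiff_entry(283L, 5L, 1L, o$rat + 8L),
        .tiff_entry(296L, 3L, 1L, 3L))    # centimeter
    }
    out[[length(out) + 1L]] <- c(.w16(n_tags), entries, .w32(next_ifd))
    if (has_res) {
      out[[length(out) + 1L]] <- c(.w32(res_num), .w32(res_den),
                                   .w32(res_num), .w32(res_den))
    }
    vals <- as.vector(t(p))  # row-major
    data <- writeBin(as.integer(round(vals)), raw(), size = bits / 8L,
                     endian = "little")
    if (o$dlen %% 2L == 1L) data <- c(data, as.raw(0L))
    out[[length(out) + 1L]] <- data
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(do.call(c, out), con)
  invisible(path)
}
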