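# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: per-pixel loops, flood fill, root bracketing.

# Phansalkar by explicit per-pixel recomputation over the circular window.
brute_phansalkar <- function(pixels, bits, radius, k = 0.25, r = 0.5,
                             p = 2, q = 10) {
  tn <- pixels / (2^bits - 1)
  nr <- nrow(tn); nc <- ncol(tn)
  span <- -radius:radius
  offs <- expand.grid(di = span, dj = span)
  offs <- offs[offs$di^2 + offs$dj^2 <= radius^2, ]
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      ii <- i + offs$di
      jj <- j + offs$dj
      ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
      vals <- tn[cbind(ii[ok], jj[ok])]
      mu <- mean(vals)
      sdv <- sqrt(mean((vals - mu)^2))
      out[i, j] <- tn[i, j] > mu * (1 + p * exp(-q * mu) + k * (sdv / r - 1))
    }
  }
  out
}

# 8-connected component count by stack-based flood fill.
flood_count <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  n <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j] || seen[i, j]) next
    n <- n + 1L
    stack <- matrix(c(i, j), 1)
    seen[i, j] <- TRUE
    while (nrow(stack)) {
      p <- stack[nrow(stack), ]
      stack <- stack[-nrow(stack), , drop = FALSE]
      for (di in -1:1) for (dj in -1:1) {
        ii <- p[1] + di; jj <- p[2] + dj
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            mask[ii, jj] && !seen[ii, jj]) {
          seen[ii, jj] <- TRUE
          stack <- rbind(stack, c(ii, jj))
        }
      }
    }
  }
  n
}

# Half-maximum crossing width of a fitted curve by root bracketing.
bracket_fwhm <- function(fit) {
  f <- function(x) fit$a + (fit$b - fit$a) * exp(-(x - fit$c)^2 / (2 * fit$d^2))
  half <- (fit$a + fit$b) / 2
  left <- stats::uniroot(function(x) f(x) - half, c(fit$c - 10 * fit$d, fit$c),
                         tol = 1e-12)$root
  right <- stats::uniroot(function(x) f(x) - half, c(fit$c, fit$c + 10 * fit$d),
                          tol = 1e-12)$root
  right - left
}

# Hand-built punctum ROI covering a full rectangle (0-based bbox).
rect_roi <- function(row0, col0, height, width, roi_id = 1L) {
  px <- as.matrix(expand.grid(row = row0:(row0 + height - 1L),
                              col = col0:(col0 + width - 1L)))
  px <- px[order(px[, 1], px[, 2]), , drop = FALSE]
  structure(list(roi_id = roi_id, pixel_set = unname(px),
                 bbox = c(row0 = row0, col0 = col0,
                          height = height, width = width),
                 area = height * width, area_units = "px2",
                 n_px = height * width),
            class = "punctum_roi")
}

# Small deterministic test image with smooth structure plus speckle.
toy_image <- function(nr, nc, seed, bits = 8) {
  set.seed(seed)
  base <- outer(seq_len(nr), seq_len(nc),
                function(i, j) 40 + 20 * sin(i / 3) * cos(j / 5))
  img <- base + matrix(stats::rnorm(nr * nc, 0, 6), nr, nc)
  img <- pmin(pmax(round(img), 0), 2^bits - 1)
  straightened_image(img, bits, NULL, sprintf("toy%d", seed))
}

# Standard synthetic fixture + its calibrated detection preset.
standard_fixture <- function(seed, ...) {
  generate_synthetic(synth_spec(seed = seed, ...))
}
fixture_params <- function() detection_preset("synthetic")

# Measurement table joined with ground truth by punctum order along the cord.
recovery_table <- function(gen, rec, img) {
  tt <- gen$truth[order(gen$truth$center_px), ]
  rec <- rec[order(rec$fwhm_center), ]
  scale <- if (is.null(img$pixel_size)) 1 else img$pixel_size
  data.frame(center_true = tt$center_px, center_fit = rec$fwhm_center,
             fwhm_true_px = tt$fwhm_px, fwhm_meas_px = rec$fwhm / scale)
}
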