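FWHM_FACTOR <- 2 * sqrt(2 * log(2))  # FWHM = 2*sqrt(2 ln 2) * sd

#' Horizontal intensity profile of an ROI
#'
#' One value per bounding-box column: the mean intensity over the box's rows
#' in that column, taken from the original (unblurred) straightened image —
#' the plot-profile of the ROI rectangle from its leftmost to rightmost side.
#'
#' @param img the original [straightened_image] the ROI was detected in.
#' @param roi a `punctum_roi`.
#' @return List with `positions` (0-based column indices) and `values`.
#' @export
extract_profile <- function(img, roi) {
  stopifnot(inherits(img, "image2d"), inherits(roi, "punctum_roi"))
  b <- roi$bbox
  if (b[["row0"]] + b[["height"]] > nrow(img$pixels) ||
      b[["col0"]] + b[["width"]] > ncol(img$pixels))
    stop("ROI bounding box outside image")
  rows <- (b[["row0"]] + 1):(b[["row0"]] + b[["height"]])
  cols <- (b[["col0"]] + 1):(b[["col0"]] + b[["width"]])
  vals <- colMeans(img$pixels[rows, cols, drop = FALSE])
  list(positions = cols - 1, values = unname(vals))
}

# Levenberg-Marquardt for y = a + (b - a) * exp(-(x - c)^2 / (2 d^2)).
# Deterministic: fixed initialization, no restarts, <= max_iter iterations,
# stops when the relative SSR improvement drops below tol.
lm_gauss <- function(x, y, max_iter = 1000L, tol = 1e-8) {
  a <- min(y); b <- max(y); c <- x[which.max(y)]
  d <- (max(x) - min(x)) / 4
  if (d <= 0) d <- 1
  theta <- c(a, b, c, d)
  model <- function(th) th[1] + (th[2] - th[1]) *
    exp(-(x - th[3])^2 / (2 * th[4]^2))
  ssr <- function(th) sum((y - model(th))^2)
  s0 <- ssr(theta)
  lambda <- 1e-3
  for (it in seq_len(max_iter)) {
    th <- theta
    E <- exp(-(x - th[3])^2 / (2 * th[4]^2))
    J <- cbind(1 - E,
               E,
               (th[2] - th[1]) * E * (x - th[3]) / th[4]^2,
               (th[2] - th[1]) * E * (x - th[3])^2 / th[4]^3)
    r <- y - model(th)
    jtj <- crossprod(J)
    g <- crossprod(J, r)
    step_ok <- FALSE
    for (try in 1:30) {
      A <- jtj + lambda * diag(diag(jtj) + 1e-12, 4)
      delta <- tryCatch(solve(A, g), error = function(e) NULL)
      if (!is.null(delta) && all(is.finite(delta))) {
        cand <- th + as.vector(delta)
        s1 <- ssr(cand)
        if (is.finite(s1) && s1 <= s0) {
          improve <- (s0 - s1) / max(s0, .Machine$double.eps)
          theta <- cand
          s0 <- s1
          lambda <- max(lambda / 10, 1e-12)
          step_ok <- TRUE
          if (improve < tol) {
            return(list(theta = theta, ssr = s0, converged = TRUE))
          }
          break
        }
      }
      lambda <- lambda * 10
      if (lambda > 1e12) break
    }
    if (!step_ok) return(list(theta = theta, ssr = s0, converged = TRUE))
  }
  list(theta = theta, ssr = s0, converged = TRUE)
}

#' Fit a Gaussian model to an intensity profile
#'
#' Unweighted least-squares fit of the 4-parameter peak model
#' `y(x) = a + (b - a) exp(-(x - c)^2 / (2 d^2))` (baseline `a`, peak value
#' `b`, centre `c`, standard deviation `d`), with deterministic
#' initialization (`a = min`, `b = max`, `c = argmax`, `d = span/4`).
#' Profiles shorter than 4 points, flat profiles, and optimizer failures
#' return `converged = FALSE`.
#'
#' @param profile list with `positions` and `values`, from
#'   [extract_profile()].
#' @return A `gaussian_fit` object with fields `a, b, c, d, converged`.
#' @export
fit_gaussian <- function(profile) {
  x <- profile$positions
  y <- profile$values
  fail <- structure(list(a = NA_real_, b = NA_real_, c = NA_real_,
                         d = NA_real_, converged = FALSE),
                    class = "gaussian_fit")
  if (length(x) < 4L || length(unique(y)) == 1L) return(fail)
  res <- tryCatch(lm_gauss(x, y), error = function(e) NULL)
  if (is.null(res) || !all(is.finite(res$theta))) return(fail)
  d <- abs(res$theta[4])
  if (!is.finite(d) || d <= 0) return(fail)
  structure(list(a = res$theta[1], b = res$theta[2], c = res$theta[3],
                 d = d, converged = res$converged),
            class = "gaussian_fit")
}

#' Full width at half maximum of a fitted Gaussian
#'
#' Closed form `2 sqrt(2 ln 2) d ~= 2.35482 d`, in pixels.
#'
#' @param fit a `gaussian_fit`.
#' @return FWHM in pixels; `NA` for a non-converged fit.
#' @export
fwhm_from_fit <- function(fit) {
  stopifnot(inherits(fit, "gaussian_fit"))
  if (!isTRUE(fit$converged)) return(NA_real_)
  FWHM_FACTOR * fit$d
}

#' Measure detected puncta
#'
#' For each ROI: bounding-box width, maximum intensity over the ROI's pixel
#' set (always from the original, unblurred image), and Gaussian-fit FWHM of
#' the horizontal profile. A record is flagged `discard = 1` when the fitted
#' FWHM exceeds the ROI width — the signature of a misfit (e.g. a profile
#' ascending strongly to one side with a sudden cut-off) — or when the fit
#' failed. With `replace_discarded = TRUE` such FWHM values are replaced by
#' the ROI width and `fwhm_replaced` is set.
#'
#' @param img the original [straightened_image].
#' @param rois ROI list from [detect_puncta()] on the same image.
#' @param replace_discarded replace misfit FWHM by the ROI width.
#' @return data.frame: `image_id, roi_id, roi_width, max_intensity, fwhm,
#'   fwhm_center, discard, fwhm_replaced, units`; widths/FWHM in um when the
#'   image is calibrated, else px.
#' @export
measure_puncta <- function(img, rois, replace_discarded = FALSE) {
  stopifnot(inherits(img, "image2d"))
  scale <- if (is.null(img$pixel_size)) 1 else img$pixel_size
  units <- if (is.null(img$pixel_size)) "px" else "um"
  out <- vector("list", length(rois))
  for (i in seq_along(rois)) {
    roi <- rois[[i]]
    prof <- extract_profile(img, roi)
    fit <- fit_gaussian(prof)
    fwhm_px <- fwhm_from_fit(fit)
    roi_width <- roi$bbox[["width"]] * scale
    fwhm <- fwhm_px * scale
    discard <- if (!isTRUE(fit$converged) || !is.finite(fwhm)) 1L
               else as.integer(fwhm > roi_width)
    replaced <- FALSE
    if (replace_discarded && discard == 1L) {
      fwhm <- roi_width
      replaced <- TRUE
    }
    mx <- max(img$pixels[roi$pixel_set + 1L])
    out[[i]] <- data.frame(
      image_id = img$image_id, roi_id = roi$roi_id, roi_width = roi_width,
      max_intensity = mx, fwhm = fwhm,
      fwhm_center = if (isTRUE(fit$converged)) fit$c * 1 else NA_real_,
      discard = discard, fwhm_replaced = replaced, units = units)
  }
  if (length(out) == 0L)
    return(data.frame(image_id = character(0), roi_id = integer(0),
                      roi_width = numeric(0), max_intensity = numeric(0),
                      fwhm = numeric(0), fwhm_center = numeric(0),
                      discard = integer(0), fwhm_replaced = logical(0),
                      units = character(0)))
  do.call(rbind, out)
}
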