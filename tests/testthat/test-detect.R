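test_that("gaussian_blur identities and impulse response", {
  img <- toy_image(12, 40, seed = 41)
  expect_equal(gaussian_blur(img, 0)$pixels, img$pixels)

  const <- straightened_image(matrix(5, 9, 30), 8)
  expect_equal(gaussian_blur(const, 2)$pixels, matrix(5, 9, 30),
               tolerance = 1e-12)

  # unit impulse: centre of blurred image = squared centre weight of the
  # sampled normalized kernel, computed here by explicit summation
  n <- 41L
  imp <- matrix(0, n, n)
  imp[21, 21] <- 1
  blurred <- gaussian_blur(straightened_image(imp, "float"), 1)
  x <- -4:4
  g <- exp(-x^2 / 2)
  g <- g / sum(g)
  k2 <- outer(g, g)
  expect_equal(blurred$pixels[21, 21], k2[5, 5], tolerance = 1e-12)
  expect_lt(abs(blurred$pixels[21, 21] - 1 / (2 * pi)), 5e-3)
  expect_error(gaussian_blur(img, -1), ">= 0")
})

test_that("phansalkar threshold matches the closed-form constant-image case", {
  # constant normalized value 0.5: threshold = 0.5*(1 + 2 exp(-5) - 0.25)
  img <- straightened_image(matrix(0.5, 10, 20), "float")
  expect_true(all(phansalkar_threshold(img, radius = 3)))
  thr <- 0.5 * (1 + 2 * exp(-5) + 0.25 * (0 / 0.5 - 1))
  expect_equal(thr, 0.3817, tolerance = 1e-4)
  # for dim constants the p-term dominates (multiplier > 1 iff mu < ~0.208),
  # so the threshold sits above the value itself: all background
  dim_img <- straightened_image(matrix(0.15, 10, 20), "float")
  thr_dim <- 0.15 * (1 + 2 * exp(-1.5) - 0.25)
  expect_gt(thr_dim, 0.15)
  expect_false(any(phansalkar_threshold(dim_img, radius = 3)))

  zero <- straightened_image(matrix(0, 8, 16), 8)
  expect_false(any(phansalkar_threshold(zero, radius = 6)))
})

test_that("phansalkar threshold equals the brute-force oracle", {
  set.seed(42)
  for (radius in c(1, 3, 6)) {
    img <- toy_image(14, 48, seed = 42 + radius)
    got <- phansalkar_threshold(img, radius = radius)
    want <- brute_phansalkar(img$pixels, 8, radius)
    expect_identical(got, want)
  }
})

test_that("find_puncta filters by size and matches the flood-fill oracle", {
  mask <- matrix(FALSE, 8, 20)
  mask[2:3, 2:3] <- TRUE       # 4 px
  mask[5:6, 10:11] <- TRUE     # 4 px
  mask[1, 18] <- TRUE          # 1 px
  rois <- find_puncta(mask, min_size = 2)
  expect_length(rois, 2)
  expect_equal(sapply(rois, function(r) r$n_px), c(4, 4))
  expect_length(find_puncta(matrix(FALSE, 4, 4)), 0)

  set.seed(43)
  for (k in 1:8) {
    m <- matrix(runif(16 * 64) < 0.35, 16, 64)
    rois <- find_puncta(m, min_size = 0)
    expect_identical(length(rois), flood_count(m))
    # ROIs partition the foreground
    all_px <- do.call(rbind, lapply(rois, function(r) r$pixel_set))
    expect_identical(nrow(all_px), sum(m))
    expect_identical(anyDuplicated(all_px), 0L)
  }
})

test_that("ROI ordering is left-to-right with deterministic tie-breaks", {
  mask <- matrix(FALSE, 10, 30)
  mask[7:8, 3:4] <- TRUE
  mask[2:3, 3:4] <- TRUE   # same left edge, higher up -> first
  mask[5, 20:24] <- TRUE
  rois <- find_puncta(mask)
  expect_equal(sapply(rois, function(r) r$roi_id), 1:3)
  expect_equal(sapply(rois, function(r) unname(r$bbox[["row0"]])), c(1, 6, 4))
  expect_equal(sapply(rois, function(r) unname(r$bbox[["col0"]])), c(2, 2, 19))
})

test_that("calibrated areas use um^2 and gate min_size accordingly", {
  mask <- matrix(FALSE, 10, 20)
  mask[4:6, 4:6] <- TRUE   # 9 px = 0.09 um^2 at 0.1 um/px
  expect_length(find_puncta(mask, min_size = 0.08, pixel_size = 0.1), 1)
  expect_length(find_puncta(mask, min_size = 0.10, pixel_size = 0.1), 0)
  r <- find_puncta(mask, pixel_size = 0.1)[[1]]
  expect_equal(r$area, 0.09)
  expect_equal(r$area_units, "um2")
})

test_that("detect_puncta recovers well-separated synthetic puncta", {
  g <- standard_fixture(seed = 44, n_puncta = 5, length_px = 400,
                        punctum_positions_px = c(60, 130, 200, 270, 340),
                        punctum_sigmas_px = rep(2, 5),
                        punctum_amplitudes = rep(120, 5))
  rois <- detect_puncta(g$image, fixture_params())
  expect_length(rois, 5)
  centers <- sapply(rois, function(r)
    r$bbox[["col0"]] + (r$bbox[["width"]] - 1) / 2)
  expect_true(all(abs(sort(centers) - g$truth$center_px) <= 1))

  none <- detect_puncta(g$image,
                        detection_params(min_size = 1e6, sigma = 3, radius = 15))
  expect_length(none, 0)

  # nuIs24 preset runs end-to-end without error on the standard fixture
  expect_no_error(detect_puncta(standard_fixture(101)$image,
                                detection_preset("nuIs24")))
})

test_that("ROI count is monotone non-increasing in min_size", {
  g <- standard_fixture(seed = 45)
  img <- g$image
  p <- fixture_params()
  counts <- sapply(c(0, 0.1, 0.35, 0.6, 1, 2), function(ms) {
    p$min_size <- ms
    length(detect_puncta(img, p))
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("detection is translation-equivariant along the cord axis", {
  delta <- 37
  pos <- c(80, 150, 230)
  mk <- function(shift) standard_fixture(
    seed = 46, n_puncta = 3, length_px = 500,
    punctum_positions_px = pos + shift,
    punctum_sigmas_px = c(1.8, 2.4, 2.9),
    punctum_amplitudes = c(100, 130, 90),
    background_noise_sd = 0)$image
  r0 <- detect_puncta(mk(0), fixture_params())
  r1 <- detect_puncta(mk(delta), fixture_params())
  expect_equal(length(r0), length(r1))
  expect_equal(sapply(r1, function(r) r$bbox[["col0"]]),
               sapply(r0, function(r) r$bbox[["col0"]]) + delta)
  expect_equal(sapply(r1, function(r) r$bbox[["width"]]),
               sapply(r0, function(r) r$bbox[["width"]]))
})

test_that("preview_settings reports one mask and count per setting", {
  g <- standard_fixture(seed = 47, length_px = 300, n_puncta = 4,
                        punctum_positions_px = c(50, 120, 190, 260))
  grid <- list(fixture_params(), detection_preset("nuIs24"),
               detection_params(min_size = 1e5, sigma = 3, radius = 15))
  pv <- preview_settings(g$image, grid)
  expect_equal(nrow(pv$table), 3)
  expect_length(pv$masks, 3)
  expect_equal(pv$table$n_rois[3], 0)
  dir <- withr::local_tempdir()
  sheet <- file.path(dir, "sheet.tif")
  preview_settings(g$image, grid, contact_sheet = sheet)
  st <- read_image(sheet)
  expect_equal(dim(st$pixels)[1], 3)
  expect_true(all(st$pixels %in% c(0, 255)))
})
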