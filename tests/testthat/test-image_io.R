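test_that("max_project takes the elementwise maximum across planes", {
  stack <- image_stack(list(matrix(c(1, 3, 2, 4), 2), matrix(c(4, 0, 1, 9), 2)),
                       bit_depth = 8)
  expect_equal(max_project(stack)$pixels, matrix(c(4, 3, 2, 9), 2))

  one <- image_stack(list(matrix(1:6, 2, 3)), bit_depth = 8, pixel_size = 0.2)
  p <- max_project(one)
  expect_equal(p$pixels, matrix(1:6, 2, 3), ignore_attr = TRUE)
  expect_equal(p$pixel_size, 0.2)

  const <- image_stack(list(matrix(5, 3, 3), matrix(7, 3, 3), matrix(6, 3, 3)),
                       bit_depth = 8)
  expect_true(all(max_project(const)$pixels == 7))
})

test_that("max_project dominates every plane and touches at least one", {
  set.seed(11)
  planes <- lapply(1:4, function(i) matrix(sample(0:255, 48, TRUE), 6, 8))
  stack <- image_stack(planes, bit_depth = 8)
  proj <- max_project(stack)
  for (p in planes) expect_true(all(proj$pixels >= p))
  hit <- Reduce(`|`, lapply(planes, function(p) proj$pixels == p))
  expect_true(all(hit))
  # idempotent when re-projected as a 1-plane stack
  again <- max_project(image_stack(list(proj$pixels), bit_depth = 8))
  expect_equal(again$pixels, proj$pixels)
})

test_that("TIFF write/read round-trips pixels bit-exactly for 8 and 16 bit", {
  dir <- withr::local_tempdir()
  set.seed(21)
  for (bits in c(8, 16)) {
    m <- matrix(sample(0:(2^bits - 1), 15 * 33, TRUE), 15, 33)
    m[1, 1] <- 0; m[15, 33] <- 2^bits - 1
    img <- projected_image(m, bits, pixel_size = 0.1, image_id = "rt")
    f <- file.path(dir, sprintf("rt%d.tif", bits))
    write_projected(img, f)
    back <- read_image(f)
    expect_equal(dim(back$pixels), c(1, 15, 33))
    expect_true(all(back$pixels[1, , ] == m))
    expect_equal(back$bit_depth, bits)
    expect_equal(back$pixel_size, 0.1)
  }
})

test_that("multi-page TIFFs round-trip as stacks", {
  dir <- withr::local_tempdir()
  set.seed(22)
  pages <- lapply(1:5, function(i) matrix(sample(0:65535, 40, TRUE), 5, 8))
  f <- file.path(dir, "stack.tif")
  punctaline:::tiff_write(pages, f, bits = 16L)
  st <- read_image(f)
  expect_equal(dim(st$pixels), c(5, 5, 8))
  for (i in 1:5) expect_true(all(st$pixels[i, , ] == pages[[i]]))
})

test_that("TIFF codec agrees with the tifffile reference implementation", {
  dir <- withr::local_tempdir()
  set.seed(23)
  m <- matrix(sample(0:65535, 9 * 14, TRUE), 9, 14)
  rfile <- file.path(dir, "r.tif")
  write_projected(projected_image(m, 16, 0.25, "x"), rfile)
  txt <- file.path(dir, "r.txt")
  py <- sprintf(paste0(
    "import tifffile, numpy as np\n",
    "a = tifffile.imread(%s)\n",
    "assert a.dtype == np.uint16\n",
    "np.savetxt(%s, a, fmt='%%d')\n",
    "b = (np.arange(77) %% 251).reshape(7, 11).astype(np.uint8)\n",
    "tifffile.imwrite(%s, b, photometric='minisblack',\n",
    "                 resolution=(10, 10), resolutionunit=1)\n"),
    deparse(rfile), deparse(txt), deparse(file.path(dir, "py.tif")))
  res <- system2("python", "-", input = py, stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(txt), info = paste(res, collapse = "\n"))
  ref <- as.matrix(utils::read.table(txt))
  expect_true(all(ref == m))
  # python-written file, resolution unit "none" read as pixels/um
  back <- read_image(file.path(dir, "py.tif"))
  expect_true(all(back$pixels[1, , ] == matrix(0:76 %% 251, 7, 11, byrow = TRUE)))
  expect_equal(back$pixel_size, 0.1)
})

test_that("unsupported files fail with the file named in the error", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.tif")
  writeBin(as.raw(1:20), bad)
  expect_error(read_image(bad), "bad.tif")
  py <- sprintf(paste0(
    "import tifffile, numpy as np\n",
    "rgb = np.zeros((4, 5, 3), dtype=np.uint8)\n",
    "tifffile.imwrite(%s, rgb, photometric='rgb')\n"),
    deparse(file.path(dir, "rgb.tif")))
  system2("python", "-", input = py, stdout = TRUE, stderr = TRUE)
  expect_error(read_image(file.path(dir, "rgb.tif")), "rgb.tif")
  expect_error(read_image(file.path(dir, "absent.tif")), "absent.tif")
})

test_that("apply_crop crops, excludes, and validates bounds", {
  m <- matrix(1:20, 4, 5)
  img <- projected_image(m, 8, 0.1, "img1")
  expect_true(is_excluded(apply_crop(img, crop_spec("img1", keep = FALSE))))
  full <- apply_crop(img, crop_spec("img1", c(0, 0, 4, 5)))
  expect_equal(full$pixels, m)
  sub <- apply_crop(img, crop_spec("img1", c(0, 0, 2, 3)))
  expect_equal(sub$pixels, m[1:2, 1:3])
  expect_equal(sub$pixel_size, 0.1)
  expect_error(apply_crop(img, crop_spec("img1", c(1, 1, 4, 5))), "outside")
  expect_error(apply_crop(img, crop_spec("other", c(0, 0, 1, 1))), "other")
})

test_that("container invariants are enforced", {
  expect_error(image_stack(array(-1, c(1, 2, 2)), 8), "non-negative")
  expect_error(image_stack(array(300, c(1, 2, 2)), 8), "8-bit")
  expect_error(image_stack(array(1, c(1, 2, 2)), 8, pixel_size = 0), "pixel_size")
})
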