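test_that("NIfTI round trip is lossless for values, spacing and origin", {
  v <- random_brainvol(c(10, 12, 14), spacing = c(0.2, 0.2, 0.2), seed = 11)
  v$grid$origin <- c(1.5, -2.25, 0.75)
  f <- tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  r <- read_volume(f, modality = "MR")
  expect_equal(r$values, v$values, tolerance = 1e-12)
  expect_equal(r$grid$spacing, v$grid$spacing, tolerance = 1e-6)
  expect_equal(r$grid$origin, v$grid$origin, tolerance = 1e-6)
  expect_equal(r$grid$shape, v$grid$shape)
})

test_that("label atlas round trip preserves exact integer labels", {
  set.seed(2)
  lv <- brainvol(array(sample(0:7, 9 * 8 * 7, TRUE), c(9, 8, 7)),
                 grid3d(c(9, 8, 7), 0.2), modality = "label")
  f <- tempfile(fileext = ".nii.gz")
  write_volume(lv, f)
  r <- read_volume(f, modality = "label")
  expect_identical(r$values, lv$values)
  expect_true(is.integer(r$values))
  # NIfTI-1 headers store geometry as 32-bit floats: exact to ~1e-7
  expect_equal(r$grid$spacing, c(0.2, 0.2, 0.2), tolerance = 1e-6)
})

test_that("a 100 um annotation-sized volume has the native reference extent", {
  ann <- brainvol(array(0L, c(132, 80, 114)), grid3d(c(132, 80, 114), 0.1),
                  modality = "annotation")
  expect_equal(sort(grid_extent(ann$grid)), sort(ara_native_box()$extent),
               tolerance = 1e-9)
})

test_that("unreadable and misoriented files raise the right errors", {
  txt <- tempfile(fileext = ".nii")
  writeLines("this is not an image", txt)
  expect_error(read_volume(txt), "format error")
  expect_error(read_volume(tempfile(fileext = ".nii.gz")), "not found")
  # oblique sform beyond tolerance -> geometry error
  arr <- array(rnorm(6 * 5 * 4), c(6, 5, 4))
  img <- RNifti::asNifti(arr)
  th <- 10 * pi / 180
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  aff <- structure(rbind(cbind(rot * 0.2, c(0, 0, 0)), c(0, 0, 0, 1)), code = 2L)
  RNifti::pixdim(img) <- c(0.2, 0.2, 0.2)
  img <- RNifti::`sform<-`(img, aff)
  img <- RNifti::`qform<-`(img, aff)
  f <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, f)
  expect_error(read_volume(f), "non-axis-aligned")
})

test_that("reading canonicalizes flipped/permuted orientations", {
  v <- random_brainvol(c(7, 6, 5), spacing = 0.3, seed = 4)
  f <- tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  ref <- read_volume(f, "MR")
  # store the same volume with the AP axis flipped and the matching affine
  M <- ccfpet:::ras_to_canonical()
  B <- ccfpet:::grid_affine_canonical(v$grid)
  Bf <- B
  Bf[1:3, 1] <- -B[1:3, 1]
  Bf[1:3, 4] <- B[1:3, 4] + B[1:3, 1] * (v$grid$shape[1] - 1)
  raff <- rbind(cbind(t(M) %*% Bf[1:3, 1:3], t(M) %*% Bf[1:3, 4]), c(0, 0, 0, 1))
  arr_f <- v$values[rev(seq_len(dim(v$values)[1])), , ]
  img <- RNifti::asNifti(arr_f)
  RNifti::pixdim(img) <- v$grid$spacing
  img <- RNifti::`sform<-`(img, structure(raff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(raff, code = 2L))
  f2 <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, f2)
  r <- read_volume(f2, "MR")
  expect_equal(r$values, ref$values, tolerance = 1e-6)
  expect_equal(r$grid$origin, ref$grid$origin, tolerance = 1e-6)
})

test_that("write failures and invalid label volumes are refused", {
  v <- random_brainvol()
  expect_error(write_volume(v, file.path(tempdir(), "no-such-dir", "x.nii")),
               "directory")
  lv <- brainvol(array(1L, c(3, 3, 3)), grid3d(c(3, 3, 3), 1), modality = "mask")
  lv$values <- array(NaN, c(3, 3, 3))   # corrupt after construction
  expect_error(write_volume(lv, tempfile(fileext = ".nii")), "non-finite")
  expect_error(brainvol(array(-1L, c(2, 2, 2)), grid3d(c(2, 2, 2), 1), modality = "label"),
               "non-negative")
})

test_that("NRRD reading handles raw and gzip encodings with spacing", {
  write_nrrd <- function(path, arr, encoding) {
    hdr <- c("NRRD0004",
             "type: int32",
             "dimension: 3",
             sprintf("sizes: %d %d %d", dim(arr)[1], dim(arr)[2], dim(arr)[3]),
             sprintf("encoding: %s", encoding),
             "endian: little",
             "space directions: (0.1,0,0) (0,0.1,0) (0,0,0.1)",
             "space origin: (0.05,0.05,0.05)",
             "")
    con <- file(path, "wb")
    writeLines(hdr, con)
    payload <- writeBin(as.integer(arr), raw(), size = 4, endian = "little")
    if (encoding == "gzip") payload <- memCompress(payload, "gzip")
    writeBin(payload, con)
    close(con)
  }
  set.seed(9)
  arr <- array(sample(0:99, 4 * 5 * 6, TRUE), c(4, 5, 6))
  for (enc in c("raw", "gzip")) {
    f <- tempfile(fileext = ".nrrd")
    write_nrrd(f, arr, enc)
    r <- read_volume(f, modality = "annotation")
    expect_identical(array(as.integer(r$values), dim(arr)), arr)
    expect_equal(r$grid$spacing, c(0.1, 0.1, 0.1), tolerance = 1e-9)
  }
  bad <- tempfile(fileext = ".nrrd")
  writeLines("not an nrrd", bad)
  expect_error(read_volume(bad), "format error")
})

test_that("resampling is exact on the identical grid and never invents labels", {
  v <- random_brainvol(c(8, 8, 8), spacing = 0.25, seed = 5)
  expect_identical(resample(v, v$grid, "trilinear")$values, v$values)
  cv <- brainvol(array(3.5, c(8, 8, 8)), grid3d(c(8, 8, 8), 0.2), "CT")
  tg <- grid3d(c(5, 5, 5), 0.3, origin = c(0.1, 0.1, 0.1))
  rc <- resample(cv, tg, "trilinear")
  inside <- abs(rc$values - 3.5) < 1e-12 | rc$values == 0
  expect_true(all(inside))
  expect_true(any(abs(rc$values - 3.5) < 1e-12))
  set.seed(6)
  lab <- brainvol(array(sample(c(0L, 2L, 5L, 9L), 10^3, TRUE), c(10, 10, 10)),
                  grid3d(c(10, 10, 10), 0.1), modality = "annotation")
  down <- resample(lab, grid3d(c(5, 5, 5), 0.2, origin = c(0.05, 0.05, 0.05)),
                   "nearest")
  back <- resample(down, lab$grid, "nearest")
  expect_true(all(unique(as.vector(down$values)) %in% unique(as.vector(lab$values))))
  expect_true(all(unique(as.vector(back$values)) %in% unique(as.vector(lab$values))))
  expect_error(resample(lab, down$grid, "trilinear"), "nearest")
})

test_that("embedding centres the volume, conserves mass and inverts by cropping", {
  shape <- c(132, 80, 114)
  set.seed(7)
  vals <- array(0, shape)
  vals[30:100, 20:60, 30:90] <- rexp(71 * 41 * 61)
  v <- brainvol(vals, grid3d(shape, 0.1), "CT")
  emb <- embed_in_box(v, extended_head_box(), 0.1)
  expect_equal(sort(emb$grid$shape), sort(c(161, 96, 121)))
  expect_equal(sum(emb$values), sum(v$values), tolerance = 0)
  back <- crop_to_shape(emb, shape)
  expect_equal(back$values, v$values, tolerance = 0)
  expect_equal(back$grid$origin, v$grid$origin, tolerance = 1e-9)
  small <- bounding_box(c(5, 5, 5))
  expect_error(embed_in_box(v, small), "smaller")
})
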