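# Image container, DICOM round trips, preprocessing, annotations.

test_that("scinti_image enforces its invariants", {
  expect_error(scinti_image(matrix(0L, 512, 512), "P", "anterior"),
               "expected 1024 x 256")
  expect_error(scinti_image(matrix(-1L, 1024, 256), "P", "anterior"),
               "\\[0, 65535\\]")
  expect_error(scinti_image(matrix(70000L, 1024, 256), "P", "anterior"),
               "\\[0, 65535\\]")
  img <- toy_image(downscale = 4L)
  expect_identical(dim(img$pixels), c(256L, 64L))
})

test_that("DICOM round-trip is the identity on the pixel matrix", {
  dir <- withr::local_tempdir()
  # zero image
  z <- toy_image(0L, downscale = 1L)
  f <- file.path(dir, "zero.dcm")
  write_scinti_dicom(z, f)
  expect_identical(read_scinti_dicom(f)$pixels, z$pixels)

  # single boundary pixel 65535
  b <- toy_image(0L, downscale = 1L)
  b$pixels[500, 100] <- 65535L
  write_scinti_dicom(b, f)
  rb <- read_scinti_dicom(f)
  expect_identical(rb$pixels[500, 100], 65535L)
  expect_identical(rb$pixels, b$pixels)

  # metadata travels in the header
  m <- noise_image(3, downscale = 4L, patient_id = "PX7",
                   view = "posterior", label = "arthritis")
  write_scinti_dicom(m, f)
  rm_ <- read_scinti_dicom(f)
  expect_identical(rm_$patient_id, "PX7")
  expect_identical(rm_$view, "posterior")
  expect_identical(rm_$label, "arthritis")
  expect_identical(rm_$downscale, 4L)
})

test_that("100 random images round-trip exactly and max counts survive", {
  dir <- withr::local_tempdir()
  ok <- 0L
  for (i in 1:100) {
    img <- noise_image(i, downscale = 8L, max_count = 4000L)
    f <- file.path(dir, sprintf("rt%03d.dcm", i))
    write_scinti_dicom(img, f)
    back <- read_scinti_dicom(f)
    if (identical(back$pixels, img$pixels)) ok <- ok + 1L
  }
  expect_identical(ok, 100L)
  img <- noise_image(5, downscale = 8L, max_count = 4000L)
  img$pixels[10, 10] <- 4000L
  f <- file.path(dir, "mx.dcm")
  write_scinti_dicom(img, f)
  expect_identical(max(read_scinti_dicom(f)$pixels), 4000L)
})

test_that("our DICOM files agree with an independent reader (pydicom)", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  dir <- withr::local_tempdir()
  img <- noise_image(11, downscale = 4L, patient_id = "CROSS1")
  f <- file.path(dir, "cross.dcm")
  write_scinti_dicom(img, f)
  out <- system2("python", c("-c", shQuote(paste0(
    "import pydicom; d = pydicom.dcmread('", f, "'); ",
    "a = d.pixel_array; ",
    "print(d.PatientID, d.Rows, d.Columns, int(a.sum()), int(a.max()))"))),
    stdout = TRUE)
  parts <- strsplit(out[length(out)], " ")[[1]]
  expect_identical(parts[1], "CROSS1")
  expect_identical(as.integer(parts[2:3]), dim(img$pixels))
  expect_identical(as.numeric(parts[4]), sum(as.numeric(img$pixels)))
  expect_identical(as.integer(parts[5]), max(img$pixels))
})

test_that("non-conforming pixel grids are rejected with the expected dims", {
  dir <- withr::local_tempdir()
  expect_error(read_scinti_dicom(file.path(dir, "nope.dcm")), "cannot read")

  # a downscale-2 grid is a valid integral reduction
  half <- scinti_image(matrix(0L, 512, 128), "P", "anterior", downscale = 2L)
  f2 <- file.path(dir, "half.dcm")
  write_scinti_dicom(half, f2)
  expect_identical(read_scinti_dicom(f2)$downscale, 2L)

  # forge a 512 x 512 monochrome file: not a reduction of (1024, 256)
  el <- dscint:::dcm_element
  pix <- dscint:::uint16le(integer(512 * 512))
  ds <- c(el(0x0028, 0x0010, "US", 512L), el(0x0028, 0x0011, "US", 512L),
          el(0x0028, 0x0100, "US", 16L), el(0x7FE0, 0x0010, "OW", pix))
  f3 <- file.path(dir, "sq.dcm")
  writeBin(c(raw(128), charToRaw("DICM"), ds), f3)
  expect_error(read_scinti_dicom(f3), "expected \\(1024, 256\\)")
})

test_that("gaussian correction preserves constants, mass and locality", {
  img <- toy_image(100L, downscale = 4L)
  out <- gaussian_correct(img)
  expect_identical(out$pixels, img$pixels)

  # impulse response: mass concentrated in the 3x3 neighborhood, center
  # dominant (hand evaluation of the normalized 3x3 kernel, sigma = 1/3:
  # adjacent weight = exp(-4.5), corner = exp(-9) relative to center)
  imp <- toy_image(0L, downscale = 4L)
  imp$pixels[100, 30] <- 900L
  sm <- gaussian_correct(imp)
  w <- exp(-c(0, 4.5, 9)) # center, edge, corner
  norm <- w[1] + 4 * w[2] + 4 * w[3]
  expect_identical(sm$pixels[100, 30], as.integer(round(900 * w[1] / norm)))
  expect_identical(sm$pixels[100, 31], as.integer(round(900 * w[2] / norm)))
  expect_identical(sm$pixels[99, 29], as.integer(round(900 * w[3] / norm)))
  expect_identical(sum(sm$pixels[98:102, 28:32]), sum(sm$pixels))

  # total-count preservation on a phantom
  ph <- tiny_cohort(1, seed = 3)$images[[1]]
  smp <- gaussian_correct(ph)
  expect_lt(abs(sum(as.numeric(smp$pixels)) - sum(as.numeric(ph$pixels))) /
              sum(as.numeric(ph$pixels)), 1e-3)

  # sigma -> 0 approaches the identity
  tiny <- gaussian_correct(ph, kernel_size = 3, sigma_px = 1e-6)
  expect_lte(max(abs(tiny$pixels - ph$pixels)), 1L)

  expect_error(gaussian_correct(img, kernel_size = 4), "odd")
})

test_that("normalization maps to [0,1] with max 1 and is scale-invariant", {
  img <- noise_image(2, downscale = 8L, max_count = 4000L)
  img$pixels[1, 1] <- 4000L
  nz <- normalize_image(img)
  expect_equal(max(nz), 1)
  expect_equal(min(nz), min(img$pixels) / 4000)
  expect_identical(dim(nz), c(dim(img$pixels), 1L))

  img3 <- img
  img3$pixels <- img$pixels * 3L
  expect_equal(normalize_image(img3), nz)

  zero <- toy_image(0L)
  expect_warning(nz0 <- normalize_image(zero), "all-zero")
  expect_true(all(nz0 == 0))
})

test_that("LabelMe annotations parse with majority-vote labelling", {
  f <- system.file("extdata", "example_annotations.json", package = "dscint")
  anns <- load_annotations(f)
  expect_length(anns, 2L)
  expect_length(anns[[1]]$regions, 3L)
  expect_length(anns[[2]]$regions, 2L)
  expect_true(anns[[1]]$positive) # 3 votes
  expect_true(anns[[2]]$positive) # 2 votes

  # zero shapes -> negative
  empty <- annotation("img0", list(), annotator_votes = 3L)
  expect_false(empty$positive)

  # one triangle, 3 votes -> positive
  tri <- annotation("img1", list(list(
    points = rbind(c(120, 130), c(130, 130), c(125, 145)),
    code = "thyroid_carcinoma")), annotator_votes = 3L)
  expect_true(tri$positive)

  # out-of-bounds polygon rejected
  expect_error(annotation("img2", list(list(
    points = rbind(c(-5, 10), c(10, 10), c(10, 30)), code = "x")),
    annotator_votes = 2L, image_dims = c(1024, 256)), "outside image bounds")
  # degenerate polygon rejected
  expect_error(annotation("img3", list(list(
    points = rbind(c(1, 1), c(2, 2)), code = "x")), 2L), ">= 3")

  # malformed JSON
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines("{ not json", bad)
  expect_error(load_annotations(bad), "malformed")

  # round trip through write_annotations
  out <- withr::local_tempfile(fileext = ".json")
  write_annotations(anns, out)
  back <- load_annotations(out)
  expect_length(back[[1]]$regions, 3L)
  expect_equal(back[[2]]$annotator_votes, 2L)
})

test_that("flipping one of three votes only matters at the 2-vote boundary", {
  for (pattern in 0:7) {
    votes <- as.logical(intToBits(pattern)[1:3])
    base <- majority_positive(votes)
    for (i in 1:3) {
      flipped <- votes
      flipped[i] <- !flipped[i]
      changed <- majority_positive(flipped) != base
      crosses <- (sum(votes) == 2 && !flipped[i]) ||
        (sum(votes) == 1 && flipped[i])
      expect_identical(changed, crosses)
    }
  }
})

test_that("block-sum downscaling preserves total counts", {
  img <- noise_image(4, downscale = 1L, max_count = 200L)
  d2 <- downscale_image(img, 2L)
  expect_identical(dim(d2$pixels), c(512L, 128L))
  expect_identical(sum(as.numeric(d2$pixels)), sum(as.numeric(img$pixels)))
  expect_identical(d2$downscale, 2L)
  expect_equal(d2$pixel_size_mm, 4.52)
})
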