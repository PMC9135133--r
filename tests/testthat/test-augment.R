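# Parametric variation operators and cohort rebalancing.

test_that("mirroring reverses columns, toggles the view, and is an involution", {
  img <- toy_image(0L, downscale = 4L)
  # plant the toy pattern [[1,2,3],[4,5,6]] in the top-left corner
  img$pixels[1:2, 1:3] <- rbind(c(1L, 2L, 3L), c(4L, 5L, 6L))
  m <- mirror_image(img)
  W <- ncol(img$pixels)
  expect_identical(m$pixels[1:2, W - (2:0)], rbind(c(3L, 2L, 1L),
                                                   c(6L, 5L, 4L)))
  expect_identical(m$view, "posterior")
  expect_identical(m$provenance, "mirrored")
  expect_identical(sort(as.vector(m$pixels)), sort(as.vector(img$pixels)))

  mm <- mirror_image(m)
  expect_identical(mm$pixels, img$pixels)
  expect_identical(mm$view, "anterior")

  # lesion centroid at column 61 (1-based; 0-based 60) maps to 0-based 195
  wide <- toy_image(0L, downscale = 1L)
  wide$pixels[500, 61] <- 1000L
  wm <- mirror_image(wide)
  expect_identical(which(wm$pixels == 1000L, arr.ind = TRUE)[1, "col"],
                   c(col = 196L)) # 0-based 195
})

test_that("translation shifts with zero fill and inverts under support bounds", {
  img <- toy_image(0L, downscale = 4L)
  img$pixels[1, 1:5] <- 1:5
  tr <- translate_image(img, 2L, "horizontal")
  expect_identical(tr$pixels[1, 1:5], c(0L, 0L, 1L, 2L, 3L))
  expect_identical(tr$provenance, "translated")

  t0 <- translate_image(img, 0L, "horizontal")
  expect_identical(t0$pixels, img$pixels)

  # +5 then -5 restores images whose support clears the border by 5 px
  mid <- toy_image(0L, downscale = 4L)
  mid$pixels[100:120, 20:40] <- 7L
  back <- translate_image(translate_image(mid, 5L, "vertical"), -5L,
                          "vertical")
  expect_identical(back$pixels, mid$pixels)

  expect_error(translate_image(img, 11L, "horizontal", t_max = 10L),
               "exceeds")
  # label and patient id are inherited
  expect_identical(tr$patient_id, img$patient_id)
  expect_identical(tr$label, img$label)
})

test_that("rotation is center-fixed, mass-preserving and bounded", {
  img <- toy_image(0L, downscale = 4L)
  r0 <- rotate_image(img, 0)
  expect_identical(r0$pixels, img$pixels)

  # bright square centered on the grid center keeps its centroid under 90 deg
  sq <- toy_image(0L, downscale = 4L)
  H <- nrow(sq$pixels); W <- ncol(sq$pixels)
  ci <- (H - 1) / 2; cj <- (W - 1) / 2 # 0-based center, x.5 on an even grid
  # 20 x 20 square symmetric about the rotation center
  sq$pixels[(ci + 1 - 9.5):(ci + 1 + 9.5), (cj + 1 - 9.5):(cj + 1 + 9.5)] <- 100L
  r90 <- rotate_image(sq, 90)
  centroid <- function(p) {
    w <- as.numeric(p)
    c(sum(row(p) * w), sum(col(p) * w)) / sum(w)
  }
  expect_lt(max(abs(centroid(r90$pixels) - centroid(sq$pixels))), 0.51)

  # small rotation keeps total counts within 1% when support clears borders
  ph <- toy_image(0L, downscale = 2L)
  ph$pixels[100:300, 50:78] <- 50L
  r3 <- rotate_image(ph, 3)
  s0 <- sum(as.numeric(ph$pixels))
  expect_lt(abs(sum(as.numeric(r3$pixels)) - s0) / s0, 0.01)

  expect_error(rotate_image(img, 6, r_max = 5), "exceeds")
  expect_identical(rotate_image(img, 3)$provenance, "rotated")

  # nearest-neighbor mode permutes values exactly for 90-degree rotation of
  # a centered square region
  rn <- rotate_image(sq, 90, interpolation = "nearest")
  expect_identical(sum(rn$pixels == 100L), sum(sq$pixels == 100L))
})

test_that("sampled variants are deterministic given the seed and uniform", {
  img <- noise_image(1, downscale = 8L)
  cfg <- augment_config(t_max = 5L, r_max = 5)

  set.seed(99); a <- sample_augmentation(img, cfg)
  set.seed(99); b <- sample_augmentation(img, cfg)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$provenance, b$provenance)

  # degenerate config: output equals input, provenance still updated
  cfg0 <- augment_config(t_max = 0L, r_max = 0)
  set.seed(1); z <- sample_augmentation(img, cfg0)
  expect_identical(z$pixels, img$pixels)
  expect_true(z$provenance %in% c("translated", "rotated"))

  # 1000 translation draws: each signed magnitude within 3 binomial SEs of
  # uniform on {-5..5}. The drawn shift is recovered from a tracer pixel.
  tracer <- toy_image(0L, downscale = 8L)
  tracer$pixels[100, 20] <- 1000L
  set.seed(7)
  ts <- integer(0)
  while (length(ts) < 1000) {
    out <- sample_augmentation(tracer, cfg)
    if (out$provenance != "translated") next
    pos <- which(out$pixels == 1000L, arr.ind = TRUE)
    ts <- c(ts, if (pos[1, "row"] == 100L) pos[1, "col"] - 20L
            else pos[1, "row"] - 100L)
  }
  counts <- table(factor(ts, levels = -5:5))
  p <- 1 / 11
  se <- sqrt(1000 * p * (1 - p))
  expect_true(all(abs(counts - 1000 * p) <= 3 * se))
})

test_that("cohort rebalancing reproduces the reference class counts exactly", {
  src <- counts_cohort(c(334L, 174L, 252L, 318L))
  targets <- c(normal = 1660L, metastasis = 1582L, arthritis = 1500L,
               thyroid_carcinoma = 1788L)
  cfg <- augment_config(t_max = 3L, r_max = 5, targets = targets, seed = 21L)
  aug <- augment_cohort(src, cfg)
  got <- table(factor(vapply(aug, function(x) x$label, character(1)),
                      levels = class_labels()))
  expect_identical(as.integer(got), unname(targets))

  # balance ratio improves: 1.92 -> 1.19
  before <- c(334, 174, 252, 318)
  expect_equal(max(before) / min(before), 1.92, tolerance = 0.01)
  expect_equal(max(targets) / min(targets), 1.19, tolerance = 0.01)

  # augmented images keep their source patient ids
  src_pids <- unique(vapply(src, function(x) x$patient_id, character(1)))
  aug_pids <- unique(vapply(aug, function(x) x$patient_id, character(1)))
  expect_true(all(aug_pids %in% src_pids))

  # deterministic given the seed
  aug2 <- augment_cohort(src, cfg)
  expect_identical(vapply(aug2, function(x) x$provenance, character(1)),
                   vapply(aug, function(x) x$provenance, character(1)))
})

test_that("already-balanced cohorts pass through and missing views mirror", {
  src <- counts_cohort(c(4L, 4L, 4L, 4L))
  cfg <- augment_config(targets = c(normal = 4L, metastasis = 4L,
                                    arthritis = 4L, thyroid_carcinoma = 4L),
                        seed = 5L)
  expect_length(augment_cohort(src, cfg), length(src))

  # a patient with only an anterior view gains exactly one mirrored posterior
  solo <- noise_image(50, downscale = 16L, patient_id = "SOLO",
                      view = "anterior", label = "normal")
  out <- augment_cohort(c(src, list(solo)), augment_config(seed = 5L))
  added <- out[(length(src) + 2L):length(out)]
  expect_length(added, 1L)
  expect_identical(added[[1]]$patient_id, "SOLO")
  expect_identical(added[[1]]$view, "posterior")
  expect_identical(added[[1]]$provenance, "mirrored")

  # unlabelled images are rejected
  bad <- solo
  bad$label <- NA_character_
  expect_error(augment_cohort(list(bad, solo), augment_config(seed = 1L)),
               "labelled")
})

test_that("operators preserve dtype range, dimensions and identity metadata", {
  img <- noise_image(9, downscale = 8L, label = "metastasis",
                     patient_id = "KEEP")
  for (op in list(function(x) mirror_image(x),
                  function(x) translate_image(x, 3L, "vertical"),
                  function(x) rotate_image(x, 4.5))) {
    out <- op(img)
    expect_identical(dim(out$pixels), dim(img$pixels))
    expect_true(all(out$pixels >= 0L & out$pixels <= 65535L))
    expect_identical(out$patient_id, "KEEP")
    expect_identical(out$label, "metastasis")
  }
})
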