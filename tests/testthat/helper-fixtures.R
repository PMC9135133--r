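# Shared fixtures: small phantom images and toy scinti_images built in code.

# a tiny valid scinti_image on a downscaled grid (1024/f x 256/f)
toy_image <- function(fill = 0L, downscale = 8L, patient_id = "T1",
                      view = "anterior", label = "normal") {
  d <- c(1024L, 256L) / downscale
  scinti_image(matrix(as.integer(fill), d[1], d[2]), patient_id = patient_id,
               view = view, label = label, downscale = downscale)
}

# deterministic pseudo-random counts image
noise_image <- function(seed = 1, downscale = 8L, max_count = 4000L, ...) {
  set.seed(seed)
  d <- c(1024L, 256L) / downscale
  px <- matrix(sample.int(max_count + 1L, prod(d), replace = TRUE) - 1L,
               d[1], d[2])
  img <- toy_image(downscale = downscale, ...)
  img$pixels <- px
  img
}

# small phantom cohort (shared template construction is the slow part)
tiny_cohort <- function(n_per_class = 2, seed = 7, downscale = 4L, ...) {
  generate_cohort(phantom_config(n_per_class = n_per_class, seed = seed, ...),
                  downscale = downscale)
}

# build a synthetic labelled image list with given (even) per-class counts;
# images are tiny (64 x 16) so dataset-level operations stay fast. Each
# patient contributes an anterior and a posterior view, so missing-view
# mirroring is a no-op and rebalancing alone controls the counts.
counts_cohort <- function(counts, downscale = 16L) {
  stopifnot(all(counts %% 2 == 0))
  imgs <- list()
  k <- 0L
  for (ci in seq_along(class_labels())) {
    for (i in seq_len(counts[ci] / 2)) {
      pid <- sprintf("C%d_%04d", ci, i)
      for (v in c("anterior", "posterior")) {
        k <- k + 1L
        img <- noise_image(seed = k, downscale = downscale, max_count = 100L,
                           patient_id = pid, view = v,
                           label = class_labels()[ci])
        imgs[[k]] <- img
      }
    }
  }
  imgs
}

expect_images_equal <- function(a, b) {
  expect_identical(a$pixels, b$pixels)
}
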