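# Parametric-variation augmentation: mirroring (missing-view completion),
# integer translation and small rotation, plus dataset-level rebalancing.
# Border policy is zero fill throughout: counts are physically absent outside
# the detector.

#' Augmentation configuration
#'
#' @param t_max Maximum translation magnitude in pixels (`t` is drawn
#'   uniformly on the integers `[-t_max, t_max]`). Must stay below a quarter
#'   of the smaller image dimension so anatomy remains in frame.
#' @param r_max Maximum rotation magnitude in degrees (`r` uniform on
#'   `[-r_max, r_max]`), at most 15.
#' @param targets Named integer vector, per-class target image counts after
#'   rebalancing (names from [class_labels()]).
#' @param seed RNG seed making the augmentation pass reproducible.
#' @return An object of class `"augment_config"`.
#' @export
augment_config <- function(t_max = 10L, r_max = 5, targets = NULL, seed = 1L) {
  t_max <- as.integer(t_max)
  if (t_max < 0L || t_max >= min(native_dims()) / 4)
    stop("t_max must be a non-negative integer below min(image dims)/4")
  if (r_max < 0 || r_max > 15) stop("r_max must lie in [0, 15] degrees")
  if (!is.null(targets)) {
    if (is.null(names(targets)) || !all(names(targets) %in% class_labels()))
      stop("targets must be named by class label")
    if (any(targets < 1)) stop("targets must be positive")
  }
  structure(list(t_max = t_max, r_max = r_max, targets = targets,
                 seed = as.integer(seed)),
            class = "augment_config")
}

stamp <- function(image, provenance) {
  image$provenance <- provenance
  image
}

#' Mirror a scintigram along its vertical centerline
#'
#' Reverses the image right-to-left (column `j` maps to `width - 1 - j`) and
#' toggles the view flag, producing the posterior counterpart of an anterior
#' view and vice versa. The pixel multiset is preserved exactly.
#'
#' @param image A [scinti_image()].
#' @return The mirrored `scinti_image` with provenance `"mirrored"`.
#' @export
mirror_image <- function(image) {
  validate_scinti_image(image)
  image$pixels <- image$pixels[, ncol(image$pixels):1, drop = FALSE]
  image$view <- setdiff(view_levels(), image$view)
  stamp(image, "mirrored")
}

#' Translate a scintigram by a whole number of pixels
#'
#' Shifts content by `t` pixels along the chosen axis; vacated pixels are
#' zero-filled and content shifted past the border is discarded.
#'
#' @param image A [scinti_image()].
#' @param t Signed integer shift. Positive moves content toward higher
#'   row/column index.
#' @param axis `"horizontal"` (columns) or `"vertical"` (rows).
#' @param t_max Optional magnitude bound; `|t| > t_max` is an error.
#' @return The shifted `scinti_image` with provenance `"translated"`.
#' @export
translate_image <- function(image, t, axis = c("horizontal", "vertical"),
                            t_max = NULL) {
  validate_scinti_image(image)
  axis <- match.arg(axis)
  t <- as.integer(t)
  if (!is.null(t_max) && abs(t) > t_max)
    stop(sprintf("|t| = %d exceeds the configured maximum %d", abs(t),
                 as.integer(t_max)))
  p <- image$pixels
  if (t != 0L) {
    out <- matrix(0L, nrow(p), ncol(p))
    if (axis == "horizontal") {
      src <- seq_len(ncol(p)) - t
      keep <- src >= 1L & src <= ncol(p)
      out[, keep] <- p[, src[keep]]
    } else {
      src <- seq_len(nrow(p)) - t
      keep <- src >= 1L & src <= nrow(p)
      out[keep, ] <- p[src[keep], ]
    }
    image$pixels <- out
  }
  stamp(image, "translated")
}

#' Rotate a scintigram about its geometric center
#'
#' Rotates by `r_deg` degrees about the pixel-grid center
#' `((H-1)/2, (W-1)/2)` with bilinear interpolation (nearest-neighbor by
#' flag), zero fill outside the frame, and re-quantization to integer counts
#' by rounding.
#'
#' @param image A [scinti_image()].
#' @param r_deg Signed rotation in degrees.
#' @param r_max Optional magnitude bound; `|r_deg| > r_max` is an error.
#' @param interpolation `"bilinear"` or `"nearest"`.
#' @return The rotated `scinti_image` with provenance `"rotated"`.
#' @export
rotate_image <- function(image, r_deg, r_max = NULL,
                         interpolation = c("bilinear", "nearest")) {
  validate_scinti_image(image)
  interpolation <- match.arg(interpolation)
  if (!is.null(r_max) && abs(r_deg) > r_max)
    stop(sprintf("|r| = %g degrees exceeds the configured maximum %g",
                 abs(r_deg), r_max))
  if (r_deg != 0) {
    p <- as.double(image$pixels)
    H <- nrow(image$pixels); W <- ncol(image$pixels)
    ci <- (H - 1) / 2; cj <- (W - 1) / 2
    a <- r_deg * pi / 180
    DI <- rep(0:(H - 1) - ci, times = W)
    DJ <- rep(0:(W - 1) - cj, each = H)
    si <- ci + cos(a) * DI + sin(a) * DJ
    sj <- cj - sin(a) * DI + cos(a) * DJ
    gather <- function(ii, jj) {
      v <- numeric(length(ii))
      ok <- ii >= 0 & ii < H & jj >= 0 & jj < W
      v[ok] <- p[ii[ok] + H * jj[ok] + 1]
      v
    }
    if (interpolation == "nearest") {
      out <- gather(round(si), round(sj))
    } else {
      i0 <- floor(si); j0 <- floor(sj)
      fi <- si - i0; fj <- sj - j0
      out <- (1 - fi) * (1 - fj) * gather(i0, j0) +
        fi * (1 - fj) * gather(i0 + 1, j0) +
        (1 - fi) * fj * gather(i0, j0 + 1) +
        fi * fj * gather(i0 + 1, j0 + 1)
    }
    image$pixels <- matrix(as.integer(pmin(pmax(round(out), 0), 65535)), H, W)
  }
  stamp(image, "rotated")
}

#' Draw one random parametric variant of an image
#'
#' Picks translation or rotation with equal probability, then the magnitude
#' and sign uniformly: `t` on the integers `[-t_max, t_max]`, `r` on the real
#' interval `[-r_max, r_max]`. Deterministic given the R RNG state.
#'
#' @param image A [scinti_image()].
#' @param config An [augment_config()].
#' @return A transformed `scinti_image`.
#' @export
sample_augmentation <- function(image, config) {
  stopifnot(inherits(config, "augment_config"))
  if (sample.int(2L, 1L) == 1L) {
    ts <- seq(-config$t_max, config$t_max)
    t <- ts[sample.int(length(ts), 1L)]
    axis <- c("horizontal", "vertical")[sample.int(2L, 1L)]
    translate_image(image, t, axis, t_max = config$t_max)
  } else {
    r <- stats::runif(1, -config$r_max, config$r_max)
    rotate_image(image, r, r_max = config$r_max)
  }
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Augment a labelled cohort and rebalance class counts
#'
#' Two stages, both reproducible given `config$seed`: (1) every examination
#' with a single recorded view gains the mirrored counterpart view; (2) each
#' class is topped up to its target count by cycling round-robin over that
#' class's source images, adding one random translate/rotate variant per
#' pass. Augmented images inherit their source's `patient_id` and label, so
#' patient-grouped splitting stays leak-free, and the max/min class-count
#' ratio never increases.
#'
#' @param dataset List of labelled [scinti_image()]s.
#' @param config An [augment_config()]; if `targets` is `NULL` only
#'   missing-view mirroring is performed.
#' @return List of `scinti_image`s (sources plus additions).
#' @export
augment_cohort <- function(dataset, config) {
  stopifnot(inherits(config, "augment_config"))
  labs <- vapply(dataset, function(x) x$label, character(1))
  if (anyNA(labs)) stop("augment_cohort requires every source image labelled")

  with_seed(config$seed, {
    out <- dataset
    # stage 1: missing-view completion by mirroring
    pid <- vapply(dataset, function(x) x$patient_id, character(1))
    for (id in unique(pid)) {
      views <- unique(vapply(dataset[pid == id], function(x) x$view,
                             character(1)))
      if (length(views) == 1L) {
        src <- dataset[[which(pid == id)[1]]]
        out[[length(out) + 1L]] <- mirror_image(src)
      }
    }
    if (!is.null(config$targets)) out <- rebalance_classes(out, dataset,
                                                           labs, config)
    out
  })
}

rebalance_classes <- function(out, dataset, labs, config) {
  counts <- table(factor(vapply(out, function(x) x$label, character(1)),
                         levels = class_labels()))
  before_ratio <- max(counts) / min(counts)
  for (cls in names(config$targets)) {
    target <- config$targets[[cls]]
    have <- sum(vapply(out, function(x) x$label, character(1)) == cls)
    if (target < have)
      stop(sprintf("class '%s': target %d below current count %d",
                   cls, target, have))
    sources <- dataset[labs == cls]
    if (target > have && length(sources) == 0L)
      stop(sprintf("class '%s' has no source images to augment", cls))
    i <- 0L
    while (have < target) {
      i <- i %% length(sources) + 1L
      out[[length(out) + 1L]] <- sample_augmentation(sources[[i]], config)
      have <- have + 1L
    }
  }
  after <- table(factor(vapply(out, function(x) x$label, character(1)),
                        levels = class_labels()))
  stopifnot(max(after) / min(after) <= before_ratio + 1e-12)
  out
}
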