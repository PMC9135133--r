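#' A single planar scintigraphic view
#'
#' Container for one whole-body planar bone-scintigraphy acquisition: a
#' 1024-row by 256-column matrix of radiotracer counts (16-bit unsigned
#' range), stored row-major anatomically top-to-bottom, together with the
#' patient identifier, the view (anterior/posterior), the diagnostic class
#' label and the physical pixel size.
#'
#' Rows run superior to inferior (1024), columns patient-left to patient-right
#' in the anterior view (256). A `downscale` factor > 1 records that the
#' matrix was block-summed from the native grid, in which case dimensions are
#' `(1024, 256) / downscale`.
#'
#' @param pixels Integer-valued matrix of non-negative counts, all entries in
#'   `[0, 65535]`.
#' @param patient_id Opaque patient identifier string.
#' @param view `"anterior"` or `"posterior"`.
#' @param label One of [class_labels()], or `NA` when unknown.
#' @param pixel_size_mm Physical pixel pitch in millimetres (default 2.26 at
#'   native resolution; scaled by `downscale`).
#' @param provenance One of `"clinical"`, `"mirrored"`, `"translated"`,
#'   `"rotated"`, `"synthetic"`.
#' @param downscale Positive integer block-sum factor relative to the native
#'   1024 x 256 grid.
#' @return An object of class `"scinti_image"`.
#' @export
#' @examples
#' img <- scinti_image(matrix(0L, 1024, 256), patient_id = "P1",
#'                     view = "anterior", label = "normal")
#' dim(img$pixels)
scinti_image <- function(pixels, patient_id, view, label = NA_character_,
                         pixel_size_mm = 2.26, provenance = "clinical",
                         downscale = 1L) {
  if (!is.matrix(pixels)) stop("pixels must be a matrix")
  storage.mode(pixels) <- "integer"
  x <- structure(
    list(pixels = pixels,
         patient_id = as.character(patient_id),
         view = match.arg(view, view_levels()),
         label = if (is.na(label)) NA_character_ else
           match.arg(label, class_labels()),
         pixel_size_mm = as.numeric(pixel_size_mm),
         provenance = match.arg(provenance, provenance_levels()),
         downscale = as.integer(downscale)),
    class = "scinti_image")
  validate_scinti_image(x)
  x
}

#' @rdname scinti_image
#' @param x A `scinti_image`.
#' @export
validate_scinti_image <- function(x) {
  stopifnot(inherits(x, "scinti_image"))
  p <- x$pixels
  if (anyNA(p)) stop("pixels contain NA")
  if (min(p) < 0L || max(p) > 65535L)
    stop("pixel counts must lie in [0, 65535]")
  want <- native_dims() / x$downscale
  if (!identical(dim(p), as.integer(want)))
    stop(sprintf("pixel matrix is %d x %d; expected %d x %d (downscale %d)",
                 nrow(p), ncol(p), want[1], want[2], x$downscale))
  if (x$pixel_size_mm <= 0) stop("pixel_size_mm must be positive")
  invisible(x)
}

native_dims <- function() c(1024L, 256L)

#' @export
print.scinti_image <- function(x, ...) {
  cat(sprintf("<scinti_image> %d x %d, patient %s, %s view, label %s\n",
              nrow(x$pixels), ncol(x$pixels), x$patient_id, x$view,
              ifelse(is.na(x$label), "unknown", x$label)))
  cat(sprintf("  counts in [%d, %d], pixel %.2f mm, provenance %s%s\n",
              min(x$pixels), max(x$pixels), x$pixel_size_mm, x$provenance,
              if (x$downscale > 1L)
                sprintf(", downscale %dx", x$downscale) else ""))
  invisible(x)
}

#' Reduce a scintigram to a coarser grid by block summation
#'
#' Sums counts over non-overlapping `factor` x `factor` blocks. Summation
#' (rather than averaging) preserves total counts and keeps the Poisson
#' counting statistics of the native acquisition.
#'
#' @param image A [scinti_image()].
#' @param factor Integer >= 1 dividing both image dimensions.
#' @return A `scinti_image` on the coarser grid with `downscale` updated.
#' @export
downscale_image <- function(image, factor = 2L) {
  validate_scinti_image(image)
  factor <- as.integer(factor)
  if (factor == 1L) return(image)
  p <- image$pixels
  if (nrow(p) %% factor != 0L || ncol(p) %% factor != 0L)
    stop("downscale factor must divide both image dimensions")
  h <- nrow(p) %/% factor; w <- ncol(p) %/% factor
  # sum factor x factor blocks via two folds
  q <- matrix(0, h, ncol(p))
  for (i in seq_len(factor)) q <- q + p[seq(i, nrow(p), by = factor), ]
  r <- matrix(0, h, w)
  for (j in seq_len(factor)) r <- r + q[, seq(j, ncol(p), by = factor)]
  r <- pmin(r, 65535)
  image$pixels <- matrix(as.integer(r), h, w)
  image$downscale <- image$downscale * factor
  image$pixel_size_mm <- image$pixel_size_mm * factor
  image
}
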