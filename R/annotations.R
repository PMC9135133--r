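#' Lesion annotations for one image
#'
#' Polygon regions in pixel coordinates with a disease-or-bodypart code,
#' plus the number of annotators who agreed the image is abnormal. An image
#' is labelled positive only under a majority (at least 2 of 3 annotators).
#'
#' @param image_ref Identifier of the annotated image.
#' @param regions List of regions, each a list with `points` (n x 2 matrix of
#'   (col, row) vertices, n >= 3) and `code` (string).
#' @param annotator_votes Number of annotators calling the image abnormal.
#' @param image_dims Optional `(rows, cols)` bounds to validate vertices
#'   against.
#' @return An object of class `"scinti_annotation"` with a `positive` flag.
#' @export
annotation <- function(image_ref, regions = list(), annotator_votes = 0L,
                       image_dims = NULL) {
  for (i in seq_along(regions)) {
    r <- regions[[i]]
    pts <- r$points
    if (!is.matrix(pts) || ncol(pts) != 2 || nrow(pts) < 3)
      stop(sprintf("region %d ('%s'): polygon needs >= 3 (x, y) vertices",
                   i, r$code))
    if (!is.null(image_dims)) {
      if (any(pts[, 1] < 0) || any(pts[, 1] > image_dims[2]) ||
          any(pts[, 2] < 0) || any(pts[, 2] > image_dims[1]))
        stop(sprintf("region %d ('%s'): polygon vertex outside image bounds",
                     i, r$code))
    }
  }
  structure(list(image_ref = as.character(image_ref),
                 regions = regions,
                 annotator_votes = as.integer(annotator_votes),
                 positive = length(regions) > 0L && annotator_votes >= 2L),
            class = "scinti_annotation")
}

#' Load LabelMe-style polygon annotations
#'
#' Parses the LabelMe JSON dialect: an object (or a list of objects) with
#' `imagePath`, `imageHeight`, `imageWidth`, optional `annotatorVotes`, and
#' `shapes`, each shape carrying `label` and `points`. Every shape becomes a
#' region; an image is flagged positive when it has at least one region and
#' at least two annotator votes.
#'
#' @param path JSON file path.
#' @return List of [annotation()] objects, one per annotated image.
#' @export
load_annotations <- function(path) {
  js <- tryCatch(jsonlite::read_json(path),
                 error = function(e) stop("malformed annotation JSON in ",
                                          path, ": ", conditionMessage(e)))
  # a single LabelMe record or a list of records
  if (!is.null(js$imagePath) || !is.null(js$shapes)) js <- list(js)
  lapply(js, function(rec) {
    dims <- if (!is.null(rec$imageHeight))
      c(rec$imageHeight, rec$imageWidth) else NULL
    regions <- lapply(rec$shapes, function(s) {
      pts <- do.call(rbind, lapply(s$points, function(p)
        c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
      list(points = pts, code = as.character(s$label))
    })
    annotation(image_ref = rec$imagePath %||% "unknown",
               regions = regions,
               annotator_votes = rec$annotatorVotes %||% 0L,
               image_dims = dims)
  })
}

#' Write annotations as LabelMe-style JSON
#'
#' @param annotations List of [annotation()] objects.
#' @param path Output JSON path.
#' @param image_dims `(rows, cols)` recorded in each record.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path, image_dims = native_dims()) {
  recs <- lapply(annotations, function(a) {
    list(imagePath = a$image_ref,
         imageHeight = image_dims[1], imageWidth = image_dims[2],
         annotatorVotes = a$annotator_votes,
         shapes = lapply(a$regions, function(r) {
           list(label = r$code,
                points = lapply(seq_len(nrow(r$points)), function(i)
                  as.numeric(r$points[i, ])),
                shape_type = "polygon")
         }))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Majority-vote image labelling
#'
#' An image with at least one disease-coded region is positive iff at least
#' `threshold` annotators agree.
#'
#' @param votes Logical/0-1 vector, one entry per annotator.
#' @param threshold Required number of agreeing annotators (default 2).
#' @return Logical.
#' @export
majority_positive <- function(votes, threshold = 2L) {
  sum(as.logical(votes)) >= threshold
}
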