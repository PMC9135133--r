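#' Diagnostic class labels
#'
#' The classifier distinguishes four unordered categories of whole-body
#' scintigram: normal, bone metastasis, arthritis, and thyroid carcinoma.
#' The integer encoding 0..3, in that order, is fixed and stable across
#' save/load so that confusion matrices and manifests are comparable
#' between runs.
#'
#' @return Character vector of the four class names, in encoding order.
#' @export
#' @examples
#' class_labels()
#' class_encoding("arthritis")
class_labels <- function() {
  c("normal", "metastasis", "arthritis", "thyroid_carcinoma")
}

#' @rdname class_labels
#' @param label Character vector of class names.
#' @return `class_encoding()`: integer codes in 0..3.
#' @export
class_encoding <- function(label) {
  m <- match(label, class_labels())
  if (anyNA(m)) {
    stop("unknown class label(s): ",
         paste(unique(label[is.na(m)]), collapse = ", "),
         "; expected one of ", paste(class_labels(), collapse = ", "))
  }
  m - 1L
}

#' @rdname class_labels
#' @param code Integer codes in 0..3.
#' @return `class_decoding()`: class names.
#' @export
class_decoding <- function(code) {
  code <- as.integer(code)
  if (any(code < 0L | code > 3L)) stop("class codes must lie in 0..3")
  class_labels()[code + 1L]
}

#' Image views
#' @return The two planar acquisition views.
#' @keywords internal
view_levels <- function() c("anterior", "posterior")

provenance_levels <- function() {
  c("clinical", "mirrored", "translated", "rotated", "synthetic")
}
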