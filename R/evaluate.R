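#' Misclassification error of a binary segmentation
#'
#' \deqn{ME = 1 - \frac{|B_o \cap B_T| + |F_o \cap F_T|}{|B_o| + |F_o|}}
#' where \eqn{B_o, F_o} are the ground-truth background/foreground pixel sets
#' and \eqn{B_T, F_T} the thresholded ones.  Equals the fraction of pixels
#' whose class disagrees with the ground truth: 0 is a perfect segmentation,
#' 1 a completely wrong one.  Symmetric in its arguments.
#'
#' @param truth,predicted logical matrices of identical size
#'   (`TRUE` = foreground).
#' @return scalar in `[0, 1]`.
#' @export
misclassification_error <- function(truth, predicted) {
  truth <- as_mask(truth, "truth")
  predicted <- as_mask(predicted, "predicted")
  if (!identical(dim(truth), dim(predicted))) {
    stop("truth and predicted masks must have identical dimensions",
         call. = FALSE)
  }
  agree <- sum(!truth & !predicted) + sum(truth & predicted)
  1 - agree / length(truth)
}

as_mask <- function(x, what = "mask") {
  if (is.matrix(x) && is.numeric(x)) x <- x != 0
  if (!is.matrix(x) || !is.logical(x)) {
    stop(sprintf("%s must be a logical matrix", what), call. = FALSE)
  }
  if (anyNA(x)) stop(sprintf("%s contains missing values", what), call. = FALSE)
  x
}

#' Align the polarity of a predicted mask with the ground truth
#'
#' A threshold method does not know which side of the threshold is
#' "foreground".  Returns `predicted` or its complement, whichever has the
#' lower misclassification error against `truth` (the original orientation is
#' kept on ties).
#'
#' @inheritParams misclassification_error
#' @return logical matrix.
#' @export
polarity_align <- function(truth, predicted) {
  truth <- as_mask(truth, "truth")
  predicted <- as_mask(predicted, "predicted")
  me_keep <- misclassification_error(truth, predicted)
  me_flip <- misclassification_error(truth, !predicted)
  if (me_flip < me_keep) !predicted else predicted
}

#' Read a ground-truth mask from an image file
#'
#' Gray level 0 is background; any nonzero level is foreground.
#'
#' @param path PNG/TIFF/PGM file.
#' @param L gray-level count of the file.
#' @return logical matrix.
#' @export
read_mask <- function(path, L = 256L) {
  read_gray_image(path, L) != 0L
}
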