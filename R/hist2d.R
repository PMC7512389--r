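#' One-dimensional gray-level histogram
#'
#' @param image integer gray-image matrix.
#' @param L gray-level count.
#' @return numeric vector of length `L` with the relative frequency of each
#'   gray level `0..L-1`; sums to 1.
#' @export
build_histogram1d <- function(image, L = 256L) {
  img <- validate_gray_image(image, L)
  tabulate(as.vector(img) + 1L, nbins = L) / length(img)
}

#' Joint histogram of an image and its filtered companion
#'
#' Builds the `L x L` joint probability matrix `p[i+1, j+1] = n_ij / (M*N)`,
#' where `n_ij` counts the pixels whose gray level is `i` in the original
#' image and `j` in the companion image.  With the companion produced by
#' [nlm_filter()] this is the non-local-means two-dimensional histogram at the
#' heart of the segmentation criterion; with [local_mean_image()] it is the
#' classical local-mean (Abutaleb-style) 2D histogram.
#'
#' Rows index the original image's gray level, columns the companion's.
#'
#' @param original,companion integer gray-image matrices of identical size.
#' @param L gray-level count for both images.
#' @return `L x L` numeric matrix summing to 1, with attributes `L` and
#'   `n_pixels`.
#' @export
build_joint_histogram <- function(original, companion, L = 256L) {
  a <- validate_gray_image(original, L, "original")
  b <- validate_gray_image(companion, L, "companion")
  if (!identical(dim(a), dim(b))) {
    stop("original and companion images must have identical dimensions",
         call. = FALSE)
  }
  idx <- as.vector(a) * L + as.vector(b) + 1L
  counts <- tabulate(idx, nbins = L * L)
  p <- matrix(counts / length(a), nrow = L, ncol = L, byrow = TRUE)
  attr(p, "L") <- as.integer(L)
  attr(p, "n_pixels") <- length(a)
  p
}

# internal: validate an L x L joint histogram
validate_hist2d <- function(h) {
  if (!is.matrix(h) || nrow(h) != ncol(h)) {
    stop("a 2D histogram must be a square matrix", call. = FALSE)
  }
  if (any(h < 0)) stop("histogram entries must be non-negative", call. = FALSE)
  if (abs(sum(h) - 1) > 1e-6) {
    stop("histogram entries must sum to 1", call. = FALSE)
  }
  h
}

#' Local mean image
#'
#' Each output pixel is the rounded mean of the `window x window` neighborhood
#' centered on it (reflect padding at the borders).  This is the smoothing
#' stage of the local-mean 2D-histogram baseline; the proposed pipeline uses
#' [nlm_filter()] instead.
#'
#' @param image integer gray-image matrix.
#' @param window odd window side length, at least 3.
#' @param L gray-level count.
#' @param pad_mode boundary extension, `"reflect"` (default) or `"edge"`.
#' @return integer gray-image matrix.
#' @export
local_mean_image <- function(image, window = 3L, L = 256L,
                             pad_mode = c("reflect", "edge")) {
  pad_mode <- match.arg(pad_mode)
  img <- validate_gray_image(image, L)
  window <- as.integer(window)
  if (is.na(window) || window < 3L || window %% 2L == 0L) {
    stop("window must be an odd integer >= 3", call. = FALSE)
  }
  r <- (window - 1L) %/% 2L
  A <- pad_image(matrix(as.numeric(img), nrow(img), ncol(img)), r, pad_mode)
  m <- box_sum(A, window) / window^2
  out <- pmin(pmax(round_half_up(m), 0), L - 1)
  storage.mode(out) <- "integer"
  out
}

#' Quadrant masses of a 2D histogram
#'
#' A threshold vector `(s, t)` partitions the histogram support into four
#' quadrants: region 1 = `[0..s] x [0..t]` (background), region 2 =
#' `[0..s] x [t+1..L-1]`, region 3 = `[s+1..L-1] x [t+1..L-1]` (object), and
#' region 4 = `[s+1..L-1] x [0..t]`.  Regions 2 and 4 collect edge and noise
#' pixels whose original and filtered levels fall on opposite sides of the
#' thresholds.
#'
#' @param h `L x L` joint histogram from [build_joint_histogram()].
#' @param s,t integer thresholds in `[0, L-1]` on the original and companion
#'   gray levels respectively.
#' @return named numeric vector `c(r1, r2, r3, r4)` summing to 1.
#' @export
quadrant_masses <- function(h, s, t) {
  h <- validate_hist2d(h)
  L <- nrow(h)
  if (s < 0 || s > L - 1 || t < 0 || t > L - 1 || s != floor(s) || t != floor(t)) {
    stop(sprintf("thresholds s, t must be integers in [0, %d]", L - 1L),
         call. = FALSE)
  }
  lo_i <- seq_len(s + 1L)
  lo_j <- seq_len(t + 1L)
  hi_i <- if (s + 2L <= L) (s + 2L):L else integer(0)
  hi_j <- if (t + 2L <= L) (t + 2L):L else integer(0)
  c(r1 = sum(h[lo_i, lo_j]),
    r2 = sum(h[lo_i, hi_j]),
    r3 = sum(h[hi_i, hi_j]),
    r4 = sum(h[hi_i, lo_j]))
}

#' Export / import a histogram as CSV
#'
#' Plain `L` rows by `L` columns of probabilities, no header, for inspection
#' and for use as a text fixture.
#'
#' @param h histogram matrix.
#' @param path CSV file path.
#' @return for the writer, `path` invisibly; for the reader, the matrix.
#' @export
write_histogram_csv <- function(h, path) {
  utils::write.table(h, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_histogram_csv
#' @export
read_histogram_csv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(m) <- NULL
  attr(m, "L") <- nrow(m)
  m
}
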