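#' Non-local means filter parameters
#'
#' Bundles the tunable parameters of the non-local means (NLM) filter.  Each
#' pixel is replaced by a weighted average of candidate pixels, the weight
#' decaying exponentially with the squared Euclidean distance between the two
#' pixels' square patches:
#' \deqn{w(i,j) = \exp\{-\|X(N_i) - X(N_j)\|^2 / (h^2 \sigma^2)\} / Z(i)}
#' where \eqn{Z(i)} normalizes the weights to sum to one.  The patch distance
#' is the plain sum of squared gray-level differences over the
#' `(2*patch_radius+1)^2` patch; `sigma` enters only through the product
#' `h^2 * sigma^2` in the denominator.
#'
#' @param patch_radius half-width of the square comparison patch (default 2,
#'   i.e. a 5x5 patch).
#' @param search_radius half-width of the square search window around each
#'   pixel, or `"full"` to average over every pixel of the image (the literal
#'   definition; quadratic in image size).  Default 10.
#' @param h filtering degree (gray levels); larger values smooth more.
#' @param sigma Gaussian kernel standard deviation entering the weight
#'   denominator `h^2 * sigma^2`.
#' @param pad_mode boundary extension used when patches overrun the image
#'   border: `"reflect"` (default) or `"edge"`.
#' @return an object of class `nlm_params`.
#' @export
nlm_params <- function(patch_radius = 2L, search_radius = 10L, h = 10,
                       sigma = 1, pad_mode = c("reflect", "edge")) {
  pad_mode <- match.arg(pad_mode)
  patch_radius <- as.integer(patch_radius)
  if (is.na(patch_radius) || patch_radius < 0L) {
    stop("patch_radius must be a non-negative integer", call. = FALSE)
  }
  full <- identical(search_radius, "full")
  if (!full) {
    search_radius <- as.integer(search_radius)
    if (is.na(search_radius) || search_radius < 1L) {
      stop("search_radius must be a positive integer or \"full\"", call. = FALSE)
    }
  }
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0) {
    stop("h must be a positive number", call. = FALSE)
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0) {
    stop("sigma must be a positive number", call. = FALSE)
  }
  structure(list(patch_radius = patch_radius,
                 search_radius = if (full) "full" else search_radius,
                 h = as.numeric(h), sigma = as.numeric(sigma),
                 pad_mode = pad_mode),
            class = "nlm_params")
}

#' @export
print.nlm_params <- function(x, ...) {
  cat(sprintf(
    "NLM parameters: patch %dx%d, search %s, h = %g, sigma = %g, pad = %s\n",
    2L * x$patch_radius + 1L, 2L * x$patch_radius + 1L,
    if (identical(x$search_radius, "full")) "full image"
    else sprintf("%dx%d window", 2L * x$search_radius + 1L, 2L * x$search_radius + 1L),
    x$h, x$sigma, x$pad_mode))
  invisible(x)
}

# per-axis effective search radii: offsets beyond the image extent can never
# reach a valid candidate pixel
effective_search <- function(params, M, N) {
  if (identical(params$search_radius, "full")) {
    c(M - 1L, N - 1L)
  } else {
    c(min(params$search_radius, M - 1L), min(params$search_radius, N - 1L))
  }
}

# windowed column sums: x is (n+k-1) x m, returns (n) x m with
# out[i,] = colSums over rows i..i+k-1
run_win_sum <- function(x, k) {
  if (nrow(x) == 1L && k == 1L) return(x)
  cs <- apply(x, 2L, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, nrow = nrow(x))
  out <- cs[k:nrow(x), , drop = FALSE]
  if (nrow(x) > k) {
    out[-1L, ] <- out[-1L, , drop = FALSE] - cs[seq_len(nrow(x) - k), , drop = FALSE]
  }
  out
}

# 2D box sum: x is (n+k-1) x (m+k-1); out[i,j] = sum of the k x k block of x
# with top-left corner (i,j)
box_sum <- function(x, k) {
  t(run_win_sum(t(run_win_sum(x, k)), k))
}

#' Non-local means weights for one pixel
#'
#' Reference (loop-based) evaluation of the normalized NLM weights of a single
#' pixel over all candidate pixels in its search window.  Mostly useful for
#' inspection and testing; [nlm_filter()] computes the same quantities for the
#' whole image at once.
#'
#' @param image integer gray-image matrix.
#' @param i pixel index `c(row, col)` (1-based).
#' @param params an [nlm_params()] object.
#' @param L gray-level count.
#' @return numeric vector of weights summing to 1, with attribute
#'   `"candidates"`: a two-column matrix of the (row, col) index of each
#'   candidate pixel `j`.
#' @export
nlm_weights <- function(image, i, params = nlm_params(), L = 256L) {
  img <- validate_gray_image(image, L)
  if (length(i) != 2L || any(i < 1L) || i[1L] > nrow(img) || i[2L] > ncol(img)) {
    stop("pixel index i = c(row, col) must lie inside the image", call. = FALSE)
  }
  M <- nrow(img); N <- ncol(img)
  pr <- params$patch_radius
  sr <- effective_search(params, M, N)
  A <- pad_image(matrix(as.numeric(img), M, N), pr, params$pad_mode)
  patch_of <- function(r, c) A[r:(r + 2L * pr), c:(c + 2L * pr)]
  Pi <- patch_of(i[1L], i[2L])
  rows <- max(1L, i[1L] - sr[1L]):min(M, i[1L] + sr[1L])
  cols <- max(1L, i[2L] - sr[2L]):min(N, i[2L] + sr[2L])
  cand <- as.matrix(expand.grid(row = rows, col = cols, KEEP.OUT.ATTRS = FALSE))
  inv <- 1 / (params$h^2 * params$sigma^2)
  w <- vapply(seq_len(nrow(cand)), function(k) {
    Pj <- patch_of(cand[k, 1L], cand[k, 2L])
    exp(-sum((Pi - Pj)^2) * inv)
  }, numeric(1L))
  w <- w / sum(w)
  attr(w, "candidates") <- cand
  w
}

#' Non-local means filter
#'
#' Produces the spatially informed companion image `J` used to build the
#' two-dimensional histogram: each pixel becomes the NLM-weighted average of
#' the candidate pixels in its search window, then (by default) is rounded
#' half-up and clipped to `[0, L-1]` so the result is again a valid gray
#' image.
#'
#' The implementation loops over window offsets rather than pixels: for each
#' offset the patch distances of every pixel are obtained with a box filter
#' over the squared difference image, which is algebraically identical to the
#' per-pixel definition.
#'
#' @inheritParams nlm_weights
#' @param quantize if `FALSE`, return the real-valued weighted averages
#'   without rounding/clipping (useful for numerical comparison).
#' @return integer gray-image matrix (or a numeric matrix when
#'   `quantize = FALSE`).
#' @export
nlm_filter <- function(image, params = nlm_params(), L = 256L, quantize = TRUE) {
  img <- validate_gray_image(image, L)
  M <- nrow(img); N <- ncol(img)
  pr <- params$patch_radius
  sr <- effective_search(params, M, N)
  inv <- 1 / (params$h^2 * params$sigma^2)
  imgd <- matrix(as.numeric(img), M, N)
  A <- pad_image(imgd, pr, params$pad_mode)
  num <- matrix(0, M, N)
  den <- matrix(0, M, N)
  k <- 2L * pr + 1L
  for (dx in -sr[1L]:sr[1L]) {
    r1 <- max(1L, 1L - dx); r2 <- min(M, M - dx)
    if (r1 > r2) next
    for (dy in -sr[2L]:sr[2L]) {
      c1 <- max(1L, 1L - dy); c2 <- min(N, N - dy)
      if (c1 > c2) next
      E1 <- A[r1:(r2 + 2L * pr), c1:(c2 + 2L * pr), drop = FALSE]
      E2 <- A[(r1 + dx):(r2 + 2L * pr + dx), (c1 + dy):(c2 + 2L * pr + dy),
              drop = FALSE]
      S <- box_sum((E1 - E2)^2, k)
      w <- exp(-S * inv)
      num[r1:r2, c1:c2] <- num[r1:r2, c1:c2] +
        w * imgd[(r1 + dx):(r2 + dx), (c1 + dy):(c2 + dy), drop = FALSE]
      den[r1:r2, c1:c2] <- den[r1:r2, c1:c2] + w
    }
  }
  y <- num / den
  if (!quantize) return(y)
  out <- pmin(pmax(round_half_up(y), 0), L - 1)
  storage.mode(out) <- "integer"
  out
}
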