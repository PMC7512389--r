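#' Kullback-Leibler divergence between two discrete distributions
#'
#' \eqn{D(P,Q) = \sum_i p_i \log(p_i/q_i)} with the convention
#' \eqn{0 \log(0/q) = 0}.  Natural logarithm.  Requires the support of `p` to
#' be contained in that of `q`.
#'
#' @param p,q numeric probability vectors of equal length, each summing to 1.
#' @return non-negative scalar; 0 iff `p == q`.
#' @export
kl_divergence <- function(p, q) {
  if (length(p) != length(q)) stop("p and q must have equal length", call. = FALSE)
  if (any(p < 0) || any(q < 0)) stop("probabilities must be non-negative", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6) {
    stop("p and q must each sum to 1", call. = FALSE)
  }
  if (any(q == 0 & p > 0)) {
    stop("support violation: q is zero where p is positive", call. = FALSE)
  }
  pos <- p > 0
  sum(p[pos] * log(p[pos] / q[pos]))
}

# m * log(m / P) = m * log(mu), the class term of the reduced criterion,
# with 0 log 0 := 0 (m is a first moment, P the class mass)
moment_log_mean <- function(m, P) {
  mu <- m / P
  out <- numeric(length(m))
  dim(out) <- dim(m)
  pos <- is.finite(mu) & m > 0 & P > 0
  out[pos] <- m[pos] * log(mu[pos])
  out
}

# image-wide constant of the reduced criterion:
# sum_ij (i p_ij log i + j p_ij log j), via the two marginals
moment_entropy_constant <- function(h) {
  L <- nrow(h)
  g <- 0:(L - 1)
  glg <- ifelse(g > 0, g * log(g), 0)
  sum(glg * rowSums(h)) + sum(glg * colSums(h))
}

# accept c(s, t), list(s =, t =), or a threshold2d object
as_threshold_vector <- function(tv) {
  if (inherits(tv, "threshold2d")) return(c(tv$s, tv$t))
  if (is.list(tv)) tv <- c(tv$s, tv$t)
  tv <- as.integer(tv)
  if (length(tv) != 2L || anyNA(tv)) {
    stop("threshold vector must supply two integers (s, t)", call. = FALSE)
  }
  tv
}

#' Class probabilities and mean vectors at a threshold vector
#'
#' For the two-class partition induced by `(s, t)` on a joint histogram,
#' computes the background mass `P0` over quadrant 1 (`i <= s, j <= t`), the
#' object mass `P1` over quadrant 3 (`i > s, j > t`), and the class mean
#' vectors `mu0 = (mu0i, mu0j)` and `mu1 = (mu1i, mu1j)` (first moments over
#' the quadrant divided by the corresponding class mass).  A threshold vector
#' that empties either class is flagged infeasible rather than raising an
#' error, so that a search can simply skip it.
#'
#' @param h `L x L` joint histogram.
#' @param tv threshold vector `c(s, t)`.
#' @return list with `P0`, `P1`, `mu0`, `mu1`, first moments `m0`, `m1`, and
#'   logical `feasible`.
#' @export
class_statistics <- function(h, tv) {
  h <- validate_hist2d(h)
  L <- nrow(h)
  tv <- as_threshold_vector(tv)
  s <- tv[1L]; t <- tv[2L]
  if (s < 0L || s > L - 1L || t < 0L || t > L - 1L) {
    stop(sprintf("thresholds must lie in [0, %d]", L - 1L), call. = FALSE)
  }
  g <- 0:(L - 1)
  lo_i <- seq_len(s + 1L); lo_j <- seq_len(t + 1L)
  hi_i <- if (s + 2L <= L) (s + 2L):L else integer(0)
  hi_j <- if (t + 2L <= L) (t + 2L):L else integer(0)

  r1 <- h[lo_i, lo_j, drop = FALSE]
  r3 <- h[hi_i, hi_j, drop = FALSE]
  P0 <- sum(r1); P1 <- sum(r3)
  m0 <- c(sum(g[lo_i] * rowSums(r1)), sum(g[lo_j] * colSums(r1)))
  m1 <- if (length(hi_i) && length(hi_j)) {
    c(sum(g[hi_i] * rowSums(r3)), sum(g[hi_j] * colSums(r3)))
  } else c(0, 0)
  list(P0 = P0, P1 = P1,
       mu0 = if (P0 > 0) m0 / P0 else c(NA_real_, NA_real_),
       mu1 = if (P1 > 0) m1 / P1 else c(NA_real_, NA_real_),
       m0 = m0, m1 = m1,
       feasible = P0 > 0 && P1 > 0)
}

#' Relative-entropy criterion at a threshold vector
#'
#' The segmentation criterion minimized by [select_threshold()]: the relative
#' entropy between the image's joint (original, filtered) gray-level
#' distribution and its two-class approximation in which each class is
#' represented by its mean vector.  In reduced form,
#' \deqn{D(s,t) = M - m_{0i}\log\mu_{0i} - m_{0j}\log\mu_{0j}
#'               - m_{1i}\log\mu_{1i} - m_{1j}\log\mu_{1j},}
#' where \eqn{m_k} are the class first moments, \eqn{\mu_k = m_k / P_k} the
#' class means, and \eqn{M = \sum_{ij}(i\,p_{ij}\log i + j\,p_{ij}\log j)} is
#' a constant of the image, independent of `(s, t)`.  This is the
#' two-dimensional analogue of the Li-Lee minimum cross-entropy criterion.
#' Natural logarithm; any term with gray level 0 or zero probability
#' contributes 0.
#'
#' @param h `L x L` joint histogram.
#' @param tv threshold vector `c(s, t)`.
#' @return the criterion value, or `NA_real_` if `tv` is infeasible (either
#'   class empty).
#' @export
relative_entropy_objective <- function(h, tv) {
  st <- class_statistics(h, tv)
  if (!st$feasible) return(NA_real_)
  moment_entropy_constant(h) -
    sum(moment_log_mean(st$m0, st$P0)) -
    sum(moment_log_mean(st$m1, st$P1))
}

#' Criterion surface over all threshold vectors
#'
#' Evaluates the relative-entropy criterion at every `(s, t)` in
#' `[0, L-1]^2` using cumulative (prefix-sum) tables, so the whole surface
#' costs `O(L^2)`.  Infeasible vectors (an empty class) are `NA`.
#'
#' @param h `L x L` joint histogram.
#' @return `L x L` numeric matrix `D` with `D[s+1, t+1]` the criterion at
#'   `(s, t)`.
#' @export
objective_surface <- function(h) {
  h <- validate_hist2d(h)
  L <- nrow(h)
  g <- 0:(L - 1)
  sat <- function(m) t(apply(apply(m, 2L, cumsum), 1L, cumsum))
  hi <- h * g                 # i * p_ij  (g recycles down rows)
  hj <- sweep(h, 2L, g, "*")  # j * p_ij
  Sp <- sat(h); Si <- sat(hi); Sj <- sat(hj)

  upper_tail <- function(S) {
    tot <- S[L, L]
    tot - matrix(S[, L], L, L) - matrix(S[L, ], L, L, byrow = TRUE) + S
  }
  P0 <- Sp;            P1 <- upper_tail(Sp)
  m0i <- Si;           m1i <- upper_tail(Si)
  m0j <- Sj;           m1j <- upper_tail(Sj)

  eps <- 1e-12
  feasible <- P0 > eps & P1 > eps
  D <- moment_entropy_constant(h) -
    (moment_log_mean(m0i, P0) + moment_log_mean(m0j, P0) +
     moment_log_mean(m1i, P1) + moment_log_mean(m1j, P1))
  D[!feasible] <- NA_real_
  D
}

#' Select the optimal two-dimensional threshold vector
#'
#' Exhaustive search over all `(s, t)` in `[0, L-1]^2` for the feasible
#' threshold vector minimizing the relative-entropy criterion
#' ([relative_entropy_objective()]).  Ties are broken by the smallest `s`,
#' then the smallest `t`.
#'
#' @param h `L x L` joint histogram (typically of an image and its
#'   [nlm_filter()] companion).
#' @return object of class `threshold2d`: a list with the selected `s`, `t`,
#'   the criterion value `D`, class masses `P0`, `P1` and mean vectors `mu0`,
#'   `mu1`.
#' @export
select_threshold <- function(h) {
  D <- objective_surface(h)
  if (all(is.na(D))) {
    stop(paste("no feasible threshold vector: every (s, t) leaves one class",
               "empty (the image appears to contain a single gray-level",
               "cluster, e.g. a constant image)"), call. = FALSE)
  }
  dmin <- min(D, na.rm = TRUE)
  sel <- which(D == dmin, arr.ind = TRUE)
  sel <- sel[order(sel[, 1L], sel[, 2L]), , drop = FALSE]
  s <- sel[1L, 1L] - 1L
  t <- sel[1L, 2L] - 1L
  st <- class_statistics(h, c(s, t))
  structure(list(s = as.integer(s), t = as.integer(t), D = dmin,
                 P0 = st$P0, P1 = st$P1, mu0 = st$mu0, mu1 = st$mu1),
            class = "threshold2d")
}

#' @export
print.threshold2d <- function(x, ...) {
  cat(sprintf("2D threshold vector (s, t) = (%d, %d)\n", x$s, x$t))
  cat(sprintf("  criterion D = %.6f\n", x$D))
  cat(sprintf("  background: P0 = %.4f, mean (%.2f, %.2f)\n",
              x$P0, x$mu0[1L], x$mu0[2L]))
  cat(sprintf("  object:     P1 = %.4f, mean (%.2f, %.2f)\n",
              x$P1, x$mu1[1L], x$mu1[2L]))
  invisible(x)
}

#' Binarize an image with a two-dimensional threshold vector
#'
#' Pixels with `I <= s` and `J <= t` (quadrant 1) become background (`FALSE`);
#' pixels with `I > s` and `J > t` (quadrant 3) become object (`TRUE`).
#' Pixels falling in quadrants 2 or 4 (typically edges and noise) are assigned
#' to the class whose mean vector is nearer in Euclidean distance in the
#' `(i, j)` gray-level plane, ties going to the background.  If only one class
#' has positive mass at `tv`, the off-quadrant pixels join that class.
#'
#' @param original,companion integer gray-image matrices of identical size.
#' @param tv threshold vector `c(s, t)` or a [select_threshold()] result.
#' @param L gray-level count.
#' @return logical matrix: `TRUE` = object, `FALSE` = background.
#' @export
binarize <- function(original, companion, tv, L = 256L) {
  a <- validate_gray_image(original, L, "original")
  b <- validate_gray_image(companion, L, "companion")
  if (!identical(dim(a), dim(b))) {
    stop("original and companion images must have identical dimensions",
         call. = FALSE)
  }
  tv <- as_threshold_vector(tv)
  s <- tv[1L]; t <- tv[2L]
  st <- class_statistics(build_joint_histogram(a, b, L), tv)

  in1 <- a <= s & b <= t
  in3 <- a > s & b > t
  out <- in3
  off <- !(in1 | in3)
  if (any(off)) {
    if (st$P0 > 0 && st$P1 > 0) {
      d0 <- (a[off] - st$mu0[1L])^2 + (b[off] - st$mu0[2L])^2
      d1 <- (a[off] - st$mu1[1L])^2 + (b[off] - st$mu1[2L])^2
      out[off] <- d1 < d0
    } else if (st$P1 > 0) {
      out[off] <- TRUE
    } else {
      out[off] <- FALSE
    }
  }
  out
}

#' Apply a one-dimensional threshold
#'
#' @param image integer gray-image matrix.
#' @param s threshold; pixels with gray level greater than `s` become `TRUE`.
#' @return logical matrix.
#' @export
apply_threshold <- function(image, s) {
  image > s
}

#' Segment an image with the NLM two-dimensional histogram method
#'
#' The full proposed pipeline: filter the image with non-local means, build
#' the joint histogram of original and filtered gray levels, select the
#' threshold vector minimizing the relative-entropy criterion, and binarize.
#'
#' @param image integer gray-image matrix.
#' @param params [nlm_params()] controlling the filter.
#' @param L gray-level count.
#' @return list with `mask` (logical matrix), `threshold` (a `threshold2d`
#'   object), `filtered` (the NLM companion image) and `histogram` (the joint
#'   histogram).
#' @export
nlm_segment <- function(image, params = nlm_params(), L = 256L) {
  img <- validate_gray_image(image, L)
  J <- nlm_filter(img, params, L)
  h <- build_joint_histogram(img, J, L)
  tv <- select_threshold(h)
  mask <- binarize(img, J, tv, L)
  list(mask = mask, threshold = tv, filtered = J, histogram = h)
}
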