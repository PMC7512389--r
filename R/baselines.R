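# Classical 1D thresholding baselines and the local-mean 2D variant.
# All share the same conventions: class 0 is gray <= s, a candidate threshold
# is feasible only if both classes have positive mass, ties are broken by the
# smallest s, and 0 log 0 terms contribute 0 (natural logarithm).

validate_hist1d <- function(p) {
  if (!is.numeric(p) || length(p) < 2L) {
    stop("a 1D histogram must be a numeric vector of length >= 2", call. = FALSE)
  }
  if (any(p < 0)) stop("histogram entries must be non-negative", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-6) stop("histogram entries must sum to 1", call. = FALSE)
  if (sum(p > 0) < 2L) {
    stop("degenerate histogram: fewer than two occupied gray levels", call. = FALSE)
  }
  p
}

# shared feasibility over candidate thresholds s = 0..L-2
split_masses <- function(p) {
  L <- length(p)
  w0 <- cumsum(p)[seq_len(L - 1L)]
  eps <- 1e-12
  list(w0 = w0, w1 = 1 - w0, feasible = w0 > eps & (1 - w0) > eps)
}

#' Otsu threshold (maximum between-class variance)
#'
#' @param p length-`L` gray-level histogram summing to 1.
#' @return integer threshold `s`; class 0 is gray `<= s`.
#' @export
otsu_threshold <- function(p) {
  p <- validate_hist1d(p)
  L <- length(p)
  g <- 0:(L - 1)
  sm <- split_masses(p)
  m0 <- cumsum(g * p)[seq_len(L - 1L)]
  mt <- sum(g * p)
  bcv <- (mt * sm$w0 - m0)^2 / (sm$w0 * sm$w1)
  bcv[!sm$feasible] <- -Inf
  which.max(bcv) - 1L
}

#' Kapur threshold (maximum sum of class entropies)
#'
#' Maximizes `H0 + H1`, the Shannon entropies of the two normalized class
#' distributions.
#'
#' @inheritParams otsu_threshold
#' @return integer threshold `s`.
#' @export
kapur_threshold <- function(p) {
  p <- validate_hist1d(p)
  L <- length(p)
  sm <- split_masses(p)
  plp <- ifelse(p > 0, p * log(p), 0)
  A0 <- cumsum(plp)[seq_len(L - 1L)]
  At <- sum(plp)
  H <- (-A0 / sm$w0 + log(sm$w0)) + (-(At - A0) / sm$w1 + log(sm$w1))
  H[!sm$feasible] <- -Inf
  which.max(H) - 1L
}

#' Minimum cross-entropy (Li-Lee) threshold
#'
#' Minimizes the cross entropy between the image and its two-class
#' approximation; in reduced form, minimizes
#' `-(m0 log mu0 + m1 log mu1)` over `s`, where `m_k` is the class first
#' moment and `mu_k = m_k / w_k` the class mean.  Terms from gray level 0
#' contribute 0.
#'
#' @inheritParams otsu_threshold
#' @return integer threshold `s`.
#' @export
mce_threshold <- function(p) {
  p <- validate_hist1d(p)
  L <- length(p)
  g <- 0:(L - 1)
  sm <- split_masses(p)
  m0 <- cumsum(g * p)[seq_len(L - 1L)]
  m1 <- sum(g * p) - m0
  crit <- -(moment_log_mean(m0, sm$w0) + moment_log_mean(m1, sm$w1))
  crit[!sm$feasible] <- Inf
  which.min(crit) - 1L
}

#' Local-mean 2D minimum cross-entropy threshold (2DMCE)
#'
#' The closest baseline to the proposed method: the identical
#' relative-entropy criterion ([select_threshold()]) applied to the joint
#' histogram of the image and its local-mean smoothed version, instead of the
#' non-local-means companion.  The two pipelines differ only in the filtering
#' stage.
#'
#' @param image integer gray-image matrix.
#' @param window odd local-mean window (default 3).
#' @param L gray-level count.
#' @return a `threshold2d` object (see [select_threshold()]).
#' @export
mce2d_threshold <- function(image, window = 3L, L = 256L) {
  img <- validate_gray_image(image, L)
  J <- local_mean_image(img, window, L)
  select_threshold(build_joint_histogram(img, J, L))
}

#' Run the proposed method and all four baselines on one image
#'
#' Mirrors the comparison protocol: the proposed NLM 2D-histogram method,
#' the local-mean 2DMCE variant, and the three 1D methods (MCE, Otsu, Kapur).
#' If a ground-truth mask is supplied, the polarity-aligned misclassification
#' error of each method is reported.
#'
#' @param image integer gray-image matrix.
#' @param truth optional logical ground-truth mask of the same size.
#' @param params [nlm_params()] for the proposed method.
#' @param window local-mean window for the 2DMCE baseline.
#' @param L gray-level count.
#' @param align report polarity-aligned ME (default); set `FALSE` for the
#'   strict, orientation-sensitive ME.
#' @return data frame with one row per method: `method`, thresholds `s` and
#'   `t` (`t` is `NA` for 1D methods), `objective`, and `me` (NA without
#'   ground truth).
#' @export
compare_methods <- function(image, truth = NULL, params = nlm_params(),
                            window = 3L, L = 256L, align = TRUE) {
  img <- validate_gray_image(image, L)
  p1d <- build_histogram1d(img, L)

  prop <- nlm_segment(img, params, L)
  m2d <- mce2d_threshold(img, window, L)
  Jlm <- local_mean_image(img, window, L)
  s_mce <- mce_threshold(p1d)
  s_otsu <- otsu_threshold(p1d)
  s_kapur <- kapur_threshold(p1d)

  masks <- list(
    proposed = prop$mask,
    mce2d    = binarize(img, Jlm, m2d, L),
    mce      = apply_threshold(img, s_mce),
    otsu     = apply_threshold(img, s_otsu),
    kapur    = apply_threshold(img, s_kapur)
  )
  me <- rep(NA_real_, 5L)
  if (!is.null(truth)) {
    me <- vapply(masks, function(m) {
      if (align) m <- polarity_align(truth, m)
      misclassification_error(truth, m)
    }, numeric(1L))
  }
  data.frame(
    method = c("proposed", "2DMCE", "MCE", "Otsu", "Kapur"),
    s = c(prop$threshold$s, m2d$s, s_mce, s_otsu, s_kapur),
    t = c(prop$threshold$t, m2d$t, NA_integer_, NA_integer_, NA_integer_),
    objective = c(prop$threshold$D, m2d$D, NA_real_, NA_real_, NA_real_),
    me = unname(me),
    stringsAsFactors = FALSE
  )
}
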