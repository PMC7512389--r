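# Independent reference implementations used as oracles.  Everything here is
# written as literal per-definition loops/sums, deliberately sharing no code
# with the package internals.

# reflect ("mirror", border not repeated) / edge padding index, scalar version
ref_pad_idx <- function(i, n, mode) {
  if (mode == "edge") return(min(max(i, 1L), n))
  if (n == 1L) return(1L)
  p <- 2L * n - 2L
  k <- (i - 1L) %% p
  if (k < 0L) k <- k + p
  if (k < n) k + 1L else 2L * n - 1L - k
}

ref_pixel <- function(img, r, c, mode = "reflect") {
  img[ref_pad_idx(r, nrow(img), mode), ref_pad_idx(c, ncol(img), mode)]
}

ref_patch <- function(img, r, c, pr, mode = "reflect") {
  out <- matrix(0, 2L * pr + 1L, 2L * pr + 1L)
  for (u in -pr:pr) for (v in -pr:pr) {
    out[u + pr + 1L, v + pr + 1L] <- ref_pixel(img, r + u, c + v, mode)
  }
  out
}

# quadruple-loop non-local means; returns the real-valued (pre-rounding)
# weighted averages
ref_nlm <- function(img, pr, sr, h, sigma, mode = "reflect") {
  M <- nrow(img); N <- ncol(img)
  if (identical(sr, "full")) sr <- max(M, N)
  inv <- 1 / (h^2 * sigma^2)
  # precompute every pixel's patch as a row
  patches <- matrix(0, M * N, (2L * pr + 1L)^2)
  for (r in 1:M) for (c in 1:N) {
    patches[(c - 1L) * M + r, ] <- as.vector(ref_patch(img, r, c, pr, mode))
  }
  out <- matrix(0, M, N)
  for (r in 1:M) for (c in 1:N) {
    num <- 0; den <- 0
    for (rr in max(1L, r - sr):min(M, r + sr)) {
      for (cc in max(1L, c - sr):min(N, c + sr)) {
        d2 <- sum((patches[(c - 1L) * M + r, ] - patches[(cc - 1L) * M + rr, ])^2)
        w <- exp(-d2 * inv)
        num <- num + w * img[rr, cc]
        den <- den + w
      }
    }
    out[r, c] <- num / den
  }
  out
}

ref_local_mean <- function(img, window, mode = "reflect") {
  r <- (window - 1L) %/% 2L
  out <- matrix(0L, nrow(img), ncol(img))
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
    acc <- 0
    for (u in -r:r) for (v in -r:r) acc <- acc + ref_pixel(img, i + u, j + v, mode)
    out[i, j] <- as.integer(floor(acc / window^2 + 0.5))
  }
  out
}

ref_joint_hist <- function(a, b, L) {
  p <- matrix(0, L, L)
  for (k in seq_along(a)) {
    p[a[k] + 1L, b[k] + 1L] <- p[a[k] + 1L, b[k] + 1L] + 1
  }
  p / length(a)
}

# direct term-by-term evaluation of the relative-entropy criterion: class
# divergence terms over quadrants 1/3 plus the raw moment-entropy terms of
# the off-quadrant cells (which complete the image-wide constant).  NA when
# either class is empty.
ref_objective_direct <- function(h, s, t) {
  L <- nrow(h)
  P0 <- 0; m0i <- 0; m0j <- 0; P1 <- 0; m1i <- 0; m1j <- 0
  for (i in 0:(L - 1)) for (j in 0:(L - 1)) {
    pij <- h[i + 1L, j + 1L]
    if (pij == 0) next
    if (i <= s && j <= t) {
      P0 <- P0 + pij; m0i <- m0i + i * pij; m0j <- m0j + j * pij
    } else if (i > s && j > t) {
      P1 <- P1 + pij; m1i <- m1i + i * pij; m1j <- m1j + j * pij
    }
  }
  if (P0 == 0 || P1 == 0) return(NA_real_)
  mu0i <- m0i / P0; mu0j <- m0j / P0; mu1i <- m1i / P1; mu1j <- m1j / P1
  tot <- 0
  for (i in 0:(L - 1)) for (j in 0:(L - 1)) {
    pij <- h[i + 1L, j + 1L]
    if (pij == 0) next
    if (i <= s && j <= t) {
      if (i > 0 && mu0i > 0) tot <- tot + i * pij * log(i / mu0i)
      if (j > 0 && mu0j > 0) tot <- tot + j * pij * log(j / mu0j)
    } else if (i > s && j > t) {
      if (i > 0 && mu1i > 0) tot <- tot + i * pij * log(i / mu1i)
      if (j > 0 && mu1j > 0) tot <- tot + j * pij * log(j / mu1j)
    } else {
      if (i > 0) tot <- tot + i * pij * log(i)
      if (j > 0) tot <- tot + j * pij * log(j)
    }
  }
  tot
}

# full-scan oracle: evaluates the criterion at every (s, t) by direct
# summation, each region sum computed literally via indicator-matrix products
# (no cumulative tables), then takes the lexicographically first argmin
ref_scan_surface <- function(h) {
  L <- nrow(h)
  g <- 0:(L - 1)
  A <- (row(diag(L)) >= col(diag(L))) * 1   # A[s+1, i+1] = 1 iff i <= s
  B <- 1 - A                                 # i > s
  hi <- h * g
  hj <- t(t(h) * g)
  P0 <- A %*% h %*% t(A);  P1 <- B %*% h %*% t(B)
  m0i <- A %*% hi %*% t(A); m1i <- B %*% hi %*% t(B)
  m0j <- A %*% hj %*% t(A); m1j <- B %*% hj %*% t(B)
  glg <- ifelse(g > 0, g * log(g), 0)
  Mc <- sum(glg * rowSums(h)) + sum(glg * colSums(h))
  f <- function(m, P) ifelse(m > 0 & P > 0, m * log(m / P), 0)
  D <- Mc - (f(m0i, P0) + f(m0j, P0) + f(m1i, P1) + f(m1j, P1))
  D[!(P0 > 1e-12 & P1 > 1e-12)] <- NA_real_
  D
}

ref_scan_argmin <- function(h) {
  D <- ref_scan_surface(h)
  dmin <- min(D, na.rm = TRUE)
  sel <- which(D == dmin, arr.ind = TRUE)
  sel <- sel[order(sel[, 1L], sel[, 2L]), , drop = FALSE]
  list(s = unname(sel[1L, 1L]) - 1L, t = unname(sel[1L, 2L]) - 1L, D = dmin)
}

# naive 1D criterion scans
ref_otsu <- function(p) {
  L <- length(p); g <- 0:(L - 1)
  best <- -Inf; bs <- NA
  for (s in 0:(L - 2)) {
    w0 <- sum(p[1:(s + 1)]); w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    mu0 <- sum(g[1:(s + 1)] * p[1:(s + 1)]) / w0
    mu1 <- sum(g[(s + 2):L] * p[(s + 2):L]) / w1
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best) { best <- v; bs <- s }
  }
  bs
}

ref_kapur <- function(p) {
  L <- length(p)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  best <- -Inf; bs <- NA
  for (s in 0:(L - 2)) {
    w0 <- sum(p[1:(s + 1)]); w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    v <- ent(p[1:(s + 1)] / w0) + ent(p[(s + 2):L] / w1)
    if (v > best) { best <- v; bs <- s }
  }
  bs
}

ref_mce <- function(p) {
  L <- length(p); g <- 0:(L - 1)
  best <- Inf; bs <- NA
  for (s in 0:(L - 2)) {
    w0 <- sum(p[1:(s + 1)]); w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    m0 <- sum(g[1:(s + 1)] * p[1:(s + 1)])
    m1 <- sum(g[(s + 2):L] * p[(s + 2):L])
    v <- -(if (m0 > 0) m0 * log(m0 / w0) else 0) -
          (if (m1 > 0) m1 * log(m1 / w1) else 0)
    if (v < best) { best <- v; bs <- s }
  }
  bs
}

# dense random joint histogram; exponent > 1 concentrates mass
rand_hist <- function(L, seed, power = 3) {
  set.seed(seed)
  p <- matrix(stats::runif(L * L)^power, L, L)
  p / sum(p)
}

rand_image <- function(M, N, seed, L = 256L) {
  set.seed(seed)
  matrix(sample.int(L, M * N, replace = TRUE) - 1L, M, N)
}
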