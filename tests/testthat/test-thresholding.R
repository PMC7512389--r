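two_spike_hist <- function(L = 256L, lo = 50L, hi = 200L, w_lo = 0.4) {
  p <- matrix(0, L, L)
  p[lo + 1L, lo + 1L] <- w_lo
  p[hi + 1L, hi + 1L] <- 1 - w_lo
  p
}

test_that("KL divergence matches closed forms and direct summation", {
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(kl_divergence(c(1, 0), c(0.5, 0.5)), log(2))
  set.seed(61)
  for (k in 1:20) {
    p <- stats::runif(10); p <- p / sum(p)
    q <- stats::runif(10); q <- q / sum(q)
    expect_equal(kl_divergence(p, q), sum(p * log(p / q)), tolerance = 1e-12)
    expect_gte(kl_divergence(p, q), 0)
  }
  expect_error(kl_divergence(c(1, 0), c(0, 1)), "support")
  expect_error(kl_divergence(c(0.7, 0.2), c(0.5, 0.5)), "sum to 1")
})

test_that("class statistics recover point masses and flag infeasibility", {
  p <- matrix(0, 256, 256); p[11, 11] <- 1
  st <- class_statistics(p, c(20, 20))
  expect_equal(st$P0, 1)
  expect_equal(st$mu0, c(10, 10))
  expect_false(st$feasible)

  st <- class_statistics(two_spike_hist(), c(100, 100))
  expect_true(st$feasible)
  expect_equal(st$P0, 0.4)
  expect_equal(st$P1, 0.6)
  expect_equal(st$mu0, c(50, 50))
  expect_equal(st$mu1, c(200, 200))
})

test_that("class statistics match direct region sums on a random histogram", {
  h <- rand_hist(256, seed = 71)
  st <- class_statistics(h, c(97, 131))
  r1 <- h[1:98, 1:132]
  r3 <- h[99:256, 133:256]
  expect_equal(st$P0, sum(r1), tolerance = 1e-12)
  expect_equal(st$P1, sum(r3), tolerance = 1e-12)
  expect_equal(st$mu0[1], sum((0:97) * rowSums(r1)) / sum(r1), tolerance = 1e-12)
  expect_equal(st$mu1[2], sum((132:255) * colSums(r3)) / sum(r3), tolerance = 1e-12)
})

test_that("objective is NA at infeasible vectors and minimal for separated point masses", {
  h <- two_spike_hist()
  expect_true(is.na(relative_entropy_objective(h, c(20, 20))))
  d_sep <- relative_entropy_objective(h, c(100, 100))
  # with each class a point mass at its own mean the class divergences vanish
  expect_equal(d_sep, ref_objective_direct(h, 100, 100), tolerance = 1e-10)
  surf <- objective_surface(h)
  expect_equal(min(surf, na.rm = TRUE), d_sep, tolerance = 1e-10)
})

test_that("objective equals direct term-by-term summation on random histograms", {
  h <- rand_hist(64, seed = 81)
  for (st in list(c(10, 20), c(31, 31), c(50, 12), c(5, 60))) {
    expect_equal(relative_entropy_objective(h, st),
                 ref_objective_direct(h, st[1], st[2]), tolerance = 1e-8)
  }
})

test_that("objective surface agrees with the objective function pointwise", {
  h <- rand_hist(32, seed = 91)
  surf <- objective_surface(h)
  for (s in c(0, 7, 15, 30)) for (t in c(0, 11, 31)) {
    expect_equal(surf[s + 1, t + 1], relative_entropy_objective(h, c(s, t)),
                 tolerance = 1e-9)
  }
})

test_that("threshold selection separates two point masses with lexicographic ties", {
  tv <- select_threshold(two_spike_hist())
  expect_identical(c(tv$s, tv$t), c(50L, 50L))
  expect_equal(tv$P0, 0.4)
  expect_equal(tv$mu1, c(200, 200))
})

test_that("shifting both gray levels shifts the selected vector on point masses", {
  for (shift in c(0L, 15L, 40L)) {
    h <- two_spike_hist(lo = 50L + shift, hi = 200L + shift)
    tv <- select_threshold(h)
    expect_identical(c(tv$s, tv$t), c(50L + shift, 50L + shift))
  }
})

test_that("search equals the naive full scan on random histograms", {
  for (seed in c(101, 102)) {
    h <- rand_hist(64, seed = seed)
    tv <- select_threshold(h)
    want <- ref_scan_argmin(h)
    expect_identical(c(tv$s, tv$t), c(want$s, want$t))
    expect_equal(tv$D, want$D, tolerance = 1e-9)
  }
  # histogram from an actual synthetic two-class image
  sc <- generate_scene(scene_spec(c(48L, 48L), 60, 180, 10,
                                  list(scene_disk(24, 24, 14)), seed = 111L))
  J <- local_mean_image(sc$image)
  h <- build_joint_histogram(sc$image, J)
  tv <- select_threshold(h)
  want <- ref_scan_argmin(h)
  expect_identical(c(tv$s, tv$t), c(want$s, want$t))
})

test_that("degenerate (single-cluster) histograms raise a clear error", {
  img <- matrix(42L, 8, 8)
  h <- build_joint_histogram(img, img)
  expect_error(select_threshold(h), "no feasible threshold")
})

test_that("binarize implements the quadrant + nearest-mean rule", {
  # everything in quadrant 1 -> all background
  img <- matrix(10L, 4, 4)
  expect_identical(binarize(img, img, c(50, 50)), matrix(FALSE, 4, 4))

  # two-level image split by the vector -> ground truth recovered
  sc <- generate_scene(scene_spec(c(32L, 32L), 60, 180, 0,
                                  list(scene_disk(16, 16, 8)), seed = 1L))
  expect_identical(binarize(sc$image, sc$image, c(100, 100)), sc$mask)

  # off-quadrant pixels go to the nearer class mean
  a <- matrix(c(10L, 10L, 200L, 200L, 180L, 30L), 2, 3)
  b <- matrix(c(10L, 10L, 200L, 200L, 20L, 190L), 2, 3)
  got <- binarize(a, b, c(100, 100), L = 256L)
  st <- class_statistics(build_joint_histogram(a, b), c(100, 100))
  want <- matrix(NA, 2, 3)
  for (k in seq_along(a)) {
    i <- a[k]; j <- b[k]
    want[k] <- if (i <= 100 && j <= 100) FALSE
    else if (i > 100 && j > 100) TRUE
    else {
      d0 <- (i - st$mu0[1])^2 + (j - st$mu0[2])^2
      d1 <- (i - st$mu1[1])^2 + (j - st$mu1[2])^2
      d1 < d0
    }
  }
  expect_identical(got, want)
})
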