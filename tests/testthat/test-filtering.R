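test_that("weights on a constant image are uniform and the self term is maximal", {
  img <- matrix(100L, 7, 7)
  w <- nlm_weights(img, c(4, 4), nlm_params(patch_radius = 1, search_radius = 2))
  expect_equal(sum(w), 1)
  expect_equal(as.vector(w), rep(1 / 25, 25))

  set.seed(7)
  img <- rand_image(9, 9, seed = 7)
  w <- nlm_weights(img, c(5, 5), nlm_params(patch_radius = 1, search_radius = 3))
  cand <- attr(w, "candidates")
  self <- which(cand[, 1] == 5 & cand[, 2] == 5)
  expect_equal(which.max(w), self)
  expect_equal(sum(w), 1, tolerance = 1e-12)
})

test_that("weights match a direct evaluation of the weight formula", {
  img <- rand_image(5, 5, seed = 11)
  h <- 10; sigma <- 1; pr <- 1L
  w <- nlm_weights(img, c(3, 2), nlm_params(patch_radius = pr, search_radius = "full",
                                            h = h, sigma = sigma))
  cand <- attr(w, "candidates")
  Pi <- ref_patch(img, 3, 2, pr)
  raw <- vapply(seq_len(nrow(cand)), function(k) {
    Pj <- ref_patch(img, cand[k, 1], cand[k, 2], pr)
    exp(-sum((Pi - Pj)^2) / (h^2 * sigma^2))
  }, numeric(1))
  expect_equal(as.vector(w), raw / sum(raw), tolerance = 1e-12)
})

test_that("filtering a constant image is exactly idempotent", {
  img <- matrix(100L, 12, 10)
  out <- nlm_filter(img, nlm_params(patch_radius = 2, search_radius = 4))
  expect_identical(out, matrix(100L, 12, 10))
})

test_that("with tiny h the self weight dominates away from edges", {
  img <- matrix(40L, 16, 16)
  img[, 9:16] <- 200L
  p <- nlm_params(patch_radius = 1, search_radius = 3, h = 1e-3, sigma = 1)
  out <- nlm_filter(img, p)
  expect_identical(out[8, 4], 40L)   # deep inside the left plateau
  expect_identical(out[8, 13], 200L) # deep inside the right plateau
})

test_that("vectorized filter matches the quadruple-loop reference", {
  img <- generate_scene(scene_spec(c(16L, 16L), 80, 170, 12,
                                   list(scene_disk(8, 8, 5)), seed = 5L))$image
  for (sr in list(3L, "full")) {
    p <- nlm_params(patch_radius = 1, search_radius = sr, h = 10, sigma = 1)
    got <- nlm_filter(img, p, quantize = FALSE)
    want <- ref_nlm(img, pr = 1L, sr = sr, h = 10, sigma = 1)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("edge padding mode matches the reference too", {
  img <- rand_image(10, 12, seed = 3)
  p <- nlm_params(patch_radius = 2, search_radius = 3, h = 20, sigma = 1,
                  pad_mode = "edge")
  got <- nlm_filter(img, p, quantize = FALSE)
  want <- ref_nlm(img, pr = 2L, sr = 3L, h = 20, sigma = 1, mode = "edge")
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("pre-rounding output stays within the input range", {
  img <- rand_image(20, 20, seed = 17)
  y <- nlm_filter(img, nlm_params(patch_radius = 2, search_radius = 5, h = 50),
                  quantize = FALSE)
  expect_true(all(y >= min(img) - 1e-9))
  expect_true(all(y <= max(img) + 1e-9))
  q <- nlm_filter(img, nlm_params(patch_radius = 2, search_radius = 5, h = 50))
  expect_true(all(q >= 0L & q <= 255L))
})

test_that("strong filtering reduces within-class variance on a noisy scene", {
  sc <- generate_scene(scene_spec(c(48L, 48L), 60, 180, 10,
                                  list(scene_disk(24, 24, 12)), seed = 9L))
  # h = 10 * noise sigma
  out <- nlm_filter(sc$image, nlm_params(patch_radius = 2, search_radius = 5,
                                         h = 100, sigma = 1))
  wcv <- function(img, mask) {
    stats::var(as.numeric(img[mask])) * (sum(mask) - 1) +
      stats::var(as.numeric(img[!mask])) * (sum(!mask) - 1)
  }
  expect_lt(wcv(out, sc$mask), wcv(sc$image, sc$mask))
})

test_that("invalid parameters and inputs are rejected", {
  expect_error(nlm_params(h = 0), "h must be")
  expect_error(nlm_params(h = -2), "h must be")
  expect_error(nlm_params(sigma = 0), "sigma must be")
  expect_error(nlm_params(search_radius = 0), "search_radius")
  expect_error(nlm_params(patch_radius = -1), "patch_radius")
  expect_error(nlm_filter(matrix(numeric(0), 0, 0)), "empty|matrix")
  expect_error(nlm_filter(matrix(1.5, 3, 3)), "integer")
  expect_error(nlm_filter(matrix(300L, 3, 3)), "\\[0, 255\\]")
})
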