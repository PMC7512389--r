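# Deterministic generator of two-class test images with exact ground truth.
# Scenes are foreground primitives (disks, rectangles) on a uniform
# background, two distinct mean gray levels, plus additive Gaussian noise
# rounded and clipped back to the gray-level range.

#' Scene primitives
#'
#' Foreground primitives for [scene_spec()].  A pixel belongs to a disk if its
#' center lies within the radius (pixel-center sampling); rectangle bounds are
#' inclusive.
#'
#' @param cr,cc center (row, col) of the disk, in pixels.
#' @param r disk radius in pixels.
#' @return an object describing the primitive.
#' @export
scene_disk <- function(cr, cc, r) {
  structure(list(kind = "disk", cr = cr, cc = cc, r = r), class = "scene_object")
}

#' @rdname scene_disk
#' @param r0,r1,c0,c1 inclusive row/column bounds of the rectangle.
#' @export
scene_rect <- function(r0, r1, c0, c1) {
  structure(list(kind = "rect", r0 = r0, r1 = r1, c0 = c0, c1 = c1),
            class = "scene_object")
}

#' Specification of a synthetic two-class scene
#'
#' @param shape image size `c(M, N)`.
#' @param bg_level,fg_level mean gray level of background and foreground; must
#'   differ, both in `[0, L-1]`.
#' @param noise_sigma standard deviation of the additive Gaussian noise (gray
#'   levels); 0 gives a noiseless two-level image.
#' @param objects list of [scene_disk()] / [scene_rect()] primitives.
#' @param seed integer RNG seed; the scene is fully determined by its spec.
#' @param L gray-level count.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(shape = c(64L, 64L), bg_level = 60L, fg_level = 180L,
                       noise_sigma = 10, objects = list(scene_disk(32, 32, 16)),
                       seed = 1L, L = 256L) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 1L)) {
    stop("shape must be two positive integers c(M, N)", call. = FALSE)
  }
  if (bg_level == fg_level) {
    stop("bg_level and fg_level must differ", call. = FALSE)
  }
  if (any(c(bg_level, fg_level) < 0) || any(c(bg_level, fg_level) > L - 1)) {
    stop(sprintf("gray levels must lie in [0, %d]", L - 1L), call. = FALSE)
  }
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (!all(vapply(objects, inherits, logical(1L), "scene_object"))) {
    stop("objects must be scene_disk()/scene_rect() primitives", call. = FALSE)
  }
  structure(list(shape = shape, bg_level = as.integer(bg_level),
                 fg_level = as.integer(fg_level),
                 noise_sigma = as.numeric(noise_sigma),
                 objects = objects, seed = as.integer(seed), L = as.integer(L)),
            class = "scene_spec")
}

# evaluate code with a local seed, leaving the caller's RNG state untouched
with_scene_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

rasterize_objects <- function(shape, objects) {
  M <- shape[1L]; N <- shape[2L]
  rows <- matrix(seq_len(M), M, N)
  cols <- matrix(seq_len(N), M, N, byrow = TRUE)
  mask <- matrix(FALSE, M, N)
  for (ob in objects) {
    mask <- mask | switch(ob$kind,
      disk = (rows - ob$cr)^2 + (cols - ob$cc)^2 <= ob$r^2,
      rect = rows >= ob$r0 & rows <= ob$r1 & cols >= ob$c0 & cols <= ob$c1
    )
  }
  mask
}

#' Generate a synthetic scene
#'
#' Deterministic given the spec (including its seed).  The returned mask is
#' the exact noiseless class assignment; the image is the per-pixel class
#' mean plus `N(0, noise_sigma^2)` noise, rounded half-up and clipped to
#' `[0, L-1]`.
#'
#' @param spec a [scene_spec()].
#' @return list with `image` (integer gray-image matrix), `mask` (logical
#'   ground truth, `TRUE` = foreground) and `spec`.
#' @export
generate_scene <- function(spec) {
  if (!inherits(spec, "scene_spec")) stop("spec must be a scene_spec()", call. = FALSE)
  mask <- rasterize_objects(spec$shape, spec$objects)
  levels <- ifelse(mask, spec$fg_level, spec$bg_level)
  img <- if (spec$noise_sigma > 0) {
    noise <- with_scene_seed(spec$seed,
      matrix(stats::rnorm(length(levels), sd = spec$noise_sigma),
             spec$shape[1L], spec$shape[2L]))
    levels + noise
  } else {
    levels
  }
  img <- pmin(pmax(round_half_up(img), 0), spec$L - 1)
  storage.mode(img) <- "integer"
  list(image = img, mask = mask, spec = spec)
}

#' Fixed suites of synthetic scenes
#'
#' Named, fully deterministic collections of two-class scenes used for
#' testing and benchmarking:
#' \describe{
#'   \item{"clean"}{4 noiseless scenes (contrast 120 gray levels) with varied
#'     shapes; every method should segment them perfectly.}
#'   \item{"noisy"}{10 scenes, 64x64, background 60 / foreground 180
#'     (contrast 120), Gaussian noise sigma = 10, one disk of varying radius
#'     and position per scene.}
#'   \item{"small-objects"}{6 scenes with small disks (radius 3--5) on a
#'     larger field, sigma = 5.}
#'   \item{"low-contrast"}{6 scenes with contrast 40 (100 vs 140),
#'     sigma = 8.}
#' }
#'
#' @param preset suite name.
#' @return list of scenes as returned by [generate_scene()].
#' @export
generate_suite <- function(preset = c("clean", "noisy", "small-objects",
                                      "low-contrast")) {
  preset <- match.arg(preset)
  specs <- switch(preset,
    "clean" = list(
      scene_spec(c(64L, 64L), 60, 180, 0, list(scene_disk(32, 32, 16)), seed = 11L),
      scene_spec(c(64L, 64L), 60, 180, 0, list(scene_rect(16, 48, 16, 48)), seed = 12L),
      scene_spec(c(64L, 64L), 60, 180, 0,
                 list(scene_disk(20, 20, 10), scene_disk(46, 46, 12)), seed = 13L),
      scene_spec(c(80L, 64L), 60, 180, 0,
                 list(scene_disk(24, 32, 12), scene_rect(52, 72, 12, 52)), seed = 14L)
    ),
    "noisy" = lapply(1:10, function(k) {
      scene_spec(c(64L, 64L), 60, 180, 10,
                 list(scene_disk(24 + 2 * (k %% 4), 24 + 2 * (k %% 5), 12 + (k %% 5))),
                 seed = 100L + k)
    }),
    "small-objects" = lapply(1:6, function(k) {
      scene_spec(c(96L, 96L), 80, 200, 5,
                 list(scene_disk(20 + 8 * k, 20 + 6 * k, 3 + (k %% 3)),
                      scene_disk(70, 25 + 8 * k, 4)),
                 seed = 200L + k)
    }),
    "low-contrast" = lapply(1:6, function(k) {
      scene_spec(c(64L, 64L), 100, 140, 8,
                 list(scene_disk(32, 32, 10 + k)), seed = 300L + k)
    })
  )
  lapply(specs, generate_scene)
}
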