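#' Coerce and validate a gray-level image
#'
#' A gray image is an integer matrix of gray levels in `{0, ..., L-1}` with
#' `M >= 1` rows and `N >= 1` columns.  All functions in the package operate on
#' plain matrices; this helper validates and sets integer storage.
#'
#' @param x numeric matrix of integer gray levels.
#' @param L number of gray levels (default 256 for 8-bit images).
#' @return an integer matrix with attribute `L`.
#' @export
as_gray_image <- function(x, L = 256L) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("a gray image must be a numeric matrix", call. = FALSE)
  }
  if (nrow(x) < 1L || ncol(x) < 1L) {
    stop("image must contain at least one pixel", call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop("image contains missing or non-finite values", call. = FALSE)
  }
  if (any(x != floor(x))) {
    stop("gray levels must be integers", call. = FALSE)
  }
  if (any(x < 0) || any(x > L - 1)) {
    stop(sprintf("gray levels must lie in [0, %d]", L - 1L), call. = FALSE)
  }
  storage.mode(x) <- "integer"
  attr(x, "L") <- as.integer(L)
  x
}

# internal: validate without copying attributes around
validate_gray_image <- function(x, L = 256L, what = "image") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("%s must be a numeric matrix of gray levels", what), call. = FALSE)
  }
  if (nrow(x) < 1L || ncol(x) < 1L) stop(sprintf("%s is empty", what), call. = FALSE)
  if (anyNA(x)) stop(sprintf("%s contains missing values", what), call. = FALSE)
  if (any(x < 0) || any(x > L - 1) || any(x != floor(x))) {
    stop(sprintf("%s must hold integer gray levels in [0, %d]", what, L - 1L),
         call. = FALSE)
  }
  storage.mode(x) <- "integer"
  x
}

# round-half-up quantization used everywhere a real-valued image is mapped
# back to integer gray levels
round_half_up <- function(x) floor(x + 0.5)

# indices implementing boundary extension of a length-n axis by r samples.
# "reflect" mirrors without repeating the border sample (period 2n-2),
# "edge" replicates the border sample.  Works for any pad width.
pad_indices <- function(n, r, mode) {
  idx <- seq.int(1L - r, n + r)
  if (mode == "edge") return(pmin.int(pmax.int(idx, 1L), n))
  if (n == 1L) return(rep(1L, length(idx)))
  p <- 2L * n - 2L
  k <- (idx - 1L) %% p
  k <- ifelse(k < 0L, k + p, k)
  as.integer(ifelse(k < n, k + 1L, 2L * n - 1L - k))
}

#' Pad an image at its borders
#'
#' @param img numeric matrix.
#' @param r pad width in pixels (same on all four sides).
#' @param mode `"reflect"` (mirror, border pixel not repeated) or `"edge"`
#'   (border replication).
#' @return a `(M+2r) x (N+2r)` matrix.
#' @export
pad_image <- function(img, r, mode = c("reflect", "edge")) {
  mode <- match.arg(mode)
  r <- as.integer(r)
  if (r < 0L) stop("pad width must be non-negative", call. = FALSE)
  if (r == 0L) return(img)
  img[pad_indices(nrow(img), r, mode), pad_indices(ncol(img), r, mode), drop = FALSE]
}

#' Read a single-channel grayscale image
#'
#' Supports 8-bit PNG, TIFF and PGM (both ASCII `P2` and binary `P5`).
#' Multi-channel files are rejected rather than silently converted.
#'
#' @param path file path; format is chosen by extension.
#' @param L gray-level count the file is mapped onto (default 256).
#' @return integer gray-image matrix.
#' @export
read_gray_image <- function(path, L = 256L) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") {
    img <- read_pgm(path)
    return(as_gray_image(img, L))
  }
  arr <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported image format '.%s' (use png, tiff or pgm)", ext),
         call. = FALSE)
  )
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3L] == 1L) {
      arr <- arr[, , 1L]
    } else {
      stop("multi-channel image; supply a single-channel grayscale file",
           call. = FALSE)
    }
  }
  img <- round_half_up(arr * (L - 1))
  as_gray_image(img, L)
}

#' Write a gray image to PNG, TIFF or PGM
#'
#' @param img integer gray-image matrix.
#' @param path output path; format chosen by extension.
#' @param L gray-level count (default 256).
#' @param ascii for PGM only: write ASCII `P2` (default) instead of binary `P5`.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(img, path, L = 256L, ascii = TRUE) {
  img <- validate_gray_image(img, L)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(img / (L - 1), path),
    tif  = ,
    tiff = tiff::writeTIFF(img / (L - 1), path, bits.per.sample = 8L),
    pgm  = write_pgm(img, path, L = L, ascii = ascii),
    stop(sprintf("unsupported image format '.%s' (use png, tiff or pgm)", ext),
         call. = FALSE)
  )
  invisible(path)
}

# -- PGM ----------------------------------------------------------------------
# Minimal portable graymap reader/writer (P2 ASCII, P5 binary, maxval <= 255).

read_pgm <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  # tokenizer over the header: whitespace-separated tokens, '#' starts a
  # comment running to end of line
  pos <- 1L
  n <- length(raw)
  next_token <- function() {
    tok <- character(0)
    repeat {
      if (pos > n) stop("truncated PGM header", call. = FALSE)
      ch <- rawToChar(raw[pos])
      if (ch == "#") {
        while (pos <= n && !rawToChar(raw[pos]) %in% c("\n", "\r")) pos <<- pos + 1L
      } else if (grepl("[[:space:]]", ch)) {
        if (length(tok) > 0L) break
        pos <<- pos + 1L
      } else {
        tok <- c(tok, ch)
        pos <<- pos + 1L
      }
    }
    paste(tok, collapse = "")
  }
  magic <- next_token()
  if (!magic %in% c("P2", "P5")) {
    stop("not a PGM file (expected magic P2 or P5)", call. = FALSE)
  }
  w <- as.integer(next_token())
  h <- as.integer(next_token())
  maxval <- as.integer(next_token())
  if (is.na(w) || is.na(h) || is.na(maxval) || w < 1L || h < 1L) {
    stop("invalid PGM header", call. = FALSE)
  }
  if (maxval > 255L) stop("16-bit PGM not supported", call. = FALSE)
  if (magic == "P2") {
    txt <- rawToChar(raw[pos:n])
    vals <- suppressWarnings(as.integer(scan(text = txt, what = character(),
                                             comment.char = "#", quiet = TRUE)))
  } else {
    pos <- pos + 1L  # single whitespace byte after maxval
    vals <- as.integer(raw[pos:(pos + w * h - 1L)])
  }
  if (length(vals) < w * h || anyNA(vals[seq_len(w * h)])) {
    stop("PGM pixel data truncated or malformed", call. = FALSE)
  }
  matrix(vals[seq_len(w * h)], nrow = h, ncol = w, byrow = TRUE)
}

write_pgm <- function(img, path, L = 256L, ascii = TRUE) {
  h <- nrow(img); w <- ncol(img)
  header <- sprintf("%s\n%d %d\n%d\n", if (ascii) "P2" else "P5", w, h, L - 1L)
  if (ascii) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(header, con, eos = NULL)
    body <- apply(img, 1L, paste, collapse = " ")
    writeChar(paste0(paste(body, collapse = "\n"), "\n"), con, eos = NULL)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(header, con, eos = NULL)
    writeBin(as.raw(as.vector(t(img))), con)
  }
  invisible(path)
}
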