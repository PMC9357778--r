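#' Construct a grayscale image
#'
#' A `gray_image` is an integer-valued matrix of pixel intensities together
#' with the number of representable gray levels `levels` (h). All pixel
#' values must lie in `[0, levels - 1]`.
#'
#' @param pixels numeric matrix of non-negative integer gray values.
#' @param levels number of distinct possible gray values (default 256).
#' @return an object of class `gray_image` (a matrix with attribute
#'   `levels`).
#' @export
gray_image <- function(pixels, levels = 256L) {
  pixels <- as.matrix(pixels)
  if (length(pixels) == 0L) stop("image must be non-empty")
  if (anyNA(pixels) || any(!is.finite(pixels))) stop("image contains non-finite values")
  if (any(pixels != round(pixels))) stop("pixel values must be integers")
  if (any(pixels < 0) || any(pixels > levels - 1)) {
    stop(sprintf("pixel values must lie in [0, %d]", levels - 1L))
  }
  structure(pixels, levels = as.integer(levels), class = c("gray_image", class(pixels)))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, %d levels>\n", nrow(x), ncol(x), img_levels(x)))
  invisible(x)
}

img_levels <- function(image) {
  lv <- attr(image, "levels")
  if (is.null(lv)) 256L else as.integer(lv)
}

as_gray_matrix <- function(image) {
  m <- unclass(image)
  attr(m, "levels") <- NULL
  m
}

# Shift a matrix by (dr, dc), filling vacated cells with `fill`.
shift_matrix <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  r_src <- seq_len(nr) - dr
  c_src <- seq_len(nc) - dc
  r_ok <- r_src >= 1 & r_src <= nr
  c_ok <- c_src >= 1 & c_src <= nc
  if (any(r_ok) && any(c_ok)) {
    out[r_ok, c_ok] <- m[r_src[r_ok], c_src[c_ok], drop = FALSE]
  }
  out
}

# Windowed box sums with truncation at the borders: entry (i,j) of the
# result is the sum of x over the (2k+1)x(2k+1) window centred at (i,j)
# intersected with the image. Companion count matrix gives the number of
# in-image pixels in each window.
box_sum <- function(x, half) {
  nr <- nrow(x); nc <- ncol(x)
  cs <- function(m) {
    p <- rbind(0, apply(m, 2, cumsum))
    hi <- pmin(seq_len(nr) + half, nr) + 1L
    lo <- pmax(seq_len(nr) - half, 1L)
    m2 <- p[hi, , drop = FALSE] - p[lo, , drop = FALSE]
    p2 <- cbind(0, t(apply(m2, 1, cumsum)))
    hic <- pmin(seq_len(nc) + half, nc) + 1L
    loc <- pmax(seq_len(nc) - half, 1L)
    p2[, hic, drop = FALSE] - p2[, loc, drop = FALSE]
  }
  cs(x)
}

box_count <- function(nr, nc, half) {
  rc <- pmin(seq_len(nr) + half, nr) - pmax(seq_len(nr) - half, 1L) + 1L
  cc <- pmin(seq_len(nc) + half, nc) - pmax(seq_len(nc) - half, 1L) + 1L
  outer(rc, cc)
}

#' Read / write plain PGM (P2) grayscale images
#'
#' Plain-text portable graymap is the package's on-disk image format: it
#' round-trips integer gray values exactly and needs no binary dependencies.
#'
#' @param path file path.
#' @return `read_pgm` returns a [gray_image].
#' @export
read_pgm <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- sub("#.*$", "", txt)
  toks <- scan(text = paste(txt, collapse = " "), what = character(), quiet = TRUE)
  if (length(toks) < 4L || toks[1] != "P2") stop("unsupported image format; supported: plain PGM (P2)")
  w <- as.integer(toks[2]); h <- as.integer(toks[3]); maxval <- as.integer(toks[4])
  vals <- as.integer(toks[-(1:4)])
  if (length(vals) != w * h) stop("corrupt PGM: pixel count mismatch")
  gray_image(matrix(vals, nrow = h, ncol = w, byrow = TRUE), levels = maxval + 1L)
}

#' @rdname read_pgm
#' @param image a [gray_image] or integer matrix.
#' @export
write_pgm <- function(image, path) {
  m <- as_gray_matrix(image)
  maxval <- img_levels(image) - 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(m), nrow(m)), as.character(maxval)), con)
  apply(m, 1, function(row) writeLines(paste(row, collapse = " "), con))
  invisible(path)
}
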