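# Grayscale image container, preprocessing and resampling primitives used
# by the registration stage.  Images are plain numeric matrices (rows = y,
# columns = x) with a physical pixel size; coordinates are in um with the
# centre of pixel [1, 1] at (0, 0), x increasing along columns and y along
# rows.

#' Construct a grayscale image with physical pixel size
#'
#' @param pixels numeric matrix of intensities (rows = y, columns = x).
#' @param pixel_size physical size of one pixel in um (> 0).
#' @return object of class `gray_image`: the matrix with attributes
#'   `pixel_size` (um/pixel).
#' @export
gray_image <- function(pixels, pixel_size) {
  if (!is.matrix(pixels) || !is.numeric(pixels) || length(pixels) == 0L)
    stop_invalid("'pixels' must be a non-empty numeric matrix")
  if (anyNA(pixels) || any(!is.finite(pixels)))
    stop_invalid("image intensities must be finite")
  check_number(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  structure(pixels, pixel_size = pixel_size, class = c("gray_image", "matrix"))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d pixels, %.4g um/pixel (%.4g x %.4g um)\n",
              nrow(x), ncol(x), pixel_size(x),
              ncol(x) * pixel_size(x), nrow(x) * pixel_size(x)))
  invisible(x)
}

#' Pixel size of a grayscale image
#' @param img a [gray_image()].
#' @return pixel size in um/pixel.
#' @export
pixel_size <- function(img) attr(img, "pixel_size")

#' Preprocess a raw image for registration
#'
#' Converts a multi-channel image to luminance grayscale, downsamples by
#' the smallest integer factor (block averaging) that brings both
#' dimensions under `max_dim` pixels, scales the pixel size accordingly,
#' and min--max normalizes intensities to [0, 1].  A constant image is
#' normalized to all zeros with a warning.
#'
#' @param image numeric matrix (grayscale) or 3-d array (rows x cols x
#'   channels, RGB assumed for 3+ channels).
#' @param pixel_size physical pixel size of the input, um/pixel.
#' @param max_dim both output dimensions must be strictly below this
#'   pixel count (default 2000).
#' @return a [gray_image()] with intensities in [0, 1].
#' @export
preprocess <- function(image, pixel_size, max_dim = 2000) {
  if (is.null(dim(image)) || length(image) == 0L)
    stop_invalid("'image' must be a non-empty matrix or array")
  check_number(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  if (length(dim(image)) == 3L) {
    nc <- dim(image)[3L]
    image <- if (nc >= 3L) {
      # Rec. 709 luminance
      0.2126 * image[, , 1L] + 0.7152 * image[, , 2L] + 0.0722 * image[, , 3L]
    } else image[, , 1L]
  }
  image <- as.matrix(image)
  f <- max(1L, ceiling(max(dim(image)) / (max_dim - 1L)))
  while (any(ceiling(dim(image) / f) >= max_dim)) f <- f + 1L
  if (f > 1L) image <- block_mean(image, f)
  rng <- range(image)
  if (rng[2L] > rng[1L]) {
    image <- (image - rng[1L]) / (rng[2L] - rng[1L])
  } else {
    warning("constant image: normalized to all zeros")
    image <- array(0, dim(image))
  }
  gray_image(image, pixel_size * f)
}

# Block-average downsampling by an integer factor; partial edge blocks are
# averaged over the pixels they contain.
block_mean <- function(m, f) {
  f <- as.integer(f)
  nr <- ceiling(nrow(m) / f)
  nc <- ceiling(ncol(m) / f)
  ri <- (seq_len(nrow(m)) - 1L) %/% f + 1L
  ci <- (seq_len(ncol(m)) - 1L) %/% f + 1L
  sums <- rowsum(m, ri)                     # collapse rows
  sums <- t(rowsum(t(sums), ci))            # collapse columns
  cnt <- tcrossprod(tabulate(ri, nr), tabulate(ci, nc))
  sums / cnt
}

# Vectorized bilinear interpolation of matrix `img` at physical points
# (x, y) in um.  Points outside the grid are clamped to the border.
interp_bilinear <- function(img, x, y, psz) {
  gx <- x / psz
  gy <- y / psz
  nx <- ncol(img); ny <- nrow(img)
  gx <- pmin(pmax(gx, 0), nx - 1)
  gy <- pmin(pmax(gy, 0), ny - 1)
  j0 <- pmin(floor(gx), nx - 2); i0 <- pmin(floor(gy), ny - 2)
  tx <- gx - j0; ty <- gy - i0
  i0 <- i0 + 1L; j0 <- j0 + 1L   # 1-based
  idx <- function(i, j) (j - 1L) * ny + i
  v00 <- img[idx(i0, j0)];     v01 <- img[idx(i0, j0 + 1L)]
  v10 <- img[idx(i0 + 1L, j0)]; v11 <- img[idx(i0 + 1L, j0 + 1L)]
  (1 - ty) * ((1 - tx) * v00 + tx * v01) + ty * ((1 - tx) * v10 + tx * v11)
}

# Bilinear interpolation that tolerates NA grid values (e.g. a field
# defined only on a mask): NA corners get zero weight and the remaining
# weights are renormalized; all-NA neighborhoods return NA.
interp_bilinear_na <- function(img, x, y, psz) {
  gx <- pmin(pmax(x / psz, 0), ncol(img) - 1)
  gy <- pmin(pmax(y / psz, 0), nrow(img) - 1)
  ny <- nrow(img)
  j0 <- pmin(floor(gx), ncol(img) - 2); i0 <- pmin(floor(gy), ny - 2)
  tx <- gx - j0; ty <- gy - i0
  i0 <- i0 + 1L; j0 <- j0 + 1L
  w <- cbind((1 - tx) * (1 - ty), tx * (1 - ty), (1 - tx) * ty, tx * ty)
  v <- cbind(img[(j0 - 1L) * ny + i0],       img[j0 * ny + i0],
             img[(j0 - 1L) * ny + i0 + 1L],  img[j0 * ny + i0 + 1L])
  w[is.na(v)] <- 0
  v[is.na(v)] <- 0
  tot <- rowSums(w)
  out <- rowSums(w * v) / tot
  out[tot == 0] <- NA_real_
  out
}

#' Tissue mask from a preprocessed image
#'
#' Otsu threshold on the intensity histogram, morphological closing with a
#' disc, and retention of the largest connected foreground component
#' (morphology via \pkg{EBImage}).
#'
#' @param img a [gray_image()] with intensities in [0, 1].
#' @param closing_radius radius (pixels) of the disc used for closing.
#' @return logical matrix, `TRUE` on tissue.
#' @export
tissue_mask <- function(img, closing_radius = 5) {
  m <- unclass(img)
  attr(m, "pixel_size") <- NULL
  class(m) <- "matrix"
  thr <- EBImage::otsu(EBImage::Image(m), range = c(0, 1))
  fg <- m > thr
  # brightfield tissue may be darker than background; keep the minority phase
  if (mean(fg) > 0.5) fg <- !fg
  kern <- EBImage::makeBrush(2L * as.integer(closing_radius) + 1L, "disc")
  fg <- EBImage::closing(EBImage::Image(fg * 1), kern) > 0.5
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(fg * 1)))
  if (max(lab) < 1) return(matrix(FALSE, nrow(m), ncol(m)))
  sizes <- tabulate(lab[lab > 0])
  matrix(lab == which.max(sizes), nrow(m), ncol(m))
}
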