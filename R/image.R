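# Image utilities shared by the feature extractor, the face pipeline and the
# synthetic generator. Images are plain numeric matrices with intensities in
# [0, 255]; rows index y (top to bottom) and columns index x (left to right).
# Pixel coordinates in the public interface are 0-based with the origin at
# the top-left pixel, so pixel (x, y) lives at matrix cell [y + 1, x + 1].

#' Convert an image to a single grayscale channel
#'
#' Color input (a height x width x 3 array) is collapsed with the standard
#' luma weights 0.299 R + 0.587 G + 0.114 B; grayscale input is returned
#' unchanged. Intensities are expected on the 0-255 scale.
#'
#' @param image a numeric matrix (grayscale) or a 3-d array with 3 (RGB) or
#'   more channels (extra channels beyond the third are ignored).
#' @return a numeric matrix of the same height and width.
#' @examples
#' rgb <- array(0, c(2, 2, 3))
#' rgb[, , 1] <- 100; rgb[, , 2] <- 200; rgb[, , 3] <- 50
#' toGrayscale(rgb)[1, 1] # 0.299*100 + 0.587*200 + 0.114*50
#' @export
toGrayscale <- function(image) {
  if (length(image) == 0) stop("empty image")
  if (is.matrix(image)) return(image)
  if (is.array(image) && length(dim(image)) == 3) {
    if (dim(image)[3] < 3) {
      if (dim(image)[3] == 1) return(image[, , 1])
      stop("color image must have 3 channels")
    }
    return(0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3])
  }
  stop("image must be a matrix or a 3-d array")
}

#' Resize a grayscale image to the canonical square face size
#'
#' Bilinear interpolation to \code{size} x \code{size} pixels (default 100,
#' the canonical face-crop size used throughout the recognition pipeline).
#'
#' @param image numeric matrix.
#' @param size output side length in pixels; must be >= 3.
#' @return a \code{size} x \code{size} numeric matrix.
#' @export
resizeToCanonical <- function(image, size = 100L) {
  if (length(image) == 0) stop("empty image")
  if (size < 3) stop("invalid size: must be >= 3")
  if (nrow(image) == size && ncol(image) == size) return(image)
  out <- EBImage::imageData(EBImage::resize(EBImage::Image(image),
                                            w = size, h = size))
  matrix(as.numeric(out), size, size)
}

#' Corner-removal binary mask for face crops
#'
#' The default mask excludes the four corners of the square face crop
#' (right-isosceles triangles of leg \code{cornerLeg} pixels), keeping the
#' central face area. Corner back-lighting is the main nuisance this
#' suppresses; the same mask is used for every image.
#'
#' A pixel at 0-based coordinates (x, y) is excluded from the top-left
#' corner when x + y < cornerLeg, and symmetrically at the other corners.
#'
#' @param size mask side length in pixels.
#' @param cornerLeg triangle leg in pixels; 0 disables masking. Must lie in
#'   [0, size/2].
#' @return a logical \code{size} x \code{size} matrix; TRUE = pixel included.
#' @export
defaultMask <- function(size = 100L, cornerLeg = 30L) {
  if (cornerLeg < 0 || cornerLeg > size / 2)
    stop("invalid cornerLeg: must be in [0, size/2]")
  x <- matrix(rep(0:(size - 1), each = size), size, size)  # column index
  y <- matrix(rep(0:(size - 1), times = size), size, size) # row index
  keep <- (x + y >= cornerLeg) &
    ((size - 1 - x) + y >= cornerLeg) &
    (x + (size - 1 - y) >= cornerLeg) &
    ((size - 1 - x) + (size - 1 - y) >= cornerLeg)
  keep
}

# Bilinear sample of `image` at 0-based fractional coordinates (xs, ys);
# coordinates are clamped to the image so out-of-canvas samples replicate
# the border.
bilinearSample <- function(image, xs, ys) {
  h <- nrow(image); w <- ncol(image)
  xs <- pmin(pmax(xs, 0), w - 1)
  ys <- pmin(pmax(ys, 0), h - 1)
  x0 <- floor(xs); y0 <- floor(ys)
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  fx <- xs - x0; fy <- ys - y0
  i00 <- image[cbind(y0 + 1, x0 + 1)]
  i01 <- image[cbind(y0 + 1, x1 + 1)]
  i10 <- image[cbind(y1 + 1, x0 + 1)]
  i11 <- image[cbind(y1 + 1, x1 + 1)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

# Warp an image with the inverse of the similarity u = a x - b y + tx,
# v = b x + a y + ty (i.e., for each output pixel, sample the input at the
# pre-image). theta = c(a, b, tx, ty).
warpSimilarity <- function(image, theta, outSize = c(nrow(image), ncol(image))) {
  a <- theta[1]; b <- theta[2]; tx <- theta[3]; ty <- theta[4]
  det <- a * a + b * b
  if (det < 1e-12) stop("degenerate similarity transform")
  h <- outSize[1]; w <- outSize[2]
  u <- matrix(rep(0:(w - 1), each = h), h, w)
  v <- matrix(rep(0:(h - 1), times = w), h, w)
  # inverse: [x; y] = R^-1 ([u; v] - t) with R = [a -b; b a]
  du <- u - tx; dv <- v - ty
  xs <- (a * du + b * dv) / det
  ys <- (-b * du + a * dv) / det
  matrix(bilinearSample(image, as.numeric(xs), as.numeric(ys)), h, w)
}

# Apply a forward similarity to 0-based points given as a 2-column matrix.
applySimilarity <- function(theta, pts) {
  a <- theta[1]; b <- theta[2]
  cbind(a * pts[, 1] - b * pts[, 2] + theta[3],
        b * pts[, 1] + a * pts[, 2] + theta[4])
}

# Least-squares similarity mapping src points onto dst points (both
# 2-column, 0-based x/y). Exact for two point pairs.
fitSimilarity <- function(src, dst) {
  if (nrow(src) < 2) stop("need at least two landmarks")
  A <- do.call(rbind, lapply(seq_len(nrow(src)), function(i) {
    rbind(c(src[i, 1], -src[i, 2], 1, 0),
          c(src[i, 2], src[i, 1], 0, 1))
  }))
  rhs <- as.numeric(t(dst))
  theta <- qr.solve(A, rhs)
  if (theta[1]^2 + theta[2]^2 < 1e-12)
    stop("degenerate landmarks: similarity transform has zero scale")
  theta
}

#' Read an image file as a grayscale intensity matrix
#'
#' PNG/JPEG/TIFF files are read through EBImage and converted to the 0-255
#' grayscale convention used by the package (luma weighting for color).
#'
#' @param path image file path.
#' @return numeric matrix of intensities in [0, 255].
#' @export
readFaceImage <- function(path) {
  img <- EBImage::readImage(path)
  d <- dim(img)
  a <- EBImage::imageData(img)
  if (length(d) == 2) {
    out <- t(a)
  } else {
    out <- toGrayscale(aperm(a, c(2, 1, 3)))
  }
  out * 255
}

#' Write a grayscale intensity matrix to an image file
#'
#' @param image numeric matrix, intensities in [0, 255].
#' @param path output path; format chosen from the extension (.png/.jpg).
#' @param quality JPEG quality (ignored for PNG).
#' @export
writeFaceImage <- function(image, path, quality = 95) {
  img <- EBImage::Image(t(pmin(pmax(image, 0), 255)) / 255)
  EBImage::writeImage(img, path, quality = quality)
  invisible(path)
}
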