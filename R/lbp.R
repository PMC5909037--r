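# Masked block-histogram uniform-LBP features: the descriptor behind the
# identity recognizer. A face crop is converted to grayscale, resized to the
# canonical 100 x 100, LBP-transformed, then summarised as 25 block
# histograms (5 x 5 grid of 20 x 20 px blocks) over the 59 uniform-pattern
# bins, concatenated into a single 1475-element vector.

#' Local binary pattern code of one 3 x 3 neighbourhood
#'
#' Each of the 8 neighbours is compared with the central pixel and the
#' resulting bits are packed into an 8-bit code. Two conventions are
#' supported: \code{"paper"} sets bit = 1 when the centre is strictly
#' lighter than the neighbour (ties give 0); \code{"standard"} sets
#' bit = 1 when the neighbour is at least as light as the centre (the usual
#' texture-analysis convention). The two differ only by a relabelling of
#' codes, which permutes histogram bins without changing their information.
#'
#' Neighbours are ordered clockwise starting at the top-left pixel and bits
#' are packed most-significant-first in that order.
#'
#' @param patch numeric 3 x 3 matrix.
#' @param convention "paper" or "standard".
#' @return integer code in 0-255.
#' @examples
#' lbpCode(matrix(5, 3, 3))          # ties -> 0
#' lbpCode(rbind(c(0, 0, 0), c(0, 9, 0), c(0, 0, 0))) # 255
#' @export
lbpCode <- function(patch, convention = c("paper", "standard")) {
  convention <- match.arg(convention)
  if (!is.matrix(patch) || any(dim(patch) != c(3, 3)))
    stop("patch must be 3 x 3")
  centre <- patch[2, 2]
  # clockwise from top-left: positions (row, col)
  nb <- c(patch[1, 1], patch[1, 2], patch[1, 3], patch[2, 3],
          patch[3, 3], patch[3, 2], patch[3, 1], patch[2, 1])
  bits <- if (convention == "paper") centre > nb else nb >= centre
  sum(as.integer(bits) * 2L^(7:0))
}

#' LBP transform of a grayscale image
#'
#' Computes the 8-neighbour LBP code of every interior pixel. The 1-pixel
#' border has no full neighbourhood; it is returned as NA and is never
#' counted in block histograms.
#'
#' @param image numeric matrix, at least 3 x 3.
#' @inheritParams lbpCode
#' @return integer matrix of codes (0-255) with an NA border, same shape as
#'   the input.
#' @export
lbpTransform <- function(image, convention = c("paper", "standard")) {
  convention <- match.arg(convention)
  h <- nrow(image); w <- ncol(image)
  if (is.null(h) || h < 3 || w < 3) stop("image must be at least 3 x 3")
  centre <- image[2:(h - 1), 2:(w - 1)]
  offsets <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
                  c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  weights <- 2L^(7:0)
  codes <- matrix(0L, h - 2, w - 2)
  for (k in seq_along(offsets)) {
    dr <- offsets[[k]][1]; dc <- offsets[[k]][2]
    nb <- image[(2 + dr):(h - 1 + dr), (2 + dc):(w - 1 + dc)]
    bit <- if (convention == "paper") centre > nb else nb >= centre
    codes <- codes + weights[k] * bit
  }
  out <- matrix(NA_integer_, h, w)
  out[2:(h - 1), 2:(w - 1)] <- codes
  out
}

#' Map from LBP codes to uniform-pattern histogram bins
#'
#' An LBP code is uniform when its 8-bit pattern, read circularly, has at
#' most two 0/1 transitions (such patterns correspond to local edges,
#' corners and flat spots). Exactly 58 of the 256 codes are uniform; they
#' are assigned bins 1-58 in ascending code order and all remaining codes
#' share the catch-all bin 59.
#'
#' @return integer vector of length 256: \code{bin[code + 1]} is the 1-based
#'   histogram bin of \code{code}.
#' @export
uniformBinMap <- function() {
  codes <- 0:255
  transitions <- vapply(codes, function(code) {
    bits <- as.integer(intToBits(code))[1:8]
    sum(bits != bits[c(2:8, 1)])
  }, integer(1))
  uniform <- transitions <= 2
  bin <- rep(59L, 256L)
  bin[uniform] <- seq_len(sum(uniform))
  bin
}

#' Block-wise uniform-LBP histogram feature vector
#'
#' The code image is divided into a \code{grid} x \code{grid} array of
#' equally sized blocks (row-major order). Each block contributes a 59-bin
#' histogram of the uniform-pattern bins of its in-mask, non-border pixels;
#' the histograms are concatenated. With a 5 x 5 grid this is the
#' 25 x 59 = 1475 element vector used for recognition.
#'
#' @param codes integer code matrix from [lbpTransform()] (NA border).
#' @param mask logical inclusion matrix of the same shape, or NULL for all
#'   pixels.
#' @param grid blocks per side; the image side must be divisible by it.
#' @param binMap code-to-bin table from [uniformBinMap()].
#' @param normalize when TRUE (default) each non-empty block histogram is
#'   L1-normalised to sum to 1, making features independent of the number of
#'   counted pixels per block; when FALSE raw counts are returned.
#' @return numeric vector of length \code{grid^2 * 59}, blocks in row-major
#'   order, bins in \code{binMap} order.
#' @export
blockHistogramFeatures <- function(codes, mask = NULL, grid = 5L,
                                   binMap = uniformBinMap(),
                                   normalize = TRUE) {
  h <- nrow(codes); w <- ncol(codes)
  if (is.null(mask)) mask <- matrix(TRUE, h, w)
  if (!all(dim(mask) == c(h, w)))
    stop("mask dimensions must match the code image")
  if (h %% grid != 0 || w %% grid != 0)
    stop("image side must be divisible by the block grid")
  bh <- h %/% grid; bw <- w %/% grid
  nbins <- max(binMap)
  out <- numeric(grid * grid * nbins)
  pos <- 0L
  for (br in seq_len(grid)) {
    rows <- ((br - 1) * bh + 1):(br * bh)
    for (bc in seq_len(grid)) {
      cols <- ((bc - 1) * bw + 1):(bc * bw)
      blockCodes <- codes[rows, cols]
      blockMask <- mask[rows, cols] & !is.na(blockCodes)
      counted <- blockCodes[blockMask]
      hist <- tabulate(binMap[counted + 1L], nbins = nbins)
      if (normalize && sum(hist) > 0) hist <- hist / sum(hist)
      out[pos + seq_len(nbins)] <- hist
      pos <- pos + nbins
    }
  }
  out
}

#' Default feature-extraction configuration
#'
#' @param size canonical face size in pixels.
#' @param cornerLeg corner-mask triangle leg in pixels (see [defaultMask()]).
#' @param grid block grid per side.
#' @param normalize per-block L1 normalisation flag.
#' @param convention LBP comparison convention (see [lbpCode()]).
#' @return a list of configuration values accepted by [extractFeatures()].
#' @export
featureConfig <- function(size = 100L, cornerLeg = 30L, grid = 5L,
                          normalize = TRUE,
                          convention = c("paper", "standard")) {
  list(size = as.integer(size), cornerLeg = as.integer(cornerLeg),
       grid = as.integer(grid), normalize = isTRUE(normalize),
       convention = match.arg(convention))
}

#' Extract the masked block-histogram LBP feature vector of a face image
#'
#' Full descriptor pipeline: grayscale conversion, bilinear resize to the
#' canonical square, corner mask, LBP transform, and per-block
#' uniform-pattern histograms. Deterministic: the same input always yields
#' the same vector.
#'
#' @param image grayscale matrix or RGB array, any size.
#' @param mask logical matrix of the canonical size, or NULL to use
#'   [defaultMask()] with the configured corner leg.
#' @param config configuration list from [featureConfig()].
#' @return numeric feature vector (length 1475 under the default 5 x 5 grid).
#' @examples
#' img <- matrix(runif(10000, 0, 255), 100, 100)
#' length(extractFeatures(img)) # 1475
#' @export
extractFeatures <- function(image, mask = NULL, config = featureConfig()) {
  gray <- toGrayscale(image)
  gray <- resizeToCanonical(gray, config$size)
  if (is.null(mask)) mask <- defaultMask(config$size, config$cornerLeg)
  codes <- lbpTransform(gray, config$convention)
  blockHistogramFeatures(codes, mask, grid = config$grid,
                         normalize = config$normalize)
}

#' Extract features for a list of images
#'
#' @param images list of images accepted by [extractFeatures()].
#' @inheritParams extractFeatures
#' @return numeric matrix, one row per image.
#' @export
extractFeatureMatrix <- function(images, mask = NULL,
                                 config = featureConfig()) {
  mat <- t(vapply(images, extractFeatures, mask = mask, config = config,
                  FUN.VALUE = numeric(config$grid^2 * 59)))
  rownames(mat) <- names(images)
  mat
}
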