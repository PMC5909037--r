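# Combination face detection/validation geometry. A face candidate crop is
# only accepted as "Good" when an eye detector fires in each upper quadrant
# (image-left quadrant = subject's right eye) and a nose detector fires in
# the central column. Candidate generation is a pluggable backend; the
# reference backend is a normalised cross-correlation (NCC) template matcher
# so the whole pipeline runs without any external model files. An adapter
# for externally trained cascade models can be slotted in through the same
# backend interface.
#
# A backend is a function(image, region) returning a data.frame with
# columns x, y, w, h (0-based, half-open boxes inside `region`) and score
# (higher = stronger); it must be deterministic for a fixed input.

# Fast NCC map via FFT convolution (EBImage::filter2). Returns a matrix of
# the same shape as `image`; cell [y+1, x+1] holds the NCC between the
# template and the window centred on pixel (x, y). Cells closer than half a
# template to the border are NA.
nccMap <- function(image, template) {
  th <- nrow(template); tw <- ncol(template)
  if (th %% 2 == 0 || tw %% 2 == 0)
    stop("template dimensions must be odd")
  n <- th * tw
  t0 <- template - mean(template)
  sdT <- sqrt(sum(t0 * t0))
  if (sdT < 1e-12) stop("flat template")
  flip <- function(m) m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE]
  ones <- matrix(1, th, tw)
  # filter2 performs convolution (kernel flipped); flip to get correlation
  num <- EBImage::imageData(EBImage::filter2(EBImage::Image(image),
                                             flip(t0), boundary = "replicate"))
  s1 <- EBImage::imageData(EBImage::filter2(EBImage::Image(image),
                                            ones, boundary = "replicate"))
  s2 <- EBImage::imageData(EBImage::filter2(EBImage::Image(image * image),
                                            ones, boundary = "replicate"))
  localVar <- pmax(s2 - s1 * s1 / n, 0)
  # flat windows have true variance 0 but FFT roundoff leaves a tiny
  # positive residue that would blow up the ratio; windows with per-pixel
  # intensity variance below 0.25 carry no feature and score 0
  flat <- localVar < 0.25 * n
  ncc <- num / (sqrt(localVar) * sdT + 1e-12)
  ncc[flat] <- 0
  hr <- (th - 1) %/% 2; hc <- (tw - 1) %/% 2
  out <- matrix(NA_real_, nrow(image), ncol(image))
  rows <- (hr + 1):(nrow(image) - hr)
  cols <- (hc + 1):(ncol(image) - hc)
  if (length(rows) > 0 && length(cols) > 0)
    out[rows, cols] <- ncc[rows, cols]
  out
}

# Greedy non-maximum suppression of scored boxes (data.frame x,y,w,h,score).
suppressOverlaps <- function(boxes, iouThreshold = 0.3) {
  if (nrow(boxes) <= 1) return(boxes)
  boxes <- boxes[order(-boxes$score), , drop = FALSE]
  keep <- logical(nrow(boxes))
  for (i in seq_len(nrow(boxes))) {
    if (i == 1 || all(boxIoU(boxes[i, ], boxes[keep, , drop = FALSE]) <
                      iouThreshold)) keep[i] <- TRUE
  }
  boxes[keep, , drop = FALSE]
}

# IoU of one box against each row of a box data.frame.
boxIoU <- function(box, others) {
  x0 <- pmax(box$x, others$x)
  y0 <- pmax(box$y, others$y)
  x1 <- pmin(box$x + box$w, others$x + others$w)
  y1 <- pmin(box$y + box$h, others$y + others$h)
  inter <- pmax(x1 - x0, 0) * pmax(y1 - y0, 0)
  union <- box$w * box$h + others$w * others$h - inter
  inter / union
}

#' Reference NCC template-matching detector backend
#'
#' Builds a detector backend that scores every position of \code{template}
#' inside the queried region by normalised cross-correlation and returns
#' local maxima above \code{threshold} as candidate boxes (after
#' non-maximum suppression). Serves as the reference feature detector for
#' the validation geometry; the same interface can host externally trained
#' cascade detectors.
#'
#' @param template numeric matrix with odd dimensions (an image patch of the
#'   feature to find).
#' @param threshold minimum NCC score in (0, 1) for a hit.
#' @param maxHits at most this many highest-scoring hits are returned.
#' @return a backend \code{function(image, region)}; \code{region} is
#'   \code{c(x0, x1, y0, y1)} half-open in 0-based full-image coordinates
#'   (NULL = whole image). Returns a data.frame x, y, w, h, score.
#' @export
templateBackend <- function(template, threshold = 0.55, maxHits = 5L) {
  force(template); force(threshold); force(maxHits)
  th <- nrow(template); tw <- ncol(template)
  function(image, region = NULL) {
    if (is.null(region)) region <- c(0, ncol(image), 0, nrow(image))
    sub <- image[(region[3] + 1):region[4], (region[1] + 1):region[2],
                 drop = FALSE]
    empty <- data.frame(x = numeric(0), y = numeric(0), w = numeric(0),
                        h = numeric(0), score = numeric(0))
    if (nrow(sub) < th || ncol(sub) < tw) return(empty)
    ncc <- nccMap(sub, template)
    hits <- which(!is.na(ncc) & ncc >= threshold, arr.ind = TRUE)
    if (nrow(hits) == 0) return(empty)
    boxes <- data.frame(
      x = region[1] + hits[, 2] - 1 - (tw - 1) %/% 2,
      y = region[3] + hits[, 1] - 1 - (th - 1) %/% 2,
      w = tw, h = th,
      score = ncc[hits])
    boxes <- suppressOverlaps(boxes, 0.3)
    utils::head(boxes[order(-boxes$score), , drop = FALSE], maxHits)
  }
}

#' Validate a candidate face crop by its eye and nose sub-regions
#'
#' The combination-detector acceptance rule: on a 100 x 100 candidate crop,
#' the eye detector is run on the upper-left quadrant (subject's right eye)
#' and the upper-right quadrant (left eye), and the nose detector on the
#' central column. The crop is "Good" only if all three sub-searches return
#' at least one hit; landmark coordinates are the centres of the
#' top-scoring hits.
#'
#' @param crop numeric 100 x 100 grayscale matrix.
#' @param eyeBackend,noseBackend detector backends (see [templateBackend()]).
#' @param noseRegion half-open 0-based search region \code{c(x0, x1, y0,
#'   y1)} for the nose; the default covers the central column.
#' @return list with \code{status} ("Good"/"Bad") and \code{landmarks}
#'   (list of rightEye, leftEye, nose, each \code{c(x, y)}) or NULL when Bad.
#' @export
validateFace <- function(crop, eyeBackend = defaultEyeBackend(),
                         noseBackend = defaultNoseBackend(),
                         noseRegion = c(30, 70, 30, 100)) {
  if (!is.matrix(crop) || any(dim(crop) != c(100, 100)))
    stop("invalid input: crop must be exactly 100 x 100")
  bad <- list(status = "Bad", landmarks = NULL)
  rightHits <- eyeBackend(crop, c(0, 50, 0, 50))
  if (nrow(rightHits) == 0) return(bad)
  leftHits <- eyeBackend(crop, c(50, 100, 0, 50))
  if (nrow(leftHits) == 0) return(bad)
  noseHits <- noseBackend(crop, noseRegion)
  if (nrow(noseHits) == 0) return(bad)
  centre <- function(hits) {
    top <- hits[which.max(hits$score), ]
    c(top$x + (top$w - 1) / 2, top$y + (top$h - 1) / 2)
  }
  list(status = "Good",
       landmarks = list(rightEye = centre(rightHits),
                        leftEye = centre(leftHits),
                        nose = centre(noseHits)))
}

#' Align a face crop to canonical landmark positions
#'
#' Computes a similarity transform (rotation, isotropic scale, translation)
#' taking the detected landmarks to the canonical positions — right eye
#' (30, 35), left eye (70, 35), nose (50, 65) — and resamples the crop with
#' it. Mode "eyes" fits the transform exactly to the two eye coordinates;
#' "eyes_nose" least-squares fits all three; "none" returns the crop
#' unchanged.
#'
#' @param crop numeric grayscale matrix (typically 100 x 100).
#' @param landmarks list with rightEye, leftEye and (for mode "eyes_nose")
#'   nose, each \code{c(x, y)} 0-based.
#' @param mode "none", "eyes" or "eyes_nose".
#' @return the aligned crop, same size as the input.
#' @export
alignFace <- function(crop, landmarks, mode = c("eyes", "eyes_nose", "none")) {
  mode <- match.arg(mode)
  if (mode == "none") return(crop)
  canon <- rbind(c(30, 35), c(70, 35), c(50, 65))
  src <- rbind(landmarks$rightEye, landmarks$leftEye)
  if (sqrt(sum((src[1, ] - src[2, ])^2)) < 1e-9)
    stop("degenerate landmarks: coincident eyes")
  dst <- canon[1:2, ]
  if (mode == "eyes_nose") {
    src <- rbind(src, landmarks$nose)
    dst <- canon
  }
  theta <- fitSimilarity(src, dst)
  warpSimilarity(crop, theta)
}

#' Match detections against ground-truth boxes
#'
#' Greedy one-to-one matching in order of descending IoU; pairs with IoU
#' below the threshold are never matched. Unmatched detections are false
#' positives and unmatched truth boxes are false negatives.
#'
#' @param detections,truthBoxes data.frames with columns x, y, w, h.
#' @param iouThreshold minimum IoU for a match (default 0.5).
#' @return list with counts TP, FP, FN and a data.frame \code{matching}
#'   (detection row, truth row, iou).
#' @export
matchDetections <- function(detections, truthBoxes, iouThreshold = 0.5) {
  nd <- if (is.null(detections)) 0L else nrow(detections)
  nt <- if (is.null(truthBoxes)) 0L else nrow(truthBoxes)
  matching <- data.frame(detection = integer(0), truth = integer(0),
                         iou = numeric(0))
  if (nd == 0 || nt == 0)
    return(list(TP = 0L, FP = nd, FN = nt, matching = matching))
  iou <- matrix(0, nd, nt)
  for (i in seq_len(nd))
    iou[i, ] <- boxIoU(detections[i, ], truthBoxes)
  repeat {
    best <- which.max(iou)
    if (iou[best] < iouThreshold || iou[best] == 0) break
    i <- (best - 1) %% nd + 1
    j <- (best - 1) %/% nd + 1
    matching <- rbind(matching,
                      data.frame(detection = i, truth = j, iou = iou[best]))
    iou[i, ] <- -1
    iou[, j] <- -1
    if (all(iou < iouThreshold)) break
  }
  list(TP = nrow(matching), FP = nd - nrow(matching),
       FN = nt - nrow(matching), matching = matching)
}

#' Detection performance metrics over a set of frames
#'
#' Sensitivity is the percentage of ground-truth faces detected; the
#' false-positive rate is reported both as mean false positives per frame
#' and as false positives as a percentage of the number of frames.
#'
#' @param perFrameMatches list of per-frame match results from
#'   [matchDetections()].
#' @return list with sensitivity, fpPerImage, fpPercentImages, and the
#'   totals TP, FP, FN, nFrames. When there are no ground-truth faces,
#'   sensitivity is NA and \code{noTruth} is TRUE.
#' @export
detectionMetrics <- function(perFrameMatches) {
  if (length(perFrameMatches) == 0) stop("need at least one frame")
  tp <- sum(vapply(perFrameMatches, `[[`, integer(1), "TP"))
  fp <- sum(vapply(perFrameMatches, `[[`, integer(1), "FP"))
  fn <- sum(vapply(perFrameMatches, `[[`, integer(1), "FN"))
  n <- length(perFrameMatches)
  noTruth <- (tp + fn) == 0
  if (noTruth) warning("no ground-truth faces: sensitivity undefined")
  list(sensitivity = if (noTruth) NA_real_ else 100 * tp / (tp + fn),
       fpPerImage = fp / n,
       fpPercentImages = 100 * fp / n,
       TP = tp, FP = fp, FN = fn, nFrames = n, noTruth = noTruth)
}

#' Threshold sweep of detection metrics (ROC-style curve)
#'
#' Recomputes detection metrics at each candidate-score threshold,
#' optionally discarding candidates that fail face validation first (the
#' combination-detector curve).
#'
#' @param frames list of frames, each a list with \code{image} (matrix),
#'   \code{candidates} (data.frame x, y, w, h, score) and \code{truth}
#'   (data.frame x, y, w, h).
#' @param thresholds numeric vector of score thresholds (non-empty).
#' @param validator optional function(crop) returning a [validateFace()]
#'   style list; candidates whose resized crop is "Bad" are dropped.
#' @param iouThreshold match criterion passed to [matchDetections()].
#' @return data.frame with threshold, sensitivity, fpPerImage.
#' @export
rocSweep <- function(frames, thresholds, validator = NULL,
                     iouThreshold = 0.5) {
  if (length(thresholds) == 0) stop("invalid parameter: empty threshold list")
  # validation does not depend on the threshold; do it once per candidate
  frames <- lapply(frames, function(fr) {
    cand <- fr$candidates
    if (!is.null(validator) && nrow(cand) > 0) {
      ok <- vapply(seq_len(nrow(cand)), function(i) {
        crop <- cropBox(fr$image, cand[i, ])
        if (is.null(crop)) return(FALSE)
        validator(resizeToCanonical(crop, 100))$status == "Good"
      }, logical(1))
      cand <- cand[ok, , drop = FALSE]
    }
    list(candidates = cand, truth = fr$truth)
  })
  res <- lapply(thresholds, function(th) {
    matches <- lapply(frames, function(fr) {
      keep <- fr$candidates[fr$candidates$score >= th, , drop = FALSE]
      matchDetections(keep, fr$truth, iouThreshold)
    })
    m <- detectionMetrics(matches)
    data.frame(threshold = th, sensitivity = m$sensitivity,
               fpPerImage = m$fpPerImage)
  })
  do.call(rbind, res)
}

# Extract a box from an image, clipped to the frame; NULL if degenerate.
cropBox <- function(image, box) {
  x0 <- max(0, round(box$x)); y0 <- max(0, round(box$y))
  x1 <- min(ncol(image), round(box$x + box$w))
  y1 <- min(nrow(image), round(box$y + box$h))
  if (x1 - x0 < 3 || y1 - y0 < 3) return(NULL)
  image[(y0 + 1):y1, (x0 + 1):x1, drop = FALSE]
}

#' Harvest validated face crops from a frame stream
#'
#' Samples the stream at \code{sampleRate} frames per second, runs the face
#' backend on each sampled frame, resizes each candidate to the canonical
#' 100 x 100 and keeps only crops accepted by the validator, mirroring the
#' video-processing stage that builds recognition training sets.
#'
#' @param frames list of frames, each a list with \code{image} and
#'   \code{time} (seconds).
#' @param faceBackend detector backend producing face candidate boxes.
#' @param eyeBackend,noseBackend backends forwarded to [validateFace()].
#' @param sampleRate frames per second to process (default 2).
#' @return list of accepted faces, each a list with \code{crop} (100 x 100
#'   matrix), \code{landmarks}, \code{frameIndex}, \code{time}, \code{box}.
#' @export
harvestFaces <- function(frames, faceBackend,
                         eyeBackend = defaultEyeBackend(),
                         noseBackend = defaultNoseBackend(),
                         sampleRate = 2) {
  if (sampleRate <= 0) stop("invalid parameter: sampleRate must be > 0")
  out <- list()
  lastSlot <- -1L
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    slot <- floor(fr$time * sampleRate)
    if (slot <= lastSlot) next
    lastSlot <- slot
    cand <- tryCatch(faceBackend(fr$image, NULL), error = function(e) {
      warning("frame ", i, " skipped: ", conditionMessage(e))
      NULL
    })
    if (is.null(cand) || nrow(cand) == 0) next
    for (j in seq_len(nrow(cand))) {
      crop <- cropBox(fr$image, cand[j, ])
      if (is.null(crop)) next
      crop <- resizeToCanonical(crop, 100)
      v <- validateFace(crop, eyeBackend, noseBackend)
      if (v$status == "Good") {
        out[[length(out) + 1L]] <- list(crop = crop, landmarks = v$landmarks,
                                        frameIndex = i, time = fr$time,
                                        box = cand[j, c("x", "y", "w", "h")])
      }
    }
  }
  out
}
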