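# Seeded synthetic data: face-like images with a controllable identity
# signal and nuisance conditions (rotation, contrast gradient, occlusion,
# expression warp), detection frames with ground-truth boxes, and sighting
# streams with known association structure. Every generator is deterministic
# under a fixed seed, so the recognition, detection and social modules are
# all testable end to end without external image sets.
#
# All faces share one schematic layout on the 100 x 100 canvas — elliptical
# face region, dark eye blobs at (30, 35) and (70, 35), a dark nose ridge at
# (50, 65) and a mouth line — and differ by a per-identity smooth
# (band-limited) random texture field over the face area. The texture is
# mid-frequency (~8 px features) so block-wise LBP histograms carry the
# identity information, loosely mimicking facial fur/skin texture; its
# amplitude is fixed in the generator defaults.

canonicalLandmarks <- function() {
  list(rightEye = c(30, 35), leftEye = c(70, 35), nose = c(50, 65))
}

# coordinate grids (0-based) for a size x size canvas
coordGrids <- function(size) {
  list(x = matrix(rep(0:(size - 1), each = size), size, size),
       y = matrix(rep(0:(size - 1), times = size), size, size))
}

# Schematic face layout without identity texture.
faceLayout <- function(size = 100L) {
  g <- coordGrids(size)
  cx <- (size - 1) / 2
  img <- matrix(30, size, size)
  inFace <- ((g$x - cx) / (0.40 * size))^2 +
    ((g$y - 0.53 * size) / (0.47 * size))^2 <= 1
  img[inFace] <- 150
  blob <- function(img, px, py, sx, sy, depth) {
    img - depth * exp(-(((g$x - px) / sx)^2 + ((g$y - py) / sy)^2) / 2)
  }
  img <- blob(img, 0.30 * size, 0.35 * size, 0.035 * size, 0.035 * size, 110)
  img <- blob(img, 0.70 * size, 0.35 * size, 0.035 * size, 0.035 * size, 110)
  img <- blob(img, 0.50 * size, 0.65 * size, 0.030 * size, 0.080 * size, 80)
  img <- blob(img, 0.50 * size, 0.82 * size, 0.090 * size, 0.018 * size, 50)
  attr(img, "inFace") <- inFace
  pmin(pmax(img, 0), 255)
}

# Smooth band-limited noise field: white noise on a coarse grid, bilinearly
# upsampled. gridN controls the spatial frequency (~size/gridN px features).
smoothNoiseField <- function(size, gridN = 13L) {
  coarse <- matrix(stats::rnorm(gridN * gridN), gridN, gridN)
  resizeToCanonical(coarse, size)
}

#' Generate identity templates for synthetic faces
#'
#' Each identity shares the common face layout and carries its own smooth
#' random texture field over the face area, so renders of the same identity
#' are closer in LBP feature space than renders of different identities.
#'
#' @param nIds number of identities (>= 1).
#' @param seed integer seed; the same seed and label always reproduce the
#'   same template pixel for pixel.
#' @param textureAmplitude intensity standard deviation of the identity
#'   texture (default 25 on the 0-255 scale).
#' @param size canvas side in pixels.
#' @return list of templates; each has \code{id}, \code{image} (size x size
#'   matrix) and \code{landmarks} (canonical eye/nose truth).
#' @export
makeIdentityTemplates <- function(nIds, seed = 1L, textureAmplitude = 25,
                                  size = 100L) {
  if (nIds < 1) stop("nIds must be >= 1")
  set.seed(seed)
  subSeeds <- sample.int(.Machine$integer.max, nIds)
  layout <- faceLayout(size)
  inFace <- attr(layout, "inFace")
  lm <- canonicalLandmarks()
  lapply(seq_len(nIds), function(i) {
    set.seed(subSeeds[i])
    tex <- smoothNoiseField(size) * textureAmplitude
    img <- layout
    img[inFace] <- img[inFace] + tex[inFace]
    list(id = sprintf("id%02d", i),
         image = pmin(pmax(img, 0), 255),
         landmarks = lm)
  })
}

#' Rendering condition for synthetic faces
#'
#' @param category one of "good", "rotation", "high_contrast", "obscured",
#'   "expression".
#' @param rotationDeg in-plane rotation in degrees (rotation category).
#' @param contrastStrength peak intensity change of the left-to-right
#'   illumination gradient (high_contrast category).
#' @param occlusionRange min/max side of the occluding rectangle in pixels
#'   (obscured category).
#' @param expressionAmplitude peak vertical displacement of the lower-face
#'   warp in pixels (expression category).
#' @param noiseSd standard deviation of the per-pixel Gaussian sensor noise
#'   added to every render.
#' @return a condition list for [renderFace()].
#' @export
renderCondition <- function(category = c("good", "rotation", "high_contrast",
                                         "obscured", "expression"),
                            rotationDeg = 15, contrastStrength = 60,
                            occlusionRange = c(20, 40),
                            expressionAmplitude = 2.5, noiseSd = 4) {
  category <- match.arg(category)
  if (rotationDeg < 0 || contrastStrength < 0 || expressionAmplitude < 0 ||
      noiseSd < 0 || any(occlusionRange < 0))
    stop("condition magnitudes must be >= 0")
  list(category = category, rotationDeg = rotationDeg,
       contrastStrength = contrastStrength, occlusionRange = occlusionRange,
       expressionAmplitude = expressionAmplitude, noiseSd = noiseSd)
}

#' Render one synthetic face image under a nuisance condition
#'
#' \itemize{
#' \item good: template plus sensor noise only.
#' \item rotation: in-plane rotation about the image centre; the returned
#'   landmark truth is rotated accordingly.
#' \item high_contrast: linear left-to-right illumination gradient.
#' \item obscured: a rectangle of 20-40 px (uniform) at a uniform position
#'   is filled with a flat dark patch.
#' \item expression: smooth vertical warp of the lower face (mouth/nose
#'   region), leaving the eyes untouched.
#' }
#'
#' @param template an identity template from [makeIdentityTemplates()].
#' @param condition a condition from [renderCondition()].
#' @param seed integer seed for the render's randomness.
#' @return list with \code{image} (100 x 100 matrix), \code{landmarks}
#'   (truth, transformed when the render moves them), \code{id} and
#'   \code{category}.
#' @export
renderFace <- function(template, condition = renderCondition(), seed = 1L) {
  set.seed(seed)
  img <- template$image
  size <- nrow(img)
  lm <- template$landmarks
  cx <- (size - 1) / 2
  if (condition$category == "rotation") {
    ang <- condition$rotationDeg * pi / 180
    a <- cos(ang); b <- sin(ang)
    # forward similarity about the centre
    theta <- c(a, b, cx - a * cx + b * cx, cx - b * cx - a * cx)
    img <- warpSimilarity(img, theta)
    pts <- applySimilarity(theta, rbind(lm$rightEye, lm$leftEye, lm$nose))
    if (any(pts < 0 | pts >= size))
      stop("invalid parameter: rotation moves landmarks off canvas")
    lm <- list(rightEye = pts[1, ], leftEye = pts[2, ], nose = pts[3, ])
  } else if (condition$category == "high_contrast") {
    g <- coordGrids(size)
    img <- img + condition$contrastStrength * (g$x - cx) / cx
  } else if (condition$category == "obscured") {
    side <- round(stats::runif(1, condition$occlusionRange[1],
                               condition$occlusionRange[2]))
    x0 <- sample.int(size - side, 1) - 1L
    y0 <- sample.int(size - side, 1) - 1L
    img[(y0 + 1):(y0 + side), (x0 + 1):(x0 + side)] <- 20
  } else if (condition$category == "expression") {
    yStart <- round(0.55 * size)
    rows <- (yStart + 1):size
    g <- coordGrids(size)
    envelope <- (g$y[rows, ] - yStart) / (size - yStart)
    shift <- condition$expressionAmplitude *
      sin(2 * pi * g$x[rows, ] / (0.5 * size)) * envelope
    xs <- as.numeric(g$x[rows, ])
    ys <- as.numeric(g$y[rows, ] - shift)
    img[rows, ] <- matrix(bilinearSample(img, xs, ys), length(rows), size)
  }
  if (condition$noiseSd > 0)
    img <- img + matrix(stats::rnorm(size * size, 0, condition$noiseSd),
                        size, size)
  list(image = pmin(pmax(img, 0), 255), landmarks = lm,
       id = template$id, category = condition$category)
}

#' Generate a labelled synthetic recognition dataset
#'
#' Renders \code{nPerId} images per identity, with condition categories
#' drawn proportional to \code{conditionMix}; the tags are kept so accuracy
#' can be stratified by condition.
#'
#' @param nIds identities.
#' @param nPerId images per identity.
#' @param conditionMix named numeric vector of category weights, e.g.
#'   \code{c(good = 0.7, rotation = 0.3)}.
#' @param seed master seed; the dataset is fully reproducible under it.
#' @param noiseSd sensor noise passed to every render.
#' @param textureAmplitude identity-texture amplitude (see
#'   [makeIdentityTemplates()]).
#' @return list with \code{images} (list of matrices), \code{labels},
#'   \code{conditions} (character tags) and \code{templates}.
#' @export
makeRecognitionDataset <- function(nIds, nPerId, conditionMix = c(good = 1),
                                   seed = 1L, noiseSd = 4,
                                   textureAmplitude = 25) {
  if (nIds < 1 || nPerId < 1) stop("counts must be >= 1")
  templates <- makeIdentityTemplates(nIds, seed = seed,
                                     textureAmplitude = textureAmplitude)
  set.seed(seed + 1L)
  cats <- sample(names(conditionMix), nIds * nPerId, replace = TRUE,
                 prob = conditionMix)
  renderSeeds <- sample.int(.Machine$integer.max, nIds * nPerId)
  images <- vector("list", nIds * nPerId)
  labels <- character(nIds * nPerId)
  k <- 0L
  for (i in seq_len(nIds)) {
    for (j in seq_len(nPerId)) {
      k <- k + 1L
      cond <- renderCondition(cats[k], noiseSd = noiseSd)
      r <- renderFace(templates[[i]], cond, seed = renderSeeds[k])
      images[[k]] <- r$image
      labels[k] <- r$id
    }
  }
  list(images = images, labels = labels, conditions = cats,
       templates = templates)
}

#' Generate synthetic detection frames with ground truth
#'
#' Frames contain a textured background with clutter blobs plus 0 or more
#' planted faces (rendered identity templates resized to a random scale) at
#' non-overlapping positions; the planted boxes are the ground truth.
#'
#' @param nFrames number of frames.
#' @param facesPerFrameRange inclusive min/max planted faces per frame.
#' @param frameSize c(height, width) in pixels.
#' @param scales candidate face side lengths in pixels.
#' @param nClutter clutter blobs per frame.
#' @param seed integer seed.
#' @return list of frames, each with \code{image} and \code{truth}
#'   (data.frame x, y, w, h, id).
#' @export
makeDetectionFrames <- function(nFrames, facesPerFrameRange = c(0, 4),
                                frameSize = c(240, 320),
                                scales = c(50, 65, 80), nClutter = 6,
                                seed = 1L) {
  if (min(frameSize) <= max(scales))
    stop("frame must be larger than the largest face scale")
  templates <- makeIdentityTemplates(6, seed = seed)
  set.seed(seed + 1L)
  lapply(seq_len(nFrames), function(f) {
    h <- frameSize[1]; w <- frameSize[2]
    bg <- 60 + 25 * resizeToCanonical(matrix(stats::rnorm(15 * 15), 15, 15),
                                      max(h, w))[1:h, 1:w]
    g <- coordGrids(max(h, w))
    for (k in seq_len(nClutter)) {
      px <- stats::runif(1, 0, w - 1); py <- stats::runif(1, 0, h - 1)
      s <- stats::runif(1, 4, 12)
      bg <- bg - stats::runif(1, 20, 60) *
        exp(-(((g$x[1:h, 1:w] - px) / s)^2 + ((g$y[1:h, 1:w] - py) / s)^2) / 2)
    }
    faceCounts <- facesPerFrameRange[1]:facesPerFrameRange[2]
    nFaces <- faceCounts[sample.int(length(faceCounts), 1)]
    truth <- data.frame(x = numeric(0), y = numeric(0), w = numeric(0),
                        h = numeric(0), id = character(0))
    attempts <- 0L
    while (nrow(truth) < nFaces && attempts < 200L) {
      attempts <- attempts + 1L
      s <- scales[sample.int(length(scales), 1)]
      x0 <- sample.int(w - s, 1) - 1L
      y0 <- sample.int(h - s, 1) - 1L
      box <- data.frame(x = x0, y = y0, w = s, h = s)
      if (nrow(truth) > 0 && any(boxIoU(box, truth) > 0)) next
      tmpl <- templates[[sample.int(length(templates), 1)]]
      face <- resizeToCanonical(tmpl$image, s) +
        matrix(stats::rnorm(s * s, 0, 4), s, s)
      bg[(y0 + 1):(y0 + s), (x0 + 1):(x0 + s)] <- face
      truth <- rbind(truth, cbind(box, id = tmpl$id))
    }
    if (nrow(truth) < nFaces)
      stop("could not place ", nFaces, " non-overlapping faces")
    list(image = pmin(pmax(bg, 0), 255), truth = truth)
  })
}

# --- reference templates for the detector backends -------------------------

#' Reference templates and backends for the synthetic face geometry
#'
#' Analytic templates matching the generator's schematic eye blob, nose
#' ridge and whole-face layout, wrapped as NCC [templateBackend()]s. These
#' are the reference detectors used by the validation and harvesting tests.
#'
#' @return \code{eyeTemplate}/\code{noseTemplate}/\code{faceTemplate}: a
#'   numeric odd-sized matrix; the \code{default*Backend} functions return a
#'   detector backend.
#' @name referenceBackends
NULL

#' @rdname referenceBackends
#' @export
eyeTemplate <- function() {
  n <- 13L
  g <- coordGrids(n)
  c0 <- (n - 1) / 2
  150 - 110 * exp(-(((g$x - c0) / 3.5)^2 + ((g$y - c0) / 3.5)^2) / 2)
}

#' @rdname referenceBackends
#' @export
noseTemplate <- function() {
  h <- 21L; w <- 13L
  x <- matrix(rep(0:(w - 1), each = h), h, w)
  y <- matrix(rep(0:(h - 1), times = w), h, w)
  150 - 80 * exp(-(((x - (w - 1) / 2) / 3)^2 + ((y - (h - 1) / 2) / 8)^2) / 2)
}

#' @rdname referenceBackends
#' @export
faceTemplate <- function() {
  resizeToCanonical(faceLayout(100), 49)
}

#' @rdname referenceBackends
#' @param threshold NCC acceptance threshold for the backend.
#' @export
defaultEyeBackend <- function(threshold = 0.6) {
  templateBackend(eyeTemplate(), threshold = threshold, maxHits = 3L)
}

#' @rdname referenceBackends
#' @export
defaultNoseBackend <- function(threshold = 0.6) {
  templateBackend(noseTemplate(), threshold = threshold, maxHits = 3L)
}

#' Multi-scale NCC face-candidate backend
#'
#' Scans the frame with the schematic face template resized to each scale
#' and pools the per-scale NCC hits through non-maximum suppression. The
#' reference candidate generator for synthetic detection frames; external
#' cascade detectors can be substituted through the same interface.
#'
#' @param scales face side lengths (pixels) to scan.
#' @param threshold NCC acceptance threshold.
#' @param maxHits maximum candidates returned per frame.
#' @return a detector backend \code{function(image, region)}.
#' @export
defaultFaceBackend <- function(scales = c(50, 65, 80), threshold = 0.45,
                               maxHits = 10L) {
  base <- faceLayout(100)
  templates <- lapply(scales, function(s) {
    so <- if (s %% 2 == 0) s - 1L else s
    resizeToCanonical(base, so)
  })
  force(threshold); force(maxHits)
  function(image, region = NULL) {
    hits <- lapply(templates, function(tmpl) {
      templateBackend(tmpl, threshold = threshold,
                      maxHits = maxHits)(image, region)
    })
    boxes <- do.call(rbind, hits)
    if (nrow(boxes) == 0) return(boxes)
    boxes <- suppressOverlaps(boxes, 0.3)
    utils::head(boxes[order(-boxes$score), , drop = FALSE], maxHits)
  }
}

#' Generate a synthetic sighting stream with known association structure
#'
#' Per window, each identity is present independently with the background
#' probability; each forced pair is additionally made jointly present with
#' its own probability (the mechanism that plants preferred associations).
#' Every present identity emits at least \code{minDetections} sightings in
#' the window (count = minDetections + Poisson(\code{detectionLambda})), so
#' the windowed rebuild of the association matrix reproduces the realised
#' presence exactly. The returned truth matrix is the simple-ratio index of
#' the realised presences.
#'
#' @param nIds number of identities.
#' @param nWindows number of sampling windows.
#' @param backgroundP background per-identity presence probability.
#' @param forcedPairs data.frame with columns a, b (identity indices or
#'   labels) and p (joint presence probability), or NULL.
#' @param windowS window length in seconds.
#' @param minDetections sightings guaranteed per present identity per window.
#' @param detectionLambda Poisson mean of extra sightings.
#' @param seed integer seed.
#' @return list with \code{records} (data.frame time_s, identity,
#'   confidence, frame), \code{truth} (\linkS4class{AssociationMatrix}),
#'   \code{presence} (window x identity logical matrix) and \code{ids}.
#' @export
makeSocialStream <- function(nIds = 10, nWindows = 300, backgroundP = 0.2,
                             forcedPairs = NULL, windowS = 60,
                             minDetections = 3, detectionLambda = 2,
                             seed = 1L) {
  if (nIds < 2) stop("need at least 2 identities")
  stopifnot(backgroundP >= 0, backgroundP <= 1)
  ids <- sprintf("id%02d", seq_len(nIds))
  set.seed(seed)
  presence <- matrix(stats::runif(nWindows * nIds) < backgroundP,
                     nWindows, nIds, dimnames = list(NULL, ids))
  if (!is.null(forcedPairs)) {
    for (r in seq_len(nrow(forcedPairs))) {
      a <- forcedPairs$a[r]; b <- forcedPairs$b[r]
      if (is.numeric(a)) a <- ids[a]
      if (is.numeric(b)) b <- ids[b]
      p <- forcedPairs$p[r]
      stopifnot(p >= 0, p <= 1)
      joint <- stats::runif(nWindows) < p
      presence[joint, a] <- TRUE
      presence[joint, b] <- TRUE
    }
  }
  rows <- list()
  for (w in seq_len(nWindows)) {
    for (i in which(presence[w, ])) {
      count <- minDetections + stats::rpois(1, detectionLambda)
      times <- sort(stats::runif(count, (w - 1) * windowS,
                                 w * windowS - 1e-6))
      rows[[length(rows) + 1L]] <-
        data.frame(time_s = times, identity = ids[i], confidence = 1,
                   frame = NA_integer_)
    }
  }
  records <- if (length(rows)) do.call(rbind, rows) else
    data.frame(time_s = numeric(0), identity = character(0),
               confidence = numeric(0), frame = integer(0))
  records <- records[order(records$time_s), ]
  rownames(records) <- NULL
  truth <- associationFromPresence(presence, ids)
  list(records = records, truth = truth, presence = presence, ids = ids)
}
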