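# Combination face validation, alignment, detection matching and harvesting

test_that("validation accepts a synthetic face and rejects degraded ones", {
  tmpl <- makeIdentityTemplates(2, seed = 1)[[1]]
  r <- renderFace(tmpl, renderCondition("good"), seed = 2)
  v <- validateFace(r$image)
  expect_identical(v$status, "Good")
  expect_lt(max(abs(v$landmarks$rightEye - c(30, 35))), 3)
  expect_lt(max(abs(v$landmarks$leftEye - c(70, 35))), 3)
  expect_lt(max(abs(v$landmarks$nose - c(50, 65))), 4)

  expect_identical(validateFace(matrix(128, 100, 100))$status, "Bad")

  # erase the nose ridge: acceptance requires all three features
  noNose <- r$image
  noNose[46:86, 36:66] <- 150
  expect_identical(validateFace(noNose)$status, "Bad")

  # occlusion covering both eyes fails validation
  blocked <- r$image
  blocked[21:50, 16:86] <- 20
  expect_identical(validateFace(blocked)$status, "Bad")
  expect_error(validateFace(matrix(0, 50, 50)), "100 x 100")
})

test_that("validation is monotone in feature hits", {
  # a backend returning no hits can never turn Bad into Good
  tmpl <- makeIdentityTemplates(1, seed = 3)[[1]]
  crop <- renderFace(tmpl, renderCondition("good"), seed = 1)$image
  nothing <- function(image, region = NULL)
    data.frame(x = numeric(0), y = numeric(0), w = numeric(0),
               h = numeric(0), score = numeric(0))
  expect_identical(validateFace(crop, eyeBackend = nothing)$status, "Bad")
  expect_identical(validateFace(crop, noseBackend = nothing)$status, "Bad")
})

test_that("alignment maps eyes to canonical positions and is idempotent", {
  tmpl <- makeIdentityTemplates(1, seed = 5)[[1]]
  crop <- renderFace(tmpl, renderCondition("good", noiseSd = 0), seed = 1)$image

  # canonical landmarks: alignment is (near) identity
  lm <- list(rightEye = c(30, 35), leftEye = c(70, 35), nose = c(50, 65))
  aligned <- alignFace(crop, lm, "eyes")
  expect_lt(mean(abs(aligned - crop)), 1e-6)
  expect_identical(alignFace(crop, lm, "none"), crop)

  # a 15-degree rotated render comes back with horizontal, 40 px spaced eyes
  rot <- renderFace(tmpl, renderCondition("rotation", rotationDeg = 15),
                    seed = 2)
  fixed <- alignFace(rot$image, rot$landmarks, "eyes")
  v <- validateFace(fixed)
  expect_identical(v$status, "Good")
  expect_lt(abs(v$landmarks$rightEye[2] - v$landmarks$leftEye[2]), 2)

  # a face whose eyes sit 60 px apart gets rescaled to the canonical 40 px
  # spacing: enlarge the crop 1.5x about its centre, then align
  s <- 1.5; c0 <- 49.5
  theta <- c(s, 0, c0 - s * c0, c0 - s * c0)
  big <- primateFaces:::warpSimilarity(crop, theta)
  bigEyes <- primateFaces:::applySimilarity(theta, rbind(c(30, 35), c(70, 35)))
  expect_equal(bigEyes[2, 1] - bigEyes[1, 1], 60)
  scaled <- alignFace(big, list(rightEye = bigEyes[1, ],
                                leftEye = bigEyes[2, ]), "eyes")
  vs <- validateFace(scaled)
  expect_identical(vs$status, "Good")
  d <- sqrt(sum((vs$landmarks$leftEye - vs$landmarks$rightEye)^2))
  expect_lt(abs(d - 40), 2)

  # eyes+nose mode reproduces an exact similarity's inverse
  fixed3 <- alignFace(rot$image, rot$landmarks, "eyes_nose")
  v3 <- validateFace(fixed3)
  expect_identical(v3$status, "Good")
  expect_error(alignFace(crop, list(rightEye = c(50, 35),
                                    leftEye = c(50, 35))),
               "degenerate")
})

test_that("detection matching is greedy one-to-one and oracle-optimal", {
  truth <- data.frame(x = c(0, 50), y = c(0, 50), w = c(20, 20), h = c(20, 20))
  # identical detections: all matched
  m <- matchDetections(truth, truth)
  expect_equal(m$TP, 2L); expect_equal(m$FP, 0L); expect_equal(m$FN, 0L)
  # no detections
  m0 <- matchDetections(NULL, truth)
  expect_equal(m0$FN, 2L)
  # two detections over one truth box -> 1 TP + 1 FP
  dets <- data.frame(x = c(1, 2), y = c(1, 2), w = 20, h = 20,
                     score = c(0.9, 0.8))
  m2 <- matchDetections(dets, truth[1, ])
  expect_equal(m2$TP, 1L); expect_equal(m2$FP, 1L)

  # random small instances: greedy TP count equals exhaustive optimum
  set.seed(44)
  for (rep in 1:20) {
    nd <- sample(1:4, 1); nt <- sample(1:4, 1)
    dets <- data.frame(x = runif(nd, 0, 60), y = runif(nd, 0, 60),
                       w = 25, h = 25, score = runif(nd))
    tr <- data.frame(x = runif(nt, 0, 60), y = runif(nt, 0, 60),
                     w = 25, h = 25)
    iou <- matrix(0, nd, nt)
    for (i in seq_len(nd))
      iou[i, ] <- primateFaces:::boxIoU(dets[i, ], tr)
    expect_equal(matchDetections(dets, tr)$TP, bruteBestMatching(iou, 0.5))
  }
})

test_that("detection metrics follow their defining arithmetic", {
  mk <- function(tp, fp, fn) list(TP = tp, FP = fp, FN = fn)
  perfect <- replicate(10, mk(1L, 0L, 0L), simplify = FALSE)
  m <- detectionMetrics(perfect)
  expect_equal(m$sensitivity, 100)
  expect_equal(m$fpPerImage, 0)

  # 8 of 10 faces found, 3 FPs over 6 frames
  frames <- list(mk(2L, 1L, 0L), mk(2L, 0L, 0L), mk(1L, 1L, 1L),
                 mk(1L, 0L, 0L), mk(1L, 1L, 1L), mk(1L, 0L, 0L))
  m2 <- detectionMetrics(frames)
  expect_equal(m2$sensitivity, 80)
  expect_equal(m2$fpPerImage, 0.5)
  expect_equal(m2$fpPercentImages, 50)

  none <- list(mk(0L, 0L, 3L))
  expect_equal(detectionMetrics(none)$sensitivity, 0)
  expect_warning(detectionMetrics(list(mk(0L, 2L, 0L))), "undefined")
})

test_that("ROC sweep is monotone and the validator lowers false positives", {
  frames <- makeDetectionFrames(8, facesPerFrameRange = c(1, 3), seed = 19)
  backend <- defaultFaceBackend()
  swept <- lapply(frames, function(fr)
    list(image = fr$image, candidates = backend(fr$image, NULL),
         truth = fr$truth))
  ths <- c(0.45, 0.55, 0.65, 0.75, 2)
  plain <- rocSweep(swept, ths)
  expect_true(all(diff(plain$sensitivity) <= 1e-9))
  expect_true(all(diff(plain$fpPerImage) <= 1e-9))
  # threshold above all scores: nothing detected
  expect_equal(plain$sensitivity[5], 0)
  expect_equal(plain$fpPerImage[5], 0)

  combined <- rocSweep(swept, ths, validator = validateFace)
  expect_true(all(combined$fpPerImage <= plain$fpPerImage + 1e-9))
  # at the lowest threshold the combination detector strictly reduces FPs
  # while keeping sensitivity (the clutter blobs fail eye/nose validation)
  expect_lt(combined$fpPerImage[1], plain$fpPerImage[1])
  expect_equal(combined$sensitivity[1], plain$sensitivity[1])
  expect_error(rocSweep(swept, numeric(0)), "threshold")
})

test_that("harvesting samples the stream and emits only validated crops", {
  frames <- makeDetectionFrames(6, facesPerFrameRange = c(1, 2), seed = 23)
  # pretend a 20 fps stream: timestamps 0.05 s apart, 3 copies per frame
  stream <- list()
  t <- 0
  for (fr in frames) {
    for (k in 1:3) {
      stream[[length(stream) + 1]] <- list(image = fr$image, time = t)
      t <- t + 0.05
    }
  }
  # 0.9 s of stream at 2 fps -> at most 2 sampled frames
  harvested <- harvestFaces(stream, defaultFaceBackend(threshold = 0.6),
                            sampleRate = 2)
  expect_lte(length(unique(vapply(harvested, `[[`, numeric(1), "time"))), 2)
  for (h in harvested) {
    expect_equal(dim(h$crop), c(100L, 100L))
    expect_identical(validateFace(h$crop)$status, "Good")
  }
  # a stream with no faces yields nothing
  flat <- list(list(image = matrix(100, 240, 320), time = 0))
  expect_length(harvestFaces(flat, defaultFaceBackend()), 0)
})
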