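# Identity classification on LBP feature vectors. Three classifiers mirror
# the recognition study: nearest neighbour under the chi-square histogram
# distance, Gaussian discriminant analysis with a single shared *diagonal*
# covariance matrix and uniform priors ("LDA" here), and a linear one-vs-one
# SVM with cost 1. Each can operate on raw 1475-dim vectors or in a PCA
# space retaining >95% of training variance.

#' Fit a PCA model on training feature vectors
#'
#' Centered principal component analysis; the number of retained components
#' is the smallest k whose cumulative explained-variance fraction exceeds
#' \code{threshold}.
#'
#' @param x numeric matrix, one feature vector per row (>= 2 rows).
#' @param threshold variance fraction to exceed (default 0.95).
#' @return a \linkS4class{PCAModel}.
#' @export
fitPCA <- function(x, threshold = 0.95) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 vectors to fit PCA")
  if (all(abs(sweep(x, 2, x[1, ])) < 1e-12))
    stop("degenerate data: all feature vectors identical")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  vars <- pc$sdev^2
  frac <- vars / sum(vars)
  k <- which(cumsum(frac) > threshold)[1]
  if (is.na(k)) k <- length(frac)
  new("PCAModel",
      center = as.numeric(pc$center),
      components = pc$rotation[, seq_len(k), drop = FALSE],
      explainedFraction = frac,
      k = as.integer(k),
      threshold = threshold)
}

#' Project feature vectors into a fitted PCA space
#'
#' @param pca a \linkS4class{PCAModel}.
#' @param x numeric vector or matrix (rows = vectors) in the original space.
#' @return matrix of projected coordinates (rows = vectors, k columns).
#' @export
projectPCA <- function(pca, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(pca@center))
    stop("feature length does not match the PCA input space")
  sweep(x, 2, pca@center) %*% pca@components
}

# chi-square histogram distance between a query vector and each row of a
# matrix: sum (x - y)^2 / (x + y) over bins with x + y > 0.
chiSquareDistances <- function(train, query) {
  d <- numeric(nrow(train))
  for (i in seq_len(nrow(train))) {
    s <- train[i, ] + query
    ok <- s > 0
    diff <- train[i, ok] - query[ok]
    d[i] <- sum(diff * diff / s[ok])
  }
  d
}

euclideanDistances <- function(train, query) {
  diff <- sweep(train, 2, query)
  sqrt(rowSums(diff * diff))
}

# Extract one-vs-one linear hyperplanes (w, b) from a fitted e1071::svm
# model with a linear kernel, in libsvm's pairwise order (i < j, decision
# value positive -> class i). Training must have used scale = FALSE.
svmHyperplanes <- function(fit) {
  k <- fit$nclasses
  sv <- as.matrix(fit$SV)
  coefs <- as.matrix(fit$coefs)
  start <- c(1L, cumsum(fit$nSV) + 1L)
  pairs <- list(); wcols <- list(); b <- numeric(0)
  idx <- 0L
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      idx <- idx + 1L
      ri <- start[i]:(start[i] + fit$nSV[i] - 1L)
      rj <- start[j]:(start[j] + fit$nSV[j] - 1L)
      ci <- coefs[ri, j - 1L]
      cj <- coefs[rj, i]
      w <- drop(crossprod(sv[ri, , drop = FALSE], ci) +
                crossprod(sv[rj, , drop = FALSE], cj))
      wcols[[idx]] <- w
      b[idx] <- -fit$rho[idx]
      pairs[[idx]] <- c(i, j)
    }
  }
  list(w = do.call(cbind, wcols), b = b,
       pairs = do.call(rbind, pairs),
       classOrder = fit$levels[fit$labels])
}

#' Train an identity-recognition model
#'
#' @param features numeric matrix, one feature vector per row.
#' @param labels character (or factor) identity labels, one per row. Label
#'   order in the model follows first appearance in \code{labels}.
#' @param algorithm "NN" (chi-square nearest neighbour), "LDA" (shared
#'   diagonal-covariance Gaussian discriminant) or "SVM" (linear one-vs-one,
#'   cost \code{cost}).
#' @param usePCA reduce dimensionality with PCA fitted on these training
#'   vectors before classification.
#' @param pcaThreshold explained-variance fraction for [fitPCA()].
#' @param distance NN distance: "chisq" (default on raw histograms) or
#'   "euclidean". PCA scores are not histograms, so when \code{usePCA} is
#'   TRUE and no distance is given, NN falls back to Euclidean distance.
#' @param cost SVM cost parameter (default 1).
#' @param varianceFloor lower bound applied to LDA pooled variances so
#'   constant features cannot produce division by zero.
#' @return a \linkS4class{RecognitionModel}.
#' @export
trainRecognizer <- function(features, labels,
                            algorithm = c("LDA", "NN", "SVM"),
                            usePCA = FALSE, pcaThreshold = 0.95,
                            distance = NULL, cost = 1,
                            varianceFloor = 1e-9) {
  algorithm <- match.arg(algorithm)
  features <- as.matrix(features)
  labels <- as.character(labels)
  if (nrow(features) != length(labels))
    stop("features and labels must have matching lengths")
  classes <- unique(labels)
  if (length(classes) < 2) stop("invalid input: need at least 2 classes")
  counts <- table(labels)
  if (algorithm == "LDA" && any(counts < 2))
    stop("degenerate variance: LDA requires >= 2 samples per class")

  pca <- NULL
  x <- features
  if (usePCA) {
    pca <- fitPCA(features, pcaThreshold)
    x <- projectPCA(pca, features)
  }

  params <- switch(algorithm,
    NN = {
      if (is.null(distance)) distance <- if (usePCA) "euclidean" else "chisq"
      distance <- match.arg(distance, c("chisq", "euclidean"))
      list(train = x, trainLabels = labels, distance = distance)
    },
    LDA = {
      means <- t(vapply(classes,
                        function(cl) colMeans(x[labels == cl, , drop = FALSE]),
                        numeric(ncol(x))))
      ss <- 0
      for (cl in classes) {
        xc <- x[labels == cl, , drop = FALSE]
        ss <- ss + colSums(sweep(xc, 2, colMeans(xc))^2)
      }
      variances <- pmax(ss / (nrow(x) - length(classes)), varianceFloor)
      list(means = means, variances = variances,
           priors = rep(1 / length(classes), length(classes)))
    },
    SVM = {
      y <- factor(labels, levels = classes)
      fit <- e1071::svm(x, y, kernel = "linear", cost = cost,
                        scale = FALSE)
      hp <- svmHyperplanes(fit)
      c(hp, list(cost = cost))
    })

  new("RecognitionModel",
      labels = classes,
      algorithm = algorithm,
      pca = pca,
      params = params,
      inputDim = ncol(features))
}

# log of the shared-diagonal-covariance Gaussian discriminant for each class
# (uniform priors drop out of the argmax but are kept for completeness).
ldaDiscriminants <- function(params, x) {
  v <- params$variances
  disc <- vapply(seq_len(nrow(params$means)), function(cl) {
    diff <- sweep(x, 2, params$means[cl, ])
    -0.5 * rowSums(sweep(diff * diff, 2, v, "/")) + log(params$priors[cl])
  }, numeric(nrow(x)))
  # vapply returns n x classes (or a vector when n == 1); normalise to
  # classes x n
  if (is.null(dim(disc))) disc <- matrix(disc, nrow = 1)
  t(disc)
}

svmVotePredict <- function(params, x, labels) {
  dec <- x %*% params$w + matrix(params$b, nrow(x), length(params$b),
                                 byrow = TRUE)
  classIdx <- match(params$classOrder, labels)
  k <- length(labels)
  out <- character(nrow(x)); score <- numeric(nrow(x))
  for (r in seq_len(nrow(x))) {
    votes <- numeric(k); margin <- numeric(k)
    for (p in seq_len(nrow(params$pairs))) {
      i <- classIdx[params$pairs[p, 1]]; j <- classIdx[params$pairs[p, 2]]
      d <- dec[r, p]
      if (d > 0) votes[i] <- votes[i] + 1 else votes[j] <- votes[j] + 1
      margin[i] <- margin[i] + d
      margin[j] <- margin[j] - d
    }
    # majority vote; ties broken by summed decision values, then label order
    best <- which(votes == max(votes))
    if (length(best) > 1) best <- best[order(-margin[best])][1]
    out[r] <- labels[best]
    score[r] <- votes[best]
  }
  list(labels = out, score = score)
}

#' Predict identities for feature vectors
#'
#' @param model a \linkS4class{RecognitionModel}.
#' @param features numeric vector (one face) or matrix (one row per face) in
#'   the raw feature space the model was trained on.
#' @return data.frame with one row per input: \code{label} (predicted
#'   identity) and \code{score} (NN: distance to the nearest training
#'   vector, smaller is closer; LDA: log-discriminant margin over the
#'   runner-up; SVM: winning vote count).
#' @export
predictIdentity <- function(model, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  features <- as.matrix(features)
  if (ncol(features) != model@inputDim)
    stop("invalid input: feature length ", ncol(features),
         " does not match model input dimension ", model@inputDim)
  x <- if (!is.null(model@pca)) projectPCA(model@pca, features) else features
  p <- model@params
  switch(model@algorithm,
    NN = {
      distFun <- if (p$distance == "chisq") chiSquareDistances
                 else euclideanDistances
      res <- t(apply(x, 1, function(q) {
        d <- distFun(p$train, q)
        i <- which.min(d)
        c(i, d[i])
      }))
      data.frame(label = p$trainLabels[res[, 1]], score = res[, 2],
                 stringsAsFactors = FALSE)
    },
    LDA = {
      disc <- ldaDiscriminants(p, x)   # classes x n
      idx <- apply(disc, 2, which.max)
      margin <- apply(disc, 2, function(col) {
        s <- sort(col, decreasing = TRUE)
        if (length(s) > 1) s[1] - s[2] else Inf
      })
      data.frame(label = model@labels[idx], score = margin,
                 stringsAsFactors = FALSE)
    },
    SVM = {
      res <- svmVotePredict(p, x, model@labels)
      data.frame(label = res$labels, score = res$score,
                 stringsAsFactors = FALSE)
    })
}

#' Build an evaluation report from predicted and true labels
#'
#' @param predicted character vector of predicted identities.
#' @param truth character vector of true identities (same length).
#' @param labels label universe for the confusion matrix; defaults to the
#'   union of predicted and true labels.
#' @return an \linkS4class{EvaluationReport}.
#' @export
evaluationReport <- function(predicted, truth, labels = NULL) {
  if (length(predicted) != length(truth))
    stop("predicted and truth must have the same length")
  if (length(truth) == 0) stop("empty test set")
  if (is.null(labels)) labels <- unique(c(truth, predicted))
  confusion <- table(factor(truth, levels = labels),
                     factor(predicted, levels = labels))
  confusion <- matrix(as.integer(confusion), length(labels),
                      dimnames = list(actual = labels, predicted = labels))
  rowTot <- rowSums(confusion)
  perClass <- ifelse(rowTot > 0, 100 * diag(confusion) / rowTot, NA_real_)
  new("EvaluationReport",
      accuracy = 100 * sum(diag(confusion)) / sum(confusion),
      confusion = confusion,
      perClassPercent = perClass)
}

#' Rank-1 classification accuracy of a model on a test set
#'
#' @param model a \linkS4class{RecognitionModel}.
#' @param testFeatures numeric matrix of raw feature vectors.
#' @param testLabels true identities.
#' @return an \linkS4class{EvaluationReport} over the model's label set.
#' @export
classificationAccuracy <- function(model, testFeatures, testLabels) {
  if (length(testLabels) == 0) stop("empty test set")
  pred <- predictIdentity(model, testFeatures)
  evaluationReport(pred$label, as.character(testLabels),
                   labels = unique(c(model@labels, testLabels)))
}

#' Stratified k-fold cross-validated accuracy
#'
#' Folds are stratified by class so per-class fold sizes differ by at most
#' one. When PCA is requested it is refitted on each training fold and test
#' vectors are projected with that fold's basis, so no information leaks
#' from the held-out fold.
#'
#' @inheritParams trainRecognizer
#' @param k number of folds (default 10).
#' @param seed integer seed controlling fold assignment.
#' @return list with \code{mean}, \code{sd}, \code{foldAccuracy} and the
#'   fold assignment vector \code{fold}.
#' @export
kfoldCrossValidate <- function(features, labels, k = 10,
                               algorithm = c("LDA", "NN", "SVM"),
                               usePCA = FALSE, pcaThreshold = 0.95,
                               seed = 1L, ...) {
  algorithm <- match.arg(algorithm)
  if (k < 2) stop("invalid parameter: k must be >= 2")
  labels <- as.character(labels)
  features <- as.matrix(features)
  counts <- table(labels)
  if (any(counts < k))
    warning("some classes have fewer than k samples; ",
            "folds are stratified best-effort")
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in names(counts)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  acc <- vapply(seq_len(k), function(f) {
    test <- fold == f
    if (!any(test)) return(NA_real_)
    m <- trainRecognizer(features[!test, , drop = FALSE], labels[!test],
                         algorithm = algorithm, usePCA = usePCA,
                         pcaThreshold = pcaThreshold, ...)
    classificationAccuracy(m, features[test, , drop = FALSE],
                           labels[test])@accuracy
  }, numeric(1))
  list(mean = mean(acc, na.rm = TRUE), sd = stats::sd(acc, na.rm = TRUE),
       foldAccuracy = acc, fold = fold)
}

#' Accuracy as a function of group size and training images per identity
#'
#' For every combination of M (identities), N (training images per identity)
#' and algorithm, repeatedly samples M identities, N disjoint training and
#' \code{testPerId} test images per identity, trains and evaluates, and
#' reports the mean and standard deviation of rank-1 accuracy over repeats.
#'
#' @param features numeric matrix of feature vectors (one per image).
#' @param labels identity labels, one per row of \code{features}.
#' @param MValues integer vector of group sizes to test.
#' @param NValues integer vector of training-set sizes per identity (>= 2).
#' @param algorithms character vector from {"NN", "LDA", "SVM"}.
#' @param usePCA logical, apply PCA per trained model.
#' @param repeats random resamplings per cell (default 10).
#' @param testPerId held-out test images per identity (default 10).
#' @param seed master seed; the full table is reproducible under it.
#' @return data.frame with columns M, N, algorithm, meanAccuracy, sdAccuracy.
#' @export
runAccuracyExperiment <- function(features, labels, MValues, NValues,
                                  algorithms = c("NN", "LDA", "SVM"),
                                  usePCA = TRUE, repeats = 10,
                                  testPerId = 10, seed = 1L) {
  labels <- as.character(labels)
  features <- as.matrix(features)
  if (any(NValues < 2)) stop("invalid parameter: N must be >= 2")
  counts <- table(labels)
  need <- max(NValues) + testPerId
  if (max(MValues) > length(counts))
    stop("invalid parameter: requested M = ", max(MValues),
         " identities but dataset has ", length(counts))
  if (min(counts) < need)
    stop("invalid parameter: need ", need, " images per identity but ",
         "the rarest identity has ", min(counts))
  ids <- names(counts)
  grid <- expand.grid(M = MValues, N = NValues, algorithm = algorithms,
                      stringsAsFactors = FALSE)
  set.seed(seed)
  cellSeeds <- matrix(sample.int(.Machine$integer.max, nrow(grid) * repeats),
                      nrow(grid), repeats)
  res <- lapply(seq_len(nrow(grid)), function(g) {
    M <- grid$M[g]; N <- grid$N[g]; alg <- grid$algorithm[g]
    acc <- vapply(seq_len(repeats), function(r) {
      set.seed(cellSeeds[g, r])
      chosen <- sample(ids, M)
      trainIdx <- integer(0); testIdx <- integer(0)
      for (id in chosen) {
        pool <- sample(which(labels == id))
        trainIdx <- c(trainIdx, pool[seq_len(N)])
        testIdx <- c(testIdx, pool[N + seq_len(testPerId)])
      }
      m <- trainRecognizer(features[trainIdx, , drop = FALSE],
                           labels[trainIdx], algorithm = alg,
                           usePCA = usePCA)
      classificationAccuracy(m, features[testIdx, , drop = FALSE],
                             labels[testIdx])@accuracy
    }, numeric(1))
    data.frame(M = M, N = N, algorithm = alg,
               meanAccuracy = mean(acc), sdAccuracy = stats::sd(acc))
  })
  do.call(rbind, res)
}
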