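# PCA + NN/LDA/SVM classifiers and evaluation metrics

makeGaussianClasses <- function(nClasses, nPer, d = 8, sep = 3, seed = 1) {
  set.seed(seed)
  centres <- matrix(rnorm(nClasses * d, sd = sep), nClasses, d)
  x <- do.call(rbind, lapply(seq_len(nClasses), function(k)
    sweep(matrix(rnorm(nPer * d), nPer, d), 2, centres[k, ], "+")))
  list(x = x, y = rep(paste0("c", seq_len(nClasses)), each = nPer),
       centres = centres)
}

test_that("PCA retains the smallest component count above the threshold", {
  # rank-1 data: a single component carries all variance
  set.seed(4)
  line <- outer(rnorm(20), runif(5))
  p <- fitPCA(line, 0.95)
  expect_equal(p@k, 1L)

  # random rank-3 data: k <= 3, and fractions match an eigendecomposition
  basis <- qr.Q(qr(matrix(rnorm(24), 8, 3)))
  x <- matrix(rnorm(60), 20, 3) %*% diag(c(4, 2, 1)) %*% t(basis)
  p3 <- fitPCA(x, 0.95)
  expect_lte(p3@k, 3L)
  ev <- eigen(cov(x), symmetric = TRUE)$values
  expect_equal(p3@explainedFraction[1:3], (ev / sum(ev))[1:3],
               tolerance = 1e-8)

  # reconstructing the training mean from a zero score is exact
  centre <- matrix(p3@center, 1)
  expect_equal(as.numeric(projectPCA(p3, centre)), rep(0, p3@k),
               tolerance = 1e-10)
  expect_error(fitPCA(matrix(1, 5, 4)), "degenerate")
})

test_that("all algorithms perfectly classify separable training data", {
  v1 <- c(rep(1, 5), rep(0, 5)); v2 <- c(rep(0, 5), rep(1, 5))
  x <- rbind(v1, v1, v1, v1, v1, v2, v2, v2, v2, v2) +
    matrix(rnorm(100, sd = 1e-3), 10, 10)
  y <- rep(c("alpha", "beta"), each = 5)
  for (alg in c("NN", "LDA", "SVM")) {
    m <- trainRecognizer(x, y, alg)
    expect_identical(modelLabels(m), c("alpha", "beta"))
    expect_identical(predictIdentity(m, x)$label, y)
  }
})

test_that("training validates inputs", {
  x <- matrix(rnorm(40), 10, 4)
  expect_error(trainRecognizer(x, rep("one", 10), "NN"), "2 classes")
  expect_error(trainRecognizer(x, c("a", rep("b", 9)), "LDA"),
               "degenerate variance")
})

test_that("LDA stores arithmetic class means and matches brute-force argmax", {
  x <- rbind(c(1, 2), c(3, 4), c(5, 6),
             c(10, 20), c(12, 22), c(14, 24))
  y <- rep(c("a", "b"), each = 3)
  m <- trainRecognizer(x, y, "LDA")
  expect_equal(unname(m@params$means), rbind(c(3, 4), c(12, 22)))

  gc <- makeGaussianClasses(4, 12, d = 6, seed = 8)
  m2 <- trainRecognizer(gc$x, gc$y, "LDA")
  set.seed(9)
  queries <- gc$x + matrix(rnorm(length(gc$x)), nrow(gc$x))
  pred <- predictIdentity(m2, queries)$label
  oracle <- vapply(seq_len(nrow(queries)), function(i)
    bruteLDAPredict(m2@params$means, m2@params$variances, queries[i, ],
                    modelLabels(m2)), character(1))
  expect_identical(pred, oracle)
})

test_that("LDA decisions are equivariant to consistent feature scaling", {
  gc <- makeGaussianClasses(3, 10, seed = 12)
  m <- trainRecognizer(gc$x, gc$y, "LDA")
  m2 <- trainRecognizer(gc$x * 5, gc$y, "LDA")
  set.seed(13)
  q <- matrix(rnorm(20 * ncol(gc$x), sd = 4), 20)
  expect_identical(predictIdentity(m, q)$label,
                   predictIdentity(m2, q * 5)$label)
})

test_that("chi-square NN matches an exhaustive pairwise-distance oracle", {
  set.seed(5)
  train <- matrix(runif(18 * 12), 18, 12)
  y <- rep(paste0("m", 1:6), each = 3)
  m <- trainRecognizer(train, y, "NN")
  expect_identical(m@params$distance, "chisq")
  queries <- matrix(runif(10 * 12), 10, 12)
  pred <- predictIdentity(m, queries)
  for (i in 1:10) {
    d <- vapply(seq_len(nrow(train)), function(j)
      bruteChiSquare(train[j, ], queries[i, ]), numeric(1))
    expect_identical(pred$label[i], y[which.min(d)])
    expect_equal(pred$score[i], min(d))
  }
  # a training vector is its own nearest neighbour
  expect_identical(predictIdentity(m, train[7, ])$label, y[7])
})

test_that("two-class LDA decision follows the midpoint discriminant", {
  d <- 4
  x <- rbind(matrix(rnorm(40 * d, 0, 1), ncol = d),
             matrix(rnorm(40 * d, 10, 1), ncol = d))
  y <- rep(c("lo", "hi"), each = 40)
  m <- trainRecognizer(x, y, "LDA")
  # queries just either side of the midpoint hyperplane
  expect_identical(predictIdentity(m, rep(4.0, d))$label, "lo")
  expect_identical(predictIdentity(m, rep(6.0, d))$label, "hi")
})

test_that("SVM vote prediction agrees with the fitting library's own", {
  gc <- makeGaussianClasses(4, 15, d = 10, sep = 1.5, seed = 21)
  m <- trainRecognizer(gc$x, gc$y, "SVM")
  fit <- e1071::svm(gc$x, factor(gc$y, levels = unique(gc$y)),
                    kernel = "linear", cost = 1, scale = FALSE)
  expect_identical(predictIdentity(m, gc$x)$label,
                   as.character(predict(fit, gc$x)))
})

test_that("prediction rejects mismatched feature lengths", {
  gc <- makeGaussianClasses(2, 5)
  m <- trainRecognizer(gc$x, gc$y, "NN")
  expect_error(predictIdentity(m, rnorm(3)), "dimension")
})

test_that("evaluation reports tally confusion matrices correctly", {
  truth <- c("a", "a", "b", "b", "c", "c")
  pred <- c("a", "b", "b", "b", "c", "a")
  r <- evaluationReport(pred, truth)
  expect_equal(reportAccuracy(r), 100 * 4 / 6)
  conf <- reportConfusion(r)
  expect_equal(conf["a", "b"], 1L)
  expect_equal(conf["c", "a"], 1L)
  expect_equal(sum(conf), 6L)
  expect_equal(unname(rowSums(conf)), c(2L, 2L, 2L))
  expect_equal(unname(r@perClassPercent), c(50, 100, 50))

  perfect <- evaluationReport(truth, truth)
  expect_equal(reportAccuracy(perfect), 100)
  expect_true(all(reportConfusion(perfect)[upper.tri(diag(3))] == 0))
})

test_that("uniformly random predictions sit at chance level", {
  labels <- paste0("id", 1:10)
  set.seed(31)
  truth <- sample(labels, 1000, replace = TRUE)
  accs <- vapply(1:10, function(s) {
    set.seed(s)
    evaluationReport(sample(labels, 1000, replace = TRUE), truth,
                     labels)@accuracy
  }, numeric(1))
  expect_equal(mean(accs), 10, tolerance = 0.2) # 10% +- 2 points
})

test_that("cross-validation is stratified, deterministic and near-balanced", {
  gc <- makeGaussianClasses(4, 20, seed = 17)
  cv1 <- kfoldCrossValidate(gc$x, gc$y, k = 5, algorithm = "LDA", seed = 3)
  cv2 <- kfoldCrossValidate(gc$x, gc$y, k = 5, algorithm = "LDA", seed = 3)
  expect_identical(cv1$fold, cv2$fold)
  expect_identical(cv1$foldAccuracy, cv2$foldAccuracy)
  # per-class fold sizes differ by at most one
  for (cl in unique(gc$y)) {
    sizes <- table(cv1$fold[gc$y == cl])
    expect_lte(max(sizes) - min(sizes), 1)
  }
  # clearly separable classes cross-validate perfectly
  far <- makeGaussianClasses(3, 10, sep = 50, seed = 18)
  expect_equal(kfoldCrossValidate(far$x, far$y, k = 5,
                                  algorithm = "NN")$mean, 100)
  expect_error(kfoldCrossValidate(gc$x, gc$y, k = 1), "k must be")
  expect_warning(kfoldCrossValidate(gc$x, gc$y, k = 30, algorithm = "LDA"),
                 "fewer than k")
})

test_that("accuracy experiment harness is reproducible and validates sizes", {
  gc <- makeGaussianClasses(6, 25, d = 6, sep = 2, seed = 23)
  t1 <- runAccuracyExperiment(gc$x, gc$y, MValues = c(2, 4), NValues = c(3, 6),
                              algorithms = "LDA", usePCA = FALSE,
                              repeats = 3, testPerId = 5, seed = 11)
  t2 <- runAccuracyExperiment(gc$x, gc$y, MValues = c(2, 4), NValues = c(3, 6),
                              algorithms = "LDA", usePCA = FALSE,
                              repeats = 3, testPerId = 5, seed = 11)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 4)
  expect_error(runAccuracyExperiment(gc$x, gc$y, 2, NValues = 1,
                                     algorithms = "LDA"), "N must be >= 2")
  expect_error(runAccuracyExperiment(gc$x, gc$y, 2, NValues = 30,
                                     algorithms = "LDA", testPerId = 10),
               "images per identity")
})
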