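#' @import methods
NULL

#' Principal component model for LBP feature vectors
#'
#' Centered PCA basis fitted on a training feature matrix. The number of
#' retained components \code{k} is the smallest count whose cumulative
#' explained-variance fraction exceeds the fitting threshold (0.95 by
#' default), so the retained basis always explains more variance than the
#' threshold.
#'
#' @slot center numeric mean vector of the training features.
#' @slot components matrix (features x k) of orthonormal loadings.
#' @slot explainedFraction numeric per-component variance fractions for all
#'   fitted components (sums to 1).
#' @slot k integer count of retained components.
#' @slot threshold numeric variance fraction used to choose \code{k}.
#'
#' @seealso [fitPCA()], [projectPCA()]
#' @export
setClass("PCAModel",
  representation(
    center = "numeric",
    components = "matrix",
    explainedFraction = "numeric",
    k = "integer",
    threshold = "numeric"
  )
)

setValidity("PCAModel", function(object) {
  msg <- NULL
  if (object@k < 1L) msg <- c(msg, "k must be >= 1")
  if (ncol(object@components) != object@k)
    msg <- c(msg, "components must have k columns")
  if (nrow(object@components) != length(object@center))
    msg <- c(msg, "components rows must match center length")
  g <- crossprod(object@components)
  if (max(abs(g - diag(nrow(g)))) > 1e-8)
    msg <- c(msg, "components must be orthonormal")
  if (sum(object@explainedFraction[seq_len(object@k)]) <= object@threshold &&
      object@k < length(object@explainedFraction))
    msg <- c(msg, "retained components must explain more variance than threshold")
  if (is.null(msg)) TRUE else msg
})

setClassUnion("PCAModelOrNULL", c("NULL", "PCAModel"))

#' Trained identity-recognition model
#'
#' Container for a face-identity classifier operating on block-histogram LBP
#' feature vectors, optionally in a PCA-reduced space. Three algorithms are
#' supported: \code{"NN"} (nearest neighbour under the chi-square histogram
#' distance), \code{"LDA"} (Gaussian discriminant with a single shared
#' diagonal covariance and uniform priors) and \code{"SVM"} (linear kernel,
#' one-vs-one, majority vote with decision-value tie-breaking).
#'
#' @slot labels character vector of class labels in first-appearance order.
#' @slot algorithm one of "NN", "LDA", "SVM".
#' @slot pca \linkS4class{PCAModel} or NULL when no reduction is used.
#' @slot params list of algorithm-specific fitted parameters.
#' @slot inputDim integer length of raw feature vectors the model accepts.
#'
#' @seealso [trainRecognizer()], [predictIdentity()]
#' @export
setClass("RecognitionModel",
  representation(
    labels = "character",
    algorithm = "character",
    pca = "PCAModelOrNULL",
    params = "list",
    inputDim = "integer"
  )
)

setValidity("RecognitionModel", function(object) {
  msg <- NULL
  if (length(object@labels) < 2L) msg <- c(msg, "need at least 2 classes")
  if (anyDuplicated(object@labels)) msg <- c(msg, "duplicate labels")
  if (!object@algorithm %in% c("NN", "LDA", "SVM"))
    msg <- c(msg, "algorithm must be NN, LDA or SVM")
  if (object@algorithm == "LDA" &&
      any(object@params$variances <= 0))
    msg <- c(msg, "LDA variances must be strictly positive")
  if (is.null(msg)) TRUE else msg
})

#' Classification evaluation report
#'
#' Rank-1 classification accuracy with the full confusion matrix (rows =
#' actual identity, columns = predicted identity) and per-class percent
#' correct.
#'
#' @slot accuracy numeric percent of test images whose top prediction equals
#'   the true identity.
#' @slot confusion integer matrix of counts, actual x predicted.
#' @slot perClassPercent numeric percent correct per actual class.
#'
#' @seealso [classificationAccuracy()], [evaluationReport()]
#' @export
setClass("EvaluationReport",
  representation(
    accuracy = "numeric",
    confusion = "matrix",
    perClassPercent = "numeric"
  )
)

setValidity("EvaluationReport", function(object) {
  msg <- NULL
  tot <- sum(object@confusion)
  if (tot > 0 &&
      abs(object@accuracy - 100 * sum(diag(object@confusion)) / tot) > 1e-8)
    msg <- c(msg, "accuracy must equal 100*trace/total")
  if (nrow(object@confusion) != ncol(object@confusion))
    msg <- c(msg, "confusion matrix must be square")
  if (is.null(msg)) TRUE else msg
})

#' Pairwise association matrix
#'
#' Symmetric matrix of association indices in [0, 1] between identities,
#' computed from windowed presence samples (simple-ratio or half-weight
#' index). The diagonal is NA by convention.
#'
#' @slot ids character vector of identities (row/column order).
#' @slot index numeric symmetric matrix of association indices.
#' @slot indexType "simple_ratio" or "half_weight".
#'
#' @seealso [associationMatrix()], [mantelTest()]
#' @export
setClass("AssociationMatrix",
  representation(
    ids = "character",
    index = "matrix",
    indexType = "character"
  )
)

setValidity("AssociationMatrix", function(object) {
  msg <- NULL
  n <- length(object@ids)
  if (!all(dim(object@index) == c(n, n)))
    msg <- c(msg, "index must be n x n for n identities")
  off <- object@index[row(object@index) != col(object@index)]
  if (any(off < -1e-12 | off > 1 + 1e-12, na.rm = TRUE))
    msg <- c(msg, "association indices must lie in [0, 1]")
  if (max(abs(object@index - t(object@index)), na.rm = TRUE) > 1e-12)
    msg <- c(msg, "index must be symmetric")
  if (is.null(msg)) TRUE else msg
})

#' Preferred-association permutation test result
#'
#' Result of the group-membership permutation test: per-pair null
#' distributions of association indices under repeated identity swaps that
#' conserve group sizes and individual sighting totals, plus the pairs
#' flagged as preferred (observed index above the upper two-tailed quantile
#' of the null) or avoided (below the lower quantile).
#'
#' @slot observed \linkS4class{AssociationMatrix} of the unpermuted samples.
#' @slot nullDistributions numeric matrix, nPermutations x nPairs, columns
#'   named "A|B"; each column sorted ascending.
#' @slot significantPairs character vector of preferred pairs ("A|B").
#' @slot avoidedPairs character vector of avoided pairs ("A|B").
#' @slot alpha numeric two-tailed significance level.
#' @slot nPermutations integer number of permuted sample sets.
#'
#' @seealso [preferredAssociations()]
#' @export
setClass("PermutationResult",
  representation(
    observed = "AssociationMatrix",
    nullDistributions = "matrix",
    significantPairs = "character",
    avoidedPairs = "character",
    alpha = "numeric",
    nPermutations = "integer"
  )
)

setValidity("PermutationResult", function(object) {
  msg <- NULL
  if (nrow(object@nullDistributions) != object@nPermutations)
    msg <- c(msg, "null distribution length must equal nPermutations")
  pairs <- colnames(object@nullDistributions)
  if (!all(object@significantPairs %in% pairs))
    msg <- c(msg, "significant pairs must be a subset of all pairs")
  if (!all(object@avoidedPairs %in% pairs))
    msg <- c(msg, "avoided pairs must be a subset of all pairs")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "PCAModel", function(object) {
  cat("PCAModel:", object@k, "components retained (",
      sprintf("%.1f%%", 100 * sum(object@explainedFraction[seq_len(object@k)])),
      "of variance, threshold", object@threshold, ")\n")
})

setMethod("show", "RecognitionModel", function(object) {
  cat("RecognitionModel (", object@algorithm, ")\n", sep = "")
  cat("  classes: ", length(object@labels), " [",
      paste(utils::head(object@labels, 5), collapse = ", "),
      if (length(object@labels) > 5) ", ..." else "", "]\n", sep = "")
  cat("  input dimension:", object@inputDim, "\n")
  if (!is.null(object@pca))
    cat("  PCA: reduced to", object@pca@k, "components\n")
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport: accuracy %.1f%% over %d test images, %d classes\n",
              object@accuracy, sum(object@confusion), nrow(object@confusion)))
})

setMethod("show", "AssociationMatrix", function(object) {
  cat("AssociationMatrix (", object@indexType, "), ",
      length(object@ids), " identities\n", sep = "")
  n <- min(length(object@ids), 6L)
  print(round(object@index[seq_len(n), seq_len(n), drop = FALSE], 3))
  if (length(object@ids) > n) cat("  ...\n")
})

setMethod("show", "PermutationResult", function(object) {
  cat("PermutationResult:", object@nPermutations, "permutations, alpha =",
      object@alpha, "\n")
  cat("  preferred pairs:",
      if (length(object@significantPairs)) paste(object@significantPairs, collapse = ", ")
      else "none", "\n")
  cat("  avoided pairs:",
      if (length(object@avoidedPairs)) paste(object@avoidedPairs, collapse = ", ")
      else "none", "\n")
})

#' @describeIn AssociationMatrix-class identities in matrix order
#' @param object an AssociationMatrix
#' @export
assocIds <- function(object) object@ids

#' @describeIn AssociationMatrix-class the raw index matrix (diagonal NA)
#' @export
assocIndex <- function(object) {
  m <- object@index
  dimnames(m) <- list(object@ids, object@ids)
  m
}

#' @describeIn RecognitionModel-class class labels in training order
#' @param model a RecognitionModel
#' @export
modelLabels <- function(model) model@labels

#' @describeIn RecognitionModel-class the algorithm name
#' @export
modelAlgorithm <- function(model) model@algorithm

#' @describeIn EvaluationReport-class rank-1 accuracy in percent
#' @param report an EvaluationReport
#' @export
reportAccuracy <- function(report) report@accuracy

#' @describeIn EvaluationReport-class confusion matrix (actual x predicted)
#' @export
reportConfusion <- function(report) report@confusion
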