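# Persistence: recognition models as a versioned JSON container with
# embedded numeric arrays, sightings as CSV (time_s, identity, confidence,
# frame), association matrices as square CSV with an identity header, and
# feature matrices as CSV (id, label, f0001..).

MODEL_FORMAT_VERSION <- 1L

packMatrix <- function(m) list(values = as.numeric(m), nrow = nrow(m),
                               ncol = ncol(m))
unpackMatrix <- function(p) matrix(p$values, p$nrow, p$ncol)

#' Save a recognition model to JSON
#'
#' Writes a versioned JSON container holding the label set, algorithm,
#' optional PCA basis and all classifier parameters at full numeric
#' precision, so a reloaded model produces identical predictions.
#'
#' @param model a \linkS4class{RecognitionModel}.
#' @param path output file path.
#' @export
saveModel <- function(model, path) {
  pca <- if (is.null(model@pca)) NULL else list(
    center = model@pca@center,
    components = packMatrix(model@pca@components),
    explainedFraction = model@pca@explainedFraction,
    k = model@pca@k,
    threshold = model@pca@threshold)
  p <- model@params
  params <- switch(model@algorithm,
    NN = list(train = packMatrix(p$train), trainLabels = p$trainLabels,
              distance = p$distance),
    LDA = list(means = packMatrix(p$means), variances = p$variances,
               priors = p$priors),
    SVM = list(w = packMatrix(p$w), b = p$b, pairs = packMatrix(p$pairs),
               classOrder = p$classOrder, cost = p$cost))
  obj <- list(format = "primateFaces-model",
              version = MODEL_FORMAT_VERSION,
              algorithm = model@algorithm,
              labels = model@labels,
              inputDim = model@inputDim,
              pca = pca,
              params = params)
  # 17 significant digits round-trip IEEE doubles exactly
  writeLines(jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE,
                              null = "null"), path)
  invisible(path)
}

#' Load a recognition model from JSON
#'
#' @param path file written by [saveModel()].
#' @return a \linkS4class{RecognitionModel}.
#' @export
loadModel <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("cannot parse model file: ", conditionMessage(e)))
  if (is.null(obj$format) || obj$format != "primateFaces-model")
    stop("not a primateFaces model file")
  if (is.null(obj$version) || obj$version != MODEL_FORMAT_VERSION)
    stop("unsupported model version: ", obj$version %||% "missing")
  pca <- NULL
  if (!is.null(obj$pca)) {
    pca <- new("PCAModel",
               center = obj$pca$center,
               components = unpackMatrix(obj$pca$components),
               explainedFraction = obj$pca$explainedFraction,
               k = as.integer(obj$pca$k),
               threshold = obj$pca$threshold)
  }
  params <- switch(obj$algorithm,
    NN = list(train = unpackMatrix(obj$params$train),
              trainLabels = obj$params$trainLabels,
              distance = obj$params$distance),
    LDA = list(means = unpackMatrix(obj$params$means),
               variances = obj$params$variances,
               priors = obj$params$priors),
    SVM = list(w = unpackMatrix(obj$params$w), b = obj$params$b,
               pairs = unpackMatrix(obj$params$pairs),
               classOrder = obj$params$classOrder,
               cost = obj$params$cost),
    stop("unknown algorithm in model file: ", obj$algorithm))
  new("RecognitionModel", labels = obj$labels, algorithm = obj$algorithm,
      pca = pca, params = params, inputDim = as.integer(obj$inputDim))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a sightings CSV
#'
#' Expects a header with at least time_s and identity; confidence and frame
#' are optional. Rows are returned sorted by time.
#'
#' @param path CSV path.
#' @return data.frame with columns time_s, identity, confidence, frame.
#' @export
readSightings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("time_s", "identity")) {
    if (!col %in% names(df))
      stop("sightings file is missing required column '", col, "'")
  }
  if (!"confidence" %in% names(df)) df$confidence <- NA_real_
  if (!"frame" %in% names(df)) df$frame <- NA_integer_
  bad <- which(!is.finite(suppressWarnings(as.numeric(df$time_s))) |
                 is.na(df$identity) | df$identity == "")
  if (length(bad) > 0)
    stop("malformed sightings row at line ", bad[1] + 1L,
         " (1-based, counting the header)")
  df$time_s <- as.numeric(df$time_s)
  df <- df[order(df$time_s), c("time_s", "identity", "confidence", "frame")]
  rownames(df) <- NULL
  df
}

#' Write a sightings CSV
#'
#' @param records data.frame with time_s and identity (confidence and frame
#'   filled with NA when absent).
#' @param path output path.
#' @export
writeSightings <- function(records, path) {
  if (!"confidence" %in% names(records)) records$confidence <- NA_real_
  if (!"frame" %in% names(records)) records$frame <- NA_integer_
  utils::write.csv(records[, c("time_s", "identity", "confidence", "frame")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Write/read an association matrix as square CSV
#'
#' @param m an \linkS4class{AssociationMatrix}.
#' @param path CSV path (identities as header and row names).
#' @export
writeAssociationCSV <- function(m, path) {
  utils::write.csv(assocIndex(m), path, row.names = TRUE)
  invisible(path)
}

#' @rdname writeAssociationCSV
#' @param indexType index label for the reloaded object.
#' @export
readAssociationCSV <- function(path, indexType = "simple_ratio") {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  diag(m) <- NA_real_
  new("AssociationMatrix", ids = rownames(m), index = unname(m),
      indexType = indexType)
}

# features CSV: id, label, f0001..fNNNN
writeFeaturesCSV <- function(features, labels, path, ids = NULL) {
  features <- as.matrix(features)
  if (is.null(ids)) ids <- sprintf("img%05d", seq_len(nrow(features)))
  colnames(features) <- sprintf("f%04d", seq_len(ncol(features)))
  utils::write.csv(data.frame(id = ids, label = labels, features,
                              check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}

readFeaturesCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  featCols <- grep("^f[0-9]+$", names(df))
  list(features = as.matrix(df[, featCols]),
       labels = as.character(df$label),
       ids = as.character(df$id))
}
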