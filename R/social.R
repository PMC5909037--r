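# Social-proximity analysis downstream of face identification. Timestamped
# identity sightings are aggregated into fixed consecutive 1-minute windows
# (an identity counts as present in a window when it was detected at least
# `minDetections` times there); windows become presence samples, samples
# become pairwise association indices, and two permutation procedures assess
# them: the Mantel test for correlation between association matrices, and a
# group-membership swap test for preferred/avoided associations that
# conserves each window's group size and each individual's total number of
# occurrences.

#' Aggregate sightings into windowed presence samples
#'
#' Fixed, consecutive, non-overlapping windows of \code{windowS} seconds;
#' an identity is present in a window when it has at least
#' \code{minDetections} sightings inside it.
#'
#' @param records data.frame with columns time_s and identity (sightings in
#'   any order).
#' @param windowS window length in seconds (> 0).
#' @param minDetections sightings required for presence (default 3).
#' @return named list of character vectors (identities present per window);
#'   names are 0-based window indices. Windows with no present identity are
#'   dropped.
#' @export
windowsFromSightings <- function(records, windowS = 60, minDetections = 3) {
  if (windowS <= 0) stop("invalid parameter: windowS must be > 0")
  if (nrow(records) == 0) return(list())
  win <- floor(records$time_s / windowS)
  tab <- table(win, records$identity)
  samples <- apply(tab, 1, function(cnt) {
    colnames(tab)[cnt >= minDetections]
  }, simplify = FALSE)
  samples[lengths(samples) > 0]
}

# simple-ratio / half-weight index from a window x identity presence matrix
associationFromPresence <- function(presence, ids,
                                    indexType = c("simple_ratio",
                                                  "half_weight")) {
  indexType <- match.arg(indexType)
  mode(presence) <- "integer"
  X <- crossprod(presence)            # joint presence counts
  n <- diag(X)                        # per-identity presence counts
  either <- outer(n, n, "+") - X      # windows with A or B or both
  denom <- if (indexType == "simple_ratio") either
           else X + (either - X) / 2
  index <- ifelse(denom > 0, X / denom, 0)
  diag(index) <- NA_real_
  dimnames(index) <- NULL
  new("AssociationMatrix", ids = ids, index = index, indexType = indexType)
}

samplesToPresence <- function(samples, ids) {
  presence <- matrix(FALSE, length(samples), length(ids),
                     dimnames = list(names(samples), ids))
  for (i in seq_along(samples)) {
    present <- samples[[i]]
    if (anyDuplicated(present))
      stop("duplicate identity within a sample")
    presence[i, present] <- TRUE
  }
  presence
}

presenceToSamples <- function(presence) {
  ids <- colnames(presence)
  out <- apply(presence, 1, function(row) ids[row], simplify = FALSE)
  names(out) <- rownames(presence)
  out
}

#' Association matrix from presence samples
#'
#' Simple-ratio index for pair (A, B): the number of samples containing
#' both, divided by the number containing A or B or both. The half-weight
#' index divides instead by (both) + (just one)/2. Pairs never observed
#' together (or at all) get index 0.
#'
#' @param samples list of character vectors from [windowsFromSightings()].
#' @param ids identity universe and matrix order; defaults to the sorted
#'   identities seen in \code{samples}. Identities never observed produce a
#'   zero row with a warning.
#' @param indexType "simple_ratio" (default) or "half_weight".
#' @return an \linkS4class{AssociationMatrix}.
#' @export
associationMatrix <- function(samples, ids = NULL,
                              indexType = c("simple_ratio", "half_weight")) {
  if (length(samples) < 1) stop("need at least one sample")
  seen <- sort(unique(unlist(samples)))
  if (is.null(ids)) ids <- seen
  if (length(ids) < 2) stop("need at least 2 identities")
  missing <- setdiff(ids, seen)
  if (length(missing) > 0)
    warning("identities never observed: ", paste(missing, collapse = ", "))
  if (!all(seen %in% ids))
    stop("samples contain identities outside `ids`")
  associationFromPresence(samplesToPresence(samples, ids), ids, indexType)
}

# Pearson correlation of the off-diagonal upper triangles of two matrices.
matrixCorrelation <- function(m1, m2) {
  ut <- upper.tri(m1)
  a <- m1[ut]; b <- m2[ut]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Mantel test between two association matrices
#'
#' The statistic r is the Pearson correlation of corresponding off-diagonal
#' upper-triangle entries. Significance is assessed by permuting the
#' identities (rows and columns jointly) of the second matrix; the p-value
#' is two-tailed: the fraction of permutations (plus the observed one) with
#' |r| at least as large as observed.
#'
#' @param m1,m2 \linkS4class{AssociationMatrix} objects, or plain symmetric
#'   matrices, over the same identities in the same order.
#' @param nPermutations Monte-Carlo permutations (default 10000).
#' @param seed integer seed.
#' @param exact enumerate all n! identity permutations instead of sampling
#'   (feasible for <= 7 identities); the p-value is then the exact fraction
#'   of permutations with |r| >= |observed r|.
#' @return list with r, p, nPermutations, exact.
#' @export
mantelTest <- function(m1, m2, nPermutations = 10000, seed = 1L,
                       exact = FALSE) {
  if (is(m1, "AssociationMatrix") && is(m2, "AssociationMatrix") &&
      !identical(m1@ids, m2@ids))
    stop("matrices must share the same identity ordering")
  a <- if (is(m1, "AssociationMatrix")) m1@index else m1
  b <- if (is(m2, "AssociationMatrix")) m2@index else m2
  if (!all(dim(a) == dim(b))) stop("matrices must have the same dimensions")
  n <- nrow(a)
  r <- matrixCorrelation(a, b)
  if (is.na(r)) {
    warning("constant matrix: correlation undefined")
    return(list(r = NA_real_, p = NA_real_, nPermutations = 0L,
                exact = exact))
  }
  permR <- function(perm) matrixCorrelation(a, b[perm, perm])
  if (exact) {
    perms <- allPermutations(n)
    rs <- vapply(perms, permR, numeric(1))
    p <- mean(abs(rs) >= abs(r) - 1e-12)
    return(list(r = r, p = p, nPermutations = length(perms), exact = TRUE))
  }
  set.seed(seed)
  hits <- 0L
  for (k in seq_len(nPermutations)) {
    if (abs(permR(sample.int(n))) >= abs(r) - 1e-12) hits <- hits + 1L
  }
  list(r = r, p = (hits + 1) / (nPermutations + 1),
       nPermutations = as.integer(nPermutations), exact = FALSE)
}

allPermutations <- function(n) {
  if (n > 8) stop("exact enumeration limited to n <= 8")
  if (n == 1) return(list(1L))
  sub <- allPermutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# One legal swap on a presence matrix: move individual a from sample s1 to
# s2 and b from s2 to s1, where a is present only in s1 and b only in s2
# (among the two). Conserves row sums (group sizes) and column sums
# (individual totals). Returns NULL when the sampled pair admits no swap.
trySwap <- function(presence) {
  s <- sample.int(nrow(presence), 2)
  r1 <- presence[s[1], ]; r2 <- presence[s[2], ]
  aCand <- which(r1 & !r2)
  bCand <- which(r2 & !r1)
  if (length(aCand) == 0 || length(bCand) == 0) return(NULL)
  a <- aCand[sample.int(length(aCand), 1)]
  b <- bCand[sample.int(length(bCand), 1)]
  presence[s[1], a] <- FALSE; presence[s[2], a] <- TRUE
  presence[s[2], b] <- FALSE; presence[s[1], b] <- TRUE
  presence
}

# Apply nSwaps successful swap moves (bounded retries when a sampled pair
# has no legal swap).
runSwaps <- function(presence, nSwaps, maxAttemptsPerSwap = 50L) {
  done <- 0L; attempts <- 0L
  while (done < nSwaps) {
    attempts <- attempts + 1L
    if (attempts > nSwaps * maxAttemptsPerSwap) {
      warning("no legal swap found; permutation chain stalled")
      break
    }
    nxt <- trySwap(presence)
    if (!is.null(nxt)) {
      presence <- nxt
      done <- done + 1L
    }
  }
  presence
}

#' Randomly permute identities between samples
#'
#' Performs a chain of random pairwise swaps of individuals between samples.
#' Every swap conserves each sample's group size and each individual's total
#' number of occurrences, and never duplicates an identity within a sample —
#' the group-membership null model for association data.
#'
#' @param samples list of character vectors (window presence sets).
#' @param nSwaps number of successful swap moves to apply.
#' @param seed integer seed.
#' @return a permuted list of samples with the same structure.
#' @export
permuteSamples <- function(samples, nSwaps = 100, seed = 1L) {
  if (length(samples) < 2) stop("need at least 2 samples")
  ids <- sort(unique(unlist(samples)))
  set.seed(seed)
  presence <- runSwaps(samplesToPresence(samples, ids), nSwaps)
  presenceToSamples(presence)
}

#' Permutation test for preferred and avoided associations
#'
#' Builds per-pair null distributions of the association index from
#' \code{nPermutations} permuted sample sets. The chain starts with
#' \code{burnIn} swap moves and each null matrix is separated from the
#' previous one by \code{swapsPerStep} moves. A pair is flagged preferred
#' when its observed index is strictly greater than the null value at rank
#' ceiling(n (1 - alpha/2)) (with n = 10000 and alpha = 0.01, the 9950th
#' sorted value; two-tailed at P < alpha), and avoided when it is strictly
#' below the rank floor(n alpha/2) value.
#'
#' @param samples list of character vectors (window presence sets).
#' @param nPermutations number of permuted sample sets (>= 100).
#' @param alpha two-tailed significance level (default 0.01).
#' @param swapsPerStep swap moves between consecutive null matrices.
#' @param burnIn initial swap moves before the first null matrix.
#' @param indexType association index type.
#' @param seed integer seed.
#' @return a \linkS4class{PermutationResult}.
#' @export
preferredAssociations <- function(samples, nPermutations = 10000,
                                  alpha = 0.01, swapsPerStep = 100,
                                  burnIn = 1000,
                                  indexType = c("simple_ratio",
                                                "half_weight"),
                                  seed = 1L) {
  indexType <- match.arg(indexType)
  if (nPermutations < 100)
    stop("invalid parameter: nPermutations must be >= 100")
  ids <- sort(unique(unlist(samples)))
  if (length(ids) < 2 || length(samples) < 2)
    stop("need at least 2 identities and 2 samples")
  observed <- associationMatrix(samples, ids, indexType)
  presence <- samplesToPresence(samples, ids)
  nIds <- length(ids)
  ut <- which(upper.tri(observed@index))
  pairNames <- outer(ids, ids, paste, sep = "|")[ut]
  nulls <- matrix(NA_real_, nPermutations, length(ut),
                  dimnames = list(NULL, pairNames))
  set.seed(seed)
  presence <- runSwaps(presence, burnIn)
  for (k in seq_len(nPermutations)) {
    presence <- runSwaps(presence, swapsPerStep)
    nulls[k, ] <- associationFromPresence(presence, ids,
                                          indexType)@index[ut]
  }
  nulls <- apply(nulls, 2, sort)
  upRank <- ceiling(nPermutations * (1 - alpha / 2))
  loRank <- floor(nPermutations * alpha / 2)
  obs <- observed@index[ut]
  preferred <- obs > nulls[upRank, ] + 1e-12
  avoided <- if (loRank >= 1) obs < nulls[loRank, ] - 1e-12
             else rep(FALSE, length(ut))
  new("PermutationResult",
      observed = observed,
      nullDistributions = nulls,
      significantPairs = pairNames[preferred],
      avoidedPairs = pairNames[avoided],
      alpha = alpha,
      nPermutations = as.integer(nPermutations))
}

#' Randomly corrupt sighting identities
#'
#' Reassigns round(fraction * N) randomly chosen records to a uniformly
#' chosen *different* identity from the pool, emulating classification
#' errors of a given rate: the achieved classification accuracy of the
#' corrupted stream is 100 (1 - fraction) percent.
#'
#' @param records sightings data.frame with an identity column.
#' @param fraction fraction of records to corrupt in [0, 1]; values above
#'   0.9 are allowed with a warning.
#' @param idPool identity labels to draw replacements from (>= 2).
#' @param seed integer seed.
#' @return the records with corrupted identities.
#' @export
corruptIdentities <- function(records, fraction, idPool, seed = 1L) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  if (fraction > 0.9) warning("fraction above 0.9: below chance-level accuracy")
  if (length(idPool) < 2) stop("invalid parameter: idPool must have >= 2 ids")
  n <- nrow(records)
  m <- round(fraction * n)
  if (m == 0) return(records)
  set.seed(seed)
  idx <- sample.int(n, m)
  for (i in idx) {
    pool <- setdiff(idPool, records$identity[i])
    records$identity[i] <- pool[sample.int(length(pool), 1)]
  }
  records
}

#' Association-matrix degradation under identity corruption
#'
#' For each corruption fraction, repeatedly corrupts the sighting stream,
#' rebuilds the association matrix and correlates it (Pearson over the
#' upper triangle) with the reference matrix; reports the mean and sd of
#' the correlation against the achieved classification accuracy
#' 100 (1 - fraction).
#'
#' @param records sightings data.frame (time_s, identity).
#' @param referenceMatrix \linkS4class{AssociationMatrix} over the identity
#'   pool.
#' @param fractions corruption fractions to evaluate.
#' @param repeats random corruptions per fraction (default 10).
#' @param windowS,minDetections window parameters for the rebuild.
#' @param seed master seed.
#' @return data.frame with fraction, achievedAccuracy, meanR, sdR.
#' @export
degradationCurve <- function(records, referenceMatrix, fractions,
                             repeats = 10, windowS = 60, minDetections = 3,
                             seed = 1L) {
  ids <- referenceMatrix@ids
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max,
                             length(fractions) * repeats),
                  length(fractions), repeats)
  res <- lapply(seq_along(fractions), function(fi) {
    f <- fractions[fi]
    rs <- vapply(seq_len(repeats), function(r) {
      corrupted <- suppressWarnings(
        corruptIdentities(records, f, ids, seed = seeds[fi, r]))
      samples <- windowsFromSightings(corrupted, windowS, minDetections)
      m <- suppressWarnings(associationMatrix(samples, ids,
                                              referenceMatrix@indexType))
      matrixCorrelation(m@index, referenceMatrix@index)
    }, numeric(1))
    data.frame(fraction = f, achievedAccuracy = 100 * (1 - f),
               meanR = mean(rs, na.rm = TRUE),
               sdR = stats::sd(rs, na.rm = TRUE))
  })
  do.call(rbind, res)
}
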