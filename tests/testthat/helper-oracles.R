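# Independent brute-force oracles used across the suite. These deliberately
# re-derive results pixel by pixel / pair by pair, without reusing the
# package's vectorised code paths.

# per-pixel LBP via the single-neighbourhood operation
bruteLBP <- function(image, convention = "paper") {
  h <- nrow(image); w <- ncol(image)
  out <- matrix(NA_real_, h, w)
  for (r in 2:(h - 1)) {
    for (c in 2:(w - 1)) {
      centre <- image[r, c]
      nb <- c(image[r - 1, c - 1], image[r - 1, c], image[r - 1, c + 1],
              image[r, c + 1], image[r + 1, c + 1], image[r + 1, c],
              image[r + 1, c - 1], image[r, c - 1])
      bits <- if (convention == "paper") centre > nb else nb >= centre
      out[r, c] <- sum(bits * 2^(7:0))
    }
  }
  out
}

# circular-transition count of an 8-bit code
bruteTransitions <- function(code) {
  bits <- as.integer(intToBits(code))[1:8]
  sum(bits != c(bits[-1], bits[1]))
}

bruteChiSquare <- function(x, y) {
  s <- 0
  for (i in seq_along(x)) {
    if (x[i] + y[i] > 0) s <- s + (x[i] - y[i])^2 / (x[i] + y[i])
  }
  s
}

# shared-diagonal-covariance Gaussian log-density argmax, scalar loops only
bruteLDAPredict <- function(means, variances, query, labels) {
  best <- -Inf; bestLab <- NA
  for (k in seq_len(nrow(means))) {
    ll <- 0
    for (j in seq_along(query)) {
      ll <- ll - 0.5 * log(2 * pi * variances[j]) -
        (query[j] - means[k, j])^2 / (2 * variances[j])
    }
    if (ll > best) {
      best <- ll
      bestLab <- labels[k]
    }
  }
  bestLab
}

# optimal one-to-one detection/truth assignment by exhaustive enumeration
bruteBestMatching <- function(iou, threshold) {
  nd <- nrow(iou); nt <- ncol(iou)
  best <- 0L
  assignRec <- function(d, used) {
    if (d > nd) return(0L)
    most <- assignRec(d + 1L, used) # leave detection d unmatched
    for (t in seq_len(nt)) {
      if (!used[t] && iou[d, t] >= threshold) {
        used2 <- used; used2[t] <- TRUE
        most <- max(most, 1L + assignRec(d + 1L, used2))
      }
    }
    most
  }
  assignRec(1L, rep(FALSE, nt))
}

# association index counted sample by sample
bruteSimpleRatio <- function(samples, a, b) {
  both <- 0L; either <- 0L
  for (s in samples) {
    inA <- a %in% s; inB <- b %in% s
    if (inA && inB) both <- both + 1L
    if (inA || inB) either <- either + 1L
  }
  if (either == 0) 0 else both / either
}

randomFeatureImage <- function(seed = 1L, size = 100L) {
  set.seed(seed)
  matrix(stats::runif(size * size, 0, 255), size, size)
}
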