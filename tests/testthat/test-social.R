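# Windowed sightings, association indices, Mantel and group-membership
# permutation tests

toySightings <- function(entries, windowS = 60) {
  # entries: list of c(window, identity, count)
  rows <- lapply(entries, function(e) {
    w <- as.numeric(e[1]); n <- as.numeric(e[3])
    data.frame(time_s = (w - 1) * windowS + seq_len(n) * windowS / (n + 1),
               identity = e[2])
  })
  do.call(rbind, rows)
}

test_that("window aggregation enforces the minimum-detection threshold", {
  rec <- toySightings(list(c(1, "A", 3), c(1, "B", 2), c(2, "A", 5),
                           c(3, "C", 1)))
  s <- windowsFromSightings(rec, windowS = 60, minDetections = 3)
  expect_equal(length(s), 2L)            # window 3 has no present identity
  expect_identical(s[[1]], "A")          # B had only 2 detections
  expect_identical(s[[2]], "A")
  expect_identical(windowsFromSightings(rec[0, ]), list())
  expect_error(windowsFromSightings(rec, windowS = 0), "windowS")
})

test_that("simple-ratio indices match hand counts on a 6-sample toy", {
  # A in 4 samples, B in 4, both in 2, union 6 -> 2/6
  samples <- list(c("A", "B"), c("A", "B"), "A", "A", "B", "B",
                  c("C", "A"))
  m <- associationMatrix(samples)
  idx <- assocIndex(m)
  expect_equal(idx["A", "B"], bruteSimpleRatio(samples, "A", "B"))
  expect_equal(idx["A", "B"], 2 / 7)  # C-sample adds one A-only sample
  expect_equal(idx["A", "C"], bruteSimpleRatio(samples, "A", "C"))
  # symmetry and range over random sample sets
  set.seed(3)
  ids <- LETTERS[1:6]
  rs <- replicate(30, ids[runif(6) < 0.4], simplify = FALSE)
  rs <- rs[lengths(rs) > 0]
  mm <- suppressWarnings(assocIndex(associationMatrix(rs, ids)))
  expect_true(all(abs(mm - t(mm)) < 1e-12, na.rm = TRUE))
  expect_true(all(mm[upper.tri(mm)] >= 0 & mm[upper.tri(mm)] <= 1))
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(mm[i, j], bruteSimpleRatio(rs, ids[i], ids[j]))
  }
})

test_that("association matrix edge cases behave as documented", {
  # always together -> 1; never together -> 0
  s <- list(c("A", "B"), c("A", "B"), c("C"))
  idx <- assocIndex(associationMatrix(s))
  expect_equal(idx["A", "B"], 1)
  expect_equal(idx["A", "C"], 0)
  expect_warning(associationMatrix(s, ids = c("A", "B", "C", "D")),
                 "never observed")
})

test_that("Mantel statistic hits its analytic extremes", {
  set.seed(10)
  a <- matrix(runif(36), 6); a <- (a + t(a)) / 2; diag(a) <- NA
  expect_equal(mantelTest(a, a, nPermutations = 50)$r, 1)
  expect_equal(mantelTest(a, 1 - a, nPermutations = 50)$r, -1)
  const <- matrix(0.5, 6, 6); diag(const) <- NA
  expect_warning(res <- mantelTest(a, const, nPermutations = 50), "constant")
  expect_true(is.na(res$r))

  # independent cross-check of the statistic against vegan's Mantel r
  b <- matrix(runif(36), 6); b <- (b + t(b)) / 2; diag(b) <- 0
  a0 <- a; diag(a0) <- 0
  ref <- vegan::mantel(stats::as.dist(a0), stats::as.dist(b),
                       permutations = 0)
  expect_equal(mantelTest(a, b)$r, unname(ref$statistic))
})

test_that("Monte-Carlo Mantel p agrees with exhaustive enumeration at n=4", {
  set.seed(11)
  for (rep in 1:3) {
    a <- matrix(runif(16), 4); a <- (a + t(a)) / 2; diag(a) <- NA
    b <- matrix(runif(16), 4); b <- (b + t(b)) / 2; diag(b) <- NA
    ex <- mantelTest(a, b, exact = TRUE)
    expect_equal(ex$nPermutations, 24L)
    mc <- mantelTest(a, b, nPermutations = 4000, seed = rep)
    # binomial error of the MC estimate at n = 4000
    tol <- 4 * sqrt(ex$p * (1 - ex$p) / 4000) + 1e-3
    expect_lt(abs(mc$p - ex$p), max(tol, 0.05))
  }
})

test_that("identity swaps conserve group sizes and individual totals", {
  set.seed(12)
  ids <- paste0("id", 1:8)
  samples <- replicate(25, ids[runif(8) < 0.35], simplify = FALSE)
  samples <- samples[lengths(samples) > 0]
  perm <- permuteSamples(samples, nSwaps = 200, seed = 5)
  expect_identical(lengths(perm), lengths(samples))
  expect_identical(table(unlist(perm)), table(unlist(samples)))
  expect_false(any(vapply(perm, anyDuplicated, integer(1)) > 0))
  expect_false(identical(perm, samples))
})

test_that("swap chains explore many distinct configurations", {
  samples <- list(c("A", "B"), c("B", "C"), c("A", "C"))
  seen <- unique(vapply(1:60, function(s) {
    p <- permuteSamples(samples, nSwaps = 7, seed = s)
    paste(vapply(p, function(x) paste(sort(x), collapse = ""), ""),
          collapse = "|")
  }, character(1)))
  # brute-force: configurations with these group sizes and totals are the
  # assignments of the 3 pair-samples to the 3 id-pairs
  expect_gte(length(seen), 3)
})

test_that("preferred-association test flags a planted pair and only it", {
  st <- makeSocialStream(nIds = 8, nWindows = 250, backgroundP = 0.2,
                         forcedPairs = data.frame(a = 1, b = 2, p = 0.85),
                         seed = 71)
  samples <- windowsFromSightings(st$records)
  res <- preferredAssociations(samples, nPermutations = 600, seed = 4)
  expect_true("id01|id02" %in% res@significantPairs)
  expect_lte(length(res@significantPairs), 3)
  expect_equal(nrow(res@nullDistributions), 600L)
  # null columns are sorted
  expect_true(all(apply(res@nullDistributions, 2, function(col)
    all(diff(col) >= 0))))
  expect_error(preferredAssociations(samples, nPermutations = 50),
               "nPermutations")
})

test_that("when all identities always co-occur nothing is significant", {
  samples <- replicate(20, c("A", "B", "C"), simplify = FALSE)
  # no legal swap exists: the chain stalls (with warnings) and the null
  # distribution equals the observed matrix, so nothing can be significant
  res <- suppressWarnings(
    preferredAssociations(samples, nPermutations = 100, swapsPerStep = 5,
                          burnIn = 5, seed = 1))
  expect_length(res@significantPairs, 0)
  expect_length(res@avoidedPairs, 0)
})

test_that("identity corruption honours its contract", {
  st <- makeSocialStream(nIds = 6, nWindows = 40, seed = 31)
  rec <- st$records
  expect_identical(corruptIdentities(rec, 0, st$ids), rec)
  out <- corruptIdentities(rec, 0.4, st$ids, seed = 2)
  changed <- sum(out$identity != rec$identity)
  expect_equal(changed, round(0.4 * nrow(rec)))
  expect_true(all(out$identity %in% st$ids))
  expect_error(corruptIdentities(rec, 0.2, "one"), "idPool")
  expect_warning(corruptIdentities(rec, 0.95, st$ids), "0.9")
})

test_that("degradation curve starts at the uncorrupted correlation", {
  st <- makeSocialStream(nIds = 8, nWindows = 150,
                         forcedPairs = data.frame(a = 1, b = 2, p = 0.7),
                         seed = 41)
  tab <- degradationCurve(st$records, st$truth, fractions = c(0, 0.5),
                          repeats = 3, seed = 9)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$meanR[1], 1)   # rebuild reproduces the truth matrix
  expect_equal(tab$achievedAccuracy, c(100, 50))
  expect_lt(tab$meanR[2], tab$meanR[1])
})

test_that("synthetic stream generator is seeded and self-consistent", {
  s1 <- makeSocialStream(nIds = 5, nWindows = 50, seed = 3)
  s2 <- makeSocialStream(nIds = 5, nWindows = 50, seed = 3)
  expect_identical(s1$records, s2$records)
  expect_identical(assocIndex(s1$truth), assocIndex(s2$truth))
  # forced pair with probability 1 -> index exactly 1
  sf <- makeSocialStream(nIds = 4, nWindows = 30,
                         forcedPairs = data.frame(a = 1, b = 2, p = 1),
                         seed = 8)
  expect_equal(assocIndex(sf$truth)["id01", "id02"], 1)
  # windowed rebuild reproduces the realised truth exactly
  rebuilt <- associationMatrix(windowsFromSightings(sf$records), sf$ids)
  expect_equal(assocIndex(rebuilt), assocIndex(sf$truth))
})
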