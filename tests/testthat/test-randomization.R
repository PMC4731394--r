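test_that("uniform randomization preserves (n, m) and simplicity", {
  g <- randomAttributedGraph(30, 80, q = 2, seed = 61)
  withr::with_seed(61, {
    for (i in 1:10) {
      r <- randomizeUniform(g)
      expect_identical(nodeIds(r), nodeIds(g))
      expect_identical(nodeAttributes(r), nodeAttributes(g))
      expect_equal(numEdges(r), 80)
      e <- edgeMatrix(r)
      expect_true(all(e[, 1] < e[, 2]))
      expect_equal(anyDuplicated(paste(e[, 1], e[, 2])), 0)
    }
  })
})

test_that("a saturated graph can only be randomized to itself", {
  # n = 3, m = 3: the triangle is the unique simple graph
  ids <- c("a", "b", "c")
  X <- matrix(1:3, 3, 1, dimnames = list(ids, "x"))
  g <- attributedGraph(cbind(c("a", "a", "b"), c("b", "c", "c")), X)
  withr::with_seed(62, {
    for (i in 1:5)
      expect_equal(edgeMatrix(randomizeUniform(g)), edgeMatrix(g))
  })
})

test_that("uniform randomization is uniform over the G(n, m) ensemble", {
  # n = 4, m = 1: each of the 6 edges should appear with frequency 1/6
  ids <- c("a", "b", "c", "d")
  X <- matrix(1:4, 4, 1, dimnames = list(ids, "x"))
  g <- attributedGraph(cbind("a", "b"), X, nodeIds = ids)
  draws <- withr::with_seed(63, vapply(1:6000, function(i) {
    e <- edgeMatrix(randomizeUniform(g))
    paste(e[1, 1], e[1, 2])
  }, character(1)))
  freq <- table(draws) / 6000
  expect_equal(length(freq), 6L)
  se <- sqrt((1 / 6) * (5 / 6) / 6000)
  expect_true(all(abs(freq - 1 / 6) < 3 * se))
})

test_that("degree-preserving swaps conserve the degree sequence exactly", {
  for (seed in 1:10) {
    g <- randomAttributedGraph(25, 60, q = 1, seed = seed + 70)
    r <- withr::with_seed(seed, randomizeDegreePreserving(g))
    expect_identical(degreeSequence(r), degreeSequence(g))
    e <- edgeMatrix(r)
    expect_true(all(e[, 1] < e[, 2]))
    expect_equal(anyDuplicated(paste(e[, 1], e[, 2])), 0)
  }
})

test_that("rigid graphs come back unchanged from edge swapping", {
  g <- starGraph(4)
  r <- withr::with_seed(64, suppressMessages(randomizeDegreePreserving(g)))
  expect_equal(sort(paste(edgeMatrix(r)[, 1], edgeMatrix(r)[, 2])),
               sort(paste(edgeMatrix(g)[, 1], edgeMatrix(g)[, 2])))
})

test_that("edge swapping reaches all 2-regular graphs from a 6-cycle", {
  # the 2-regular simple graphs on 6 labeled nodes are 6-cycles and
  # pairs of triangles; both families must appear across draws
  g <- cycleGraph(6)
  tri <- withr::with_seed(65, vapply(1:60, function(i) {
    r <- randomizeDegreePreserving(g, swapFactor = 5)
    ig <- igraph::graph_from_edgelist(edgeMatrix(r), directed = FALSE)
    igraph::count_components(ig)
  }, numeric(1)))
  expect_true(any(tri == 1))  # a 6-cycle
  expect_true(any(tri == 2))  # two triangles
})

test_that("covariate-matched randomization preserves per-bin edge counts", {
  g <- randomAttributedGraph(40, 100, q = 1, seed = 66)
  pos <- withr::with_seed(166, matrix(rnorm(40), ncol = 1))
  nBins <- 8
  e <- edgeMatrix(g)
  w <- abs(pos[e[, 1], 1] - pos[e[, 2], 1])
  br <- vamix:::.covariateBreaks(w, nBins)
  counts <- tabulate(.bincode(w, br, right = TRUE, include.lowest = TRUE),
                     nbins = length(br) - 1)
  withr::with_seed(67, {
    for (i in 1:10) {
      r <- randomizeCovariateMatched(g, pos, nBins = nBins)
      e2 <- edgeMatrix(r)
      w2 <- abs(pos[e2[, 1], 1] - pos[e2[, 2], 1])
      c2 <- tabulate(.bincode(w2, br, right = TRUE, include.lowest = TRUE),
                     nbins = length(br) - 1)
      expect_identical(c2, counts)
      expect_equal(anyDuplicated(paste(e2[, 1], e2[, 2])), 0)
      expect_true(all(e2[, 1] < e2[, 2]))
    }
  })
})

test_that("covariate matching tracks the real edge-covariate distribution", {
  # KS distance real-vs-randomized should not exceed the KS distance
  # between two halves of the real sample (self-comparison oracle)
  g <- randomAttributedGraph(60, 200, q = 1, seed = 68)
  pos <- withr::with_seed(168, matrix(cumsum(rnorm(60)), ncol = 1))
  e <- edgeMatrix(g)
  w <- abs(pos[e[, 1], 1] - pos[e[, 2], 1])
  withr::with_seed(69, {
    half <- sample.int(200, 100)
    ksSelf <- suppressWarnings(
      stats::ks.test(w[half], w[-half])$statistic)
    r <- randomizeCovariateMatched(g, pos, nBins = 20)
    e2 <- edgeMatrix(r)
    w2 <- abs(pos[e2[, 1], 1] - pos[e2[, 2], 1])
    ksRand <- suppressWarnings(stats::ks.test(w, w2)$statistic)
  })
  expect_lt(ksRand, ksSelf)
})

test_that("a constant covariate degenerates to a single bin", {
  g <- randomAttributedGraph(20, 40, q = 1, seed = 70)
  r <- withr::with_seed(71,
    randomizeCovariateMatched(g, rep(1, 20), nBins = 10))
  expect_equal(numEdges(r), 40)
})

test_that("sampleNull summarizes B randomizations reproducibly", {
  g <- randomAttributedGraph(30, 70, q = 3, seed = 72)
  ns1 <- sampleNull(g, B = 50, seed = 99)
  ns2 <- sampleNull(g, B = 50, seed = 99)
  expect_identical(xiMeans(ns1), xiMeans(ns2))
  expect_identical(sigmaRand(ns1), sigmaRand(ns2))
  expect_equal(ns1@B, 50L)
  expect_error(sampleNull(g, B = 1), "B must be >= 2")
})

test_that("each null mean is the mean similarity of its own replicate", {
  # reconstruct replicate edge sets from the documented substream contract
  # and recompute the mean cosine similarity with the pairwise function
  g <- randomAttributedGraph(30, 70, q = 3, seed = 73)
  B <- 20; seed <- 123
  ns <- sampleNull(g, B = B, seed = seed)
  X <- nodeAttributes(g)
  repSeeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, B))
  for (i in c(1, 7, 20)) {
    set.seed(repSeeds[i])
    idx <- igraph::as_edgelist(igraph::sample_gnm(30, 70), names = FALSE)
    ref <- mean(vapply(seq_len(nrow(idx)), function(r)
      cosineSimilarity(X[idx[r, 1], ], X[idx[r, 2], ]), numeric(1)))
    expect_equal(xiMeans(ns)[i], ref, tolerance = 1e-12)
  }
})

test_that("identical attributes give a degenerate null sample", {
  ids <- paste0("v", 1:10)
  X <- matrix(rep(c(1, 2), each = 10), 10, 2, dimnames = list(ids, NULL))
  e <- cbind(ids[1:9], ids[2:10])
  g <- attributedGraph(e, X, nodeIds = ids)
  ns <- sampleNull(g, B = 10, seed = 5)
  expect_equal(xiMeans(ns), rep(1, 10), tolerance = 1e-12)
  expect_lt(sigmaRand(ns), 1e-12)
})

test_that("null mean is stable in B for structure-independent attributes", {
  g <- randomAttributedGraph(40, 100, q = 3, seed = 74)
  nsSmall <- sampleNull(g, B = 50, seed = 7)
  nsBig <- sampleNull(g, B = 400, seed = 8)
  # standard error of the mean shrinks ~ 1/sqrt(B)
  seSmall <- stats::sd(xiMeans(nsSmall)) / sqrt(50)
  expect_lt(abs(mean(xiMeans(nsBig)) - mean(xiMeans(nsSmall))), 5 * seSmall)
})

test_that("degree-preserving null sampling also runs end to end", {
  g <- randomAttributedGraph(20, 50, q = 2, seed = 75)
  ns <- sampleNull(g, scheme = degreeSwapScheme(2), B = 10, seed = 11)
  expect_length(xiMeans(ns), 10)
  expect_true(all(is.finite(xiMeans(ns))))
})
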