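test_that("mean edge similarity matches hand sums and a brute-force loop", {
  # all nodes share one nonzero vector
  ids <- c("a", "b", "c")
  X <- matrix(rep(c(1, 2), each = 3), 3, 2, dimnames = list(ids, NULL))
  tri <- attributedGraph(cbind(c("a", "a", "b"), c("b", "c", "c")), X)
  expect_equal(meanEdgeSimilarity(tri), 1, tolerance = 1e-12)

  # triangle with vectors e1, e1, e2: edge similarities 1, 0, 0
  X2 <- rbind(a = c(1, 0), b = c(1, 0), c = c(0, 1))
  tri2 <- attributedGraph(cbind(c("a", "a", "b"), c("b", "c", "c")), X2)
  expect_equal(meanEdgeSimilarity(tri2), 1 / 3, tolerance = 1e-12)

  # brute-force loop-and-divide oracle on a random instance
  g <- randomAttributedGraph(20, 50, q = 4, seed = 81)
  X3 <- nodeAttributes(g)
  e <- edgeMatrix(g)
  for (k in c("cosine", "correlation", "euclidean")) {
    acc <- 0
    for (i in seq_len(nrow(e)))
      acc <- acc + pairSimilarity(k, X3[e[i, 1], ], X3[e[i, 2], ])
    expect_equal(meanEdgeSimilarity(g, k), acc / nrow(e), tolerance = 1e-12)
  }
})

test_that("the empirical test places extreme and central values correctly", {
  xi <- as.numeric(1:99) / 100
  res <- empiricalTest(0.999, xi, sigLevel = 0.05)
  expect_equal(res$pValue, 0.02)
  expect_equal(res$verdict, "positive")

  resLow <- empiricalTest(0.0001, xi, sigLevel = 0.05)
  expect_equal(resLow$pValue, 0.02)
  expect_equal(resLow$verdict, "negative")

  resMid <- empiricalTest(stats::median(xi), xi, sigLevel = 0.05)
  expect_equal(resMid$verdict, "random")
  expect_equal(resMid$pValue, 1)
})

test_that("a fully degenerate null with a matching observation is 'random'", {
  xi <- rep(0.5, 10)
  res <- empiricalTest(0.5, xi, sigLevel = 0.05)
  expect_equal(res$verdict, "random")
  expect_equal(res$pValue, 1)
})

test_that("p-values and quantile endpoints match a sort-and-count reference", {
  refTest <- function(obs, xi, sig) {
    s <- sort(xi); B <- length(xi)
    # (B+1) plotting positions with linear interpolation, clamped to the range
    q6 <- function(p) {
      h <- (B + 1) * p
      if (h <= 1) return(s[1])
      if (h >= B) return(s[B])
      lo <- floor(h)
      s[lo] + (h - lo) * (s[lo + 1] - s[lo])
    }
    nLe <- sum(s <= obs); nGe <- sum(s >= obs)
    list(p = min(1, 2 * min(1 + nLe, 1 + nGe) / (B + 1)),
         lo = q6(sig / 2), hi = q6(1 - sig / 2))
  }
  withr::with_seed(82, {
    for (i in 1:50) {
      B <- sample(c(10, 37, 200), 1)
      xi <- rnorm(B)
      obs <- if (i %% 3 == 0) sample(xi, 1) else rnorm(1)
      sig <- sample(c(0.01, 0.05, 0.1), 1)
      ref <- refTest(obs, xi, sig)
      got <- empiricalTest(obs, xi, sig)
      expect_equal(got$pValue, ref$p, tolerance = 1e-15)
      expect_equal(got$ciLow, ref$lo, tolerance = 1e-12)
      expect_equal(got$ciHigh, ref$hi, tolerance = 1e-12)
    }
  })
})

test_that("the standardized difference is plain arithmetic on the null", {
  ns <- new("NullSample", xiMeans = c(0.2, 0.4, 0.6), sigmaRand = 0.25,
            B = 3L, seed = 1L, scheme = gnmScheme(), similarity = "cosine")
  mXi <- mean(c(0.2, 0.4, 0.6))
  expect_equal(standardizedDifference(mXi, ns), 0)
  expect_equal(standardizedDifference(mXi + 0.25, ns), 1)
  expect_equal(standardizedDifference(0.9, ns), (0.9 - mXi) / 0.25,
               tolerance = 1e-15)

  nsZero <- new("NullSample", xiMeans = c(0.5, 0.5), sigmaRand = 0,
                B = 2L, seed = 1L, scheme = gnmScheme(), similarity = "cosine")
  expect_equal(standardizedDifference(0.5, nsZero), 0)
  expect_error(standardizedDifference(0.7, nsZero), "degenerate")
})

test_that("the bounded transform matches its closed forms and asymptote", {
  expect_equal(alphaTransform(0, 1), 0)
  expect_equal(alphaTransform(0, 17), 0)
  expect_equal(alphaTransform(1, 1), 1 / sqrt(2))
  expect_equal(alphaTransform(-3, 1), -3 / sqrt(10))
  expect_lt(1 - alphaTransform(1e6, 1), 1e-11)
  expect_error(alphaTransform(1, 0), "positive")
  expect_error(alphaTransform(1, -2), "positive")
})

test_that("the transform is odd, monotone in d, and shrinking in epsilon", {
  d <- seq(-30, 30, length.out = 301)
  a <- alphaTransform(d, 1)
  expect_true(all(abs(a) < 1))
  expect_equal(a, -rev(a), tolerance = 1e-15)        # odd in d
  expect_true(all(diff(a) > 0))                      # strictly increasing
  eps <- c(0.1, 0.5, 1, 2, 10)
  aPos <- vapply(eps, function(e) alphaTransform(2, e), numeric(1))
  expect_true(all(diff(aPos) < 0))                   # decreasing for d > 0
  aNeg <- vapply(eps, function(e) alphaTransform(-2, e), numeric(1))
  expect_true(all(diff(aNeg) > 0))                   # increasing for d < 0
})

test_that("computeVAIndex detects planted positive mixing", {
  net <- generateNetwork(
    syntheticConfig(n = 80, targetM = 240, q = 4, pIn = 0.9, pOut = 0.1),
    seed = 83)
  res <- computeVAIndex(net@graph, B = 200, seed = 84)
  expect_s4_class(res, "VAResult")
  expect_equal(res@verdict, "positive")
  expect_gt(res@alpha, 0)
  expect_lte(res@pValue, 0.05)
  # internal consistency of the stored quantities
  expect_equal(res@alpha, alphaTransform(res@d, res@params$epsilon))
  expect_equal(sign(res@alpha), sign(res@xiBarG - res@mXi))
})

test_that("computeVAIndex is deterministic given a seed", {
  g <- randomAttributedGraph(25, 60, q = 3, seed = 85)
  r1 <- computeVAIndex(g, B = 100, seed = 42)
  r2 <- computeVAIndex(g, B = 100, seed = 42)
  for (slot in c("alpha", "d", "xiBarG", "mXi", "sigmaRand", "pValue",
                 "ciLow", "ciHigh", "verdict"))
    expect_identical(methods::slot(r1, slot), methods::slot(r2, slot))
})

test_that("VAResult serializes to JSON with all fields and parameters", {
  g <- randomAttributedGraph(20, 40, q = 2, seed = 86)
  res <- computeVAIndex(g, B = 50, seed = 1)
  f <- withr::local_tempfile(fileext = ".json")
  writeVAResult(res, f)
  parsed <- jsonlite::read_json(f)
  expect_setequal(
    names(parsed),
    c("schema_version", "tool", "version", "alpha", "d", "xi_bar_G", "m_Xi",
      "sigma_rand", "p_value", "ci_low", "ci_high", "verdict", "params"))
  expect_equal(parsed$alpha, res@alpha, tolerance = 1e-12)
  expect_equal(parsed$params$seed, 1)
})
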