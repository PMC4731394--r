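#' Graph randomization null models
#'
#' Each randomizer rewires the edges of a graph while keeping the attribute
#' vectors attached to their nodes; what is preserved depends on the scheme:
#' \itemize{
#'   \item \code{randomizeUniform}: a uniform draw from G(n, m) — all simple
#'     graphs on the same node set with the same number of edges.
#'   \item \code{randomizeDegreePreserving}: \code{swapFactor * m} accepted
#'     double-edge swaps (swaps creating self-loops or duplicate edges are
#'     rejected), so the full degree sequence is preserved exactly. Graphs
#'     admitting no valid swap (e.g. stars) are returned unchanged, with a
#'     message.
#'   \item \code{randomizeCovariateMatched}: replaces the edges by random
#'     node pairs whose pairwise covariate values match, bin for bin, the
#'     real network's edge-covariate distribution (equal-frequency bins).
#' }
#'
#' @param graph an [AttributedGraph].
#' @param swapFactor accepted swaps per edge (default 10).
#' @param covariate per-node covariate as in [covariateScheme()].
#' @param nBins,maxTries binning parameters as in [covariateScheme()].
#' @return a new [AttributedGraph] with rewired edges and unchanged nodes and
#'   attributes.
#' @examples
#' g <- exampleGraph()
#' set.seed(1)
#' identical(sort(degreeSequence(randomizeDegreePreserving(g))),
#'           sort(degreeSequence(g)))
#' @name randomize
NULL

#' @rdname randomize
#' @export
randomizeUniform <- function(graph) {
  n <- length(graph@nodeIds)
  m <- nrow(graph@edges)
  .replaceEdges(graph, .gnmEdges(n, m))
}

.gnmEdges <- function(n, m) {
  if (m > n * (n - 1) / 2)
    stop("m exceeds the number of distinct node pairs", call. = FALSE)
  idx <- igraph::as_edgelist(igraph::sample_gnm(n, m), names = FALSE)
  storage.mode(idx) <- "integer"
  cbind(pmin.int(idx[, 1L], idx[, 2L]), pmax.int(idx[, 1L], idx[, 2L]))
}

#' @rdname randomize
#' @export
randomizeDegreePreserving <- function(graph, swapFactor = 10) {
  .replaceEdges(graph, .swapEdges(graph@edges, length(graph@nodeIds),
                                  swapFactor))
}

# double-edge swaps until `swapFactor * m` swaps are ACCEPTED, with an
# attempt cap (100x the target) so rigid graphs terminate. Edge membership
# is tracked in a logical vector keyed by (i-1)*n + j; memory O(n^2), fine
# for the network sizes this package targets.
.swapEdges <- function(edges, n, swapFactor = 10) {
  m <- nrow(edges)
  if (m < 2L) return(edges)
  target <- ceiling(swapFactor * m)
  maxAttempts <- 100 * target
  present <- logical(n * n)
  keyOf <- function(i, j) (pmin.int(i, j) - 1L) * n + pmax.int(i, j)
  present[keyOf(edges[, 1L], edges[, 2L])] <- TRUE
  a <- edges[, 1L]; b <- edges[, 2L]
  accepted <- 0L; attempts <- 0L
  while (accepted < target && attempts < maxAttempts) {
    attempts <- attempts + 1L
    e <- sample.int(m, 2L)
    e1 <- e[1L]; e2 <- e[2L]
    x1 <- a[e1]; y1 <- b[e1]; x2 <- a[e2]; y2 <- b[e2]
    if (stats::runif(1) < 0.5) { tmp <- x2; x2 <- y2; y2 <- tmp }
    # proposed replacement: (x1, y2) and (x2, y1)
    if (x1 == y2 || x2 == y1) next
    k1 <- keyOf(x1, y2); k2 <- keyOf(x2, y1)
    if (present[k1] || present[k2]) next
    present[keyOf(x1, y1)] <- FALSE
    present[keyOf(x2, y2)] <- FALSE
    present[k1] <- TRUE; present[k2] <- TRUE
    a[e1] <- min(x1, y2); b[e1] <- max(x1, y2)
    a[e2] <- min(x2, y1); b[e2] <- max(x2, y1)
    accepted <- accepted + 1L
  }
  if (accepted < target)
    message("degree-preserving rewiring: only ", accepted, " of ", target,
            " swaps accepted within the attempt cap (graph may admit few",
            " or no valid swaps)")
  cbind(a, b, deparse.level = 0L)
}

#' @rdname randomize
#' @export
randomizeCovariateMatched <- function(graph, covariate, nBins = 20,
                                      maxTries = 1000) {
  if (is.null(dim(covariate))) covariate <- matrix(as.numeric(covariate), ncol = 1L)
  .replaceEdges(graph, .covariateEdges(graph@edges, length(graph@nodeIds),
                                       covariate, nBins, maxTries))
}

.pairCovariate <- function(covariate, i, j) {
  if (ncol(covariate) == 1L) abs(covariate[i, 1L] - covariate[j, 1L])
  else sqrt((covariate[i, 1L] - covariate[j, 1L])^2 +
            (covariate[i, 2L] - covariate[j, 2L])^2)
}

# breaks of the equal-frequency bins of the observed edge covariate; outer
# edges open so out-of-range randomized pairs land in the extreme bins, and
# duplicated quantiles (heavy ties) collapse so ties share a bin
.covariateBreaks <- function(w, nBins) {
  br <- stats::quantile(w, probs = seq(0, 1, length.out = nBins + 1L),
                        type = 7, names = FALSE)
  br <- unique(br)
  br[1L] <- -Inf
  br[length(br)] <- Inf
  if (length(br) == 1L) br <- c(-Inf, Inf)
  br
}

.covariateEdges <- function(edges, n, covariate, nBins, maxTries) {
  m <- nrow(edges)
  if (nrow(covariate) != n)
    stop("covariate must be defined for every node", call. = FALSE)
  w <- .pairCovariate(covariate, edges[, 1L], edges[, 2L])
  br <- .covariateBreaks(w, nBins)
  nb <- length(br) - 1L
  need <- tabulate(.bincode(w, br, right = TRUE, include.lowest = TRUE),
                   nbins = nb)
  used <- logical(n * n)
  a <- integer(m); b <- integer(m)
  got <- 0L
  triesSinceAccept <- 0L
  while (got < m) {
    i <- sample.int(n, 1L); j <- sample.int(n, 1L)
    if (i == j) next
    triesSinceAccept <- triesSinceAccept + 1L
    lo <- min(i, j); hi <- max(i, j)
    key <- (lo - 1L) * n + hi
    if (!used[key]) {
      bin <- .bincode(.pairCovariate(covariate, lo, hi), br, right = TRUE,
                      include.lowest = TRUE)
      if (need[bin] > 0L) {
        used[key] <- TRUE
        got <- got + 1L
        a[got] <- lo; b[got] <- hi
        need[bin] <- need[bin] - 1L
        triesSinceAccept <- 0L
        next
      }
    }
    if (triesSinceAccept >= maxTries) {
      stop("covariate-matched randomization: no unused admissible pair found",
           " within ", maxTries, " tries for bin ", which(need > 0L)[1L],
           " (", sum(need), " pair(s) still needed)", call. = FALSE)
    }
  }
  cbind(a, b, deparse.level = 0L)
}

#' Sample the Monte-Carlo null distribution of mean edge similarity
#'
#' Runs B independent randomizations of the graph under a null-model scheme,
#' computing for each the mean attribute similarity over its edges. Each
#' replicate is seeded from its own substream derived from \code{seed}, so
#' the sample is reproducible bit for bit. Alongside the B means, the pooled
#' standard deviation of all B*m edge-level similarities (denominator
#' B*m - 1) is recorded; this edge-level dispersion is the scale on which the
#' observed excess similarity is standardized.
#'
#' @param graph an [AttributedGraph].
#' @param similarity \code{"cosine"} (default), \code{"correlation"} or
#'   \code{"euclidean"}.
#' @param scheme a [RandomizationScheme]; default [gnmScheme()].
#' @param B number of randomizations (>= 2); default 1000.
#' @param seed integer master seed; if \code{NULL} one is drawn and reported
#'   via a message.
#' @return a [NullSample].
#' @examples
#' ns <- sampleNull(exampleGraph(), B = 50, seed = 7)
#' mean(xiMeans(ns)); sigmaRand(ns)
#' @export
sampleNull <- function(graph, similarity = "cosine", scheme = gnmScheme(),
                       B = 1000, seed = NULL) {
  B <- as.integer(B)
  if (B < 2L) stop("B must be >= 2", call. = FALSE)
  similarity <- .matchSimilarity(similarity)
  seed <- .resolveSeed(seed)
  prep <- .simPrep(graph@attributes, similarity)
  n <- length(graph@nodeIds)
  m <- nrow(graph@edges)
  sampler <- .schemeSampler(graph, scheme)
  xi <- numeric(B)
  s1 <- 0; s2 <- 0; center <- NA_real_
  withr::with_seed(seed, {
    repSeeds <- sample.int(.Machine$integer.max - 1L, B)
    for (i in seq_len(B)) {
      set.seed(repSeeds[i])
      idx <- sampler()
      sims <- .edgeSims(prep, idx)
      xi[i] <- mean(sims)
      # pooled variance accumulated around a fixed center for accuracy
      if (is.na(center)) center <- sims[1L]
      s1 <- s1 + sum(sims - center)
      s2 <- s2 + sum((sims - center)^2)
    }
  })
  N <- as.double(B) * m
  sigma <- sqrt(max(0, (s2 - s1^2 / N) / (N - 1)))
  new("NullSample", xiMeans = xi, sigmaRand = sigma, B = B, seed = seed,
      scheme = scheme, similarity = similarity)
}

# one-argument closure drawing a randomized integer edge matrix
.schemeSampler <- function(graph, scheme) {
  n <- length(graph@nodeIds)
  edges <- graph@edges
  m <- nrow(edges)
  if (is(scheme, "GnmScheme")) {
    function() .gnmEdges(n, m)
  } else if (is(scheme, "DegreeSwapScheme")) {
    sf <- scheme@swapFactor
    function() .swapEdges(edges, n, sf)
  } else if (is(scheme, "CovariateScheme")) {
    cov <- scheme@covariate
    if (nrow(cov) != n)
      stop("covariate must have one row per node", call. = FALSE)
    nb <- scheme@nBins; mt <- scheme@maxTries
    function() .covariateEdges(edges, n, cov, nb, mt)
  } else stop("unknown randomization scheme", call. = FALSE)
}

.resolveSeed <- function(seed) {
  if (is.null(seed)) {
    seed <- sample.int(.Machine$integer.max - 1L, 1L)
    message("no seed supplied; using randomly drawn seed ", seed)
  }
  as.integer(seed)
}
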