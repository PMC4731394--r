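#' @import methods
NULL

#' AttributedGraph: an undirected simple graph with vector node attributes
#'
#' The central data container: an undirected simple graph on \code{n} nodes
#' together with a numeric \code{n x q} attribute matrix, one length-\code{q}
#' row per node. Edges are stored as an \code{m x 2} integer matrix of indices
#' into \code{nodeIds}, each row ordered so that the first index is smaller;
#' the adjacency matrix and degree sequence are derived views.
#'
#' @slot nodeIds character vector of opaque node identifiers (length n,
#'   unique). Numeric-looking ids are kept as strings.
#' @slot edges integer matrix with m rows and 2 columns; each row is an
#'   undirected edge (i, j) with i < j; no self-loops, no duplicates.
#' @slot attributes numeric matrix with n rows (rownames = nodeIds) and
#'   q >= 1 columns; all entries finite.
#'
#' @seealso [attributedGraph()] for the validating constructor,
#'   [readEdgeList()] and [readAttributes()] for file input.
#' @export
setClass("AttributedGraph",
  representation(
    nodeIds = "character",
    edges = "matrix",
    attributes = "matrix"
  )
)

setValidity("AttributedGraph", function(object) {
  msg <- character()
  n <- length(object@nodeIds)
  if (n < 2L) msg <- c(msg, "graph must have at least 2 nodes")
  if (anyDuplicated(object@nodeIds)) msg <- c(msg, "node ids must be unique")
  e <- object@edges
  if (!is.integer(e) || ncol(e) != 2L) {
    msg <- c(msg, "edges must be an integer matrix with 2 columns")
  } else {
    if (nrow(e) < 1L) msg <- c(msg, "graph must have at least 1 edge")
    if (nrow(e) > 0L) {
      if (any(e < 1L) || any(e > n)) {
        msg <- c(msg, "edge endpoints must index into nodeIds")
      } else {
        if (any(e[, 1L] >= e[, 2L])) {
          msg <- c(msg, "edges must satisfy i < j (no self-loops, canonical order)")
        }
        if (anyDuplicated(e[, 1L] + as.double(n) * e[, 2L])) {
          msg <- c(msg, "duplicate edges are not allowed")
        }
      }
    }
  }
  a <- object@attributes
  if (!is.numeric(a)) msg <- c(msg, "attributes must be a numeric matrix")
  else {
    if (nrow(a) != n) msg <- c(msg, "attributes must have one row per node")
    if (ncol(a) < 1L) msg <- c(msg, "attribute dimension q must be >= 1")
    if (!all(is.finite(a))) msg <- c(msg, "all attribute entries must be finite")
    if (!identical(rownames(a), object@nodeIds)) {
      msg <- c(msg, "attribute rownames must equal nodeIds")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Randomization schemes (null models)
#'
#' Virtual parent of the three graph-randomization null models used to build
#' the Monte-Carlo null distribution of mean edge similarity:
#' \describe{
#'   \item{\code{GnmScheme}}{uniform draw from the G(n, m) ensemble: all
#'     simple graphs on the same node set with the same edge count.}
#'   \item{\code{DegreeSwapScheme}}{degree-preserving double-edge swaps;
#'     \code{swapFactor * m} accepted swaps are performed.}
#'   \item{\code{CovariateScheme}}{random node pairs matched to the real
#'     network's per-bin counts of a pairwise node covariate (absolute
#'     difference of a scalar, or Euclidean distance between coordinate
#'     rows), with \code{nBins} equal-frequency bins.}
#' }
#' Construct with [gnmScheme()], [degreeSwapScheme()] or [covariateScheme()].
#'
#' @name RandomizationScheme-class
#' @aliases RandomizationScheme GnmScheme DegreeSwapScheme CovariateScheme
#' @export
setClass("RandomizationScheme", representation("VIRTUAL"))

#' @export
setClass("GnmScheme", contains = "RandomizationScheme")

#' @export
setClass("DegreeSwapScheme", contains = "RandomizationScheme",
  representation(swapFactor = "numeric"))

setValidity("DegreeSwapScheme", function(object) {
  if (length(object@swapFactor) != 1L || !is.finite(object@swapFactor) ||
      object@swapFactor <= 0) "swapFactor must be a single positive number"
  else TRUE
})

#' @export
setClass("CovariateScheme", contains = "RandomizationScheme",
  representation(covariate = "matrix", nBins = "integer", maxTries = "integer"))

setValidity("CovariateScheme", function(object) {
  msg <- character()
  if (!is.numeric(object@covariate) || !all(is.finite(object@covariate)))
    msg <- c(msg, "covariate must be a finite numeric matrix (n x 1 or n x 2)")
  if (!ncol(object@covariate) %in% 1:2)
    msg <- c(msg, "covariate must have 1 (scalar) or 2 (coordinate) columns")
  if (object@nBins < 1L) msg <- c(msg, "nBins must be >= 1")
  if (object@maxTries < 1L) msg <- c(msg, "maxTries must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Constructors for randomization schemes
#'
#' @param swapFactor accepted double-edge swaps per edge (default 10), a
#'   common burn-in heuristic for edge-swap MCMC.
#' @param covariate per-node covariate: a numeric vector (scalar covariate,
#'   pairwise value = absolute difference) or a 2-column matrix of
#'   coordinates (pairwise value = Euclidean distance). One row/value per
#'   node, in node order.
#' @param nBins number of equal-frequency bins for the edge-covariate
#'   distribution (default 20).
#' @param maxTries consecutive rejected draws tolerated while unfilled bins
#'   remain before the randomization aborts (default 1000).
#' @return a [RandomizationScheme] object.
#' @examples
#' gnmScheme()
#' degreeSwapScheme(swapFactor = 5)
#' @rdname schemes
#' @export
gnmScheme <- function() new("GnmScheme")

#' @rdname schemes
#' @export
degreeSwapScheme <- function(swapFactor = 10) {
  new("DegreeSwapScheme", swapFactor = as.numeric(swapFactor))
}

#' @rdname schemes
#' @export
covariateScheme <- function(covariate, nBins = 20, maxTries = 1000) {
  if (is.null(dim(covariate))) covariate <- matrix(as.numeric(covariate), ncol = 1L)
  new("CovariateScheme", covariate = covariate, nBins = as.integer(nBins),
      maxTries = as.integer(maxTries))
}

#' NullSample: Monte-Carlo null distribution of mean edge similarity
#'
#' Holds the sample of B mean edge similarities computed on B randomized
#' networks, plus the pooled standard deviation of the B*m edge-level
#' similarities (the dispersion used to standardize the observed excess
#' similarity). The pooled edge-level dispersion, not the spread of the B
#' means, is used because the latter shrinks as 1/sqrt(m) and would saturate
#' the bounded index for any large network.
#'
#' @slot xiMeans numeric vector of length B: mean edge similarity of each
#'   randomized network.
#' @slot sigmaRand pooled standard deviation (denominator B*m - 1) of all
#'   B*m edge-level similarities.
#' @slot B number of randomizations.
#' @slot seed master seed the sample was drawn from.
#' @slot scheme the [RandomizationScheme] used.
#' @slot similarity similarity kind ("cosine", "correlation" or "euclidean").
#' @seealso [sampleNull()]
#' @export
setClass("NullSample",
  representation(
    xiMeans = "numeric",
    sigmaRand = "numeric",
    B = "integer",
    seed = "integer",
    scheme = "RandomizationScheme",
    similarity = "character"
  )
)

setValidity("NullSample", function(object) {
  msg <- character()
  if (object@B < 2L) msg <- c(msg, "B must be >= 2")
  if (length(object@xiMeans) != object@B)
    msg <- c(msg, "xiMeans must have length B")
  if (!all(is.finite(object@xiMeans))) msg <- c(msg, "xiMeans must be finite")
  if (length(object@sigmaRand) != 1L || !is.finite(object@sigmaRand) ||
      object@sigmaRand < 0)
    msg <- c(msg, "sigmaRand must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' VAResult: result of a vector-attribute assortativity test
#'
#' All quantities of the four-step computation: the observed mean edge
#' similarity, the null sample summary, the empirical two-sided test, the
#' standardized mean difference d and the bounded index
#' alpha = d / sqrt(d^2 + epsilon) in (-1, 1).
#'
#' @slot alpha the VA-index, in (-1, 1).
#' @slot d standardized mean difference (observed minus null mean, divided
#'   by the pooled null edge-level similarity standard deviation).
#' @slot xiBarG observed mean edge similarity.
#' @slot mXi mean of the null sample of mean similarities.
#' @slot sigmaRand pooled null edge-level similarity standard deviation.
#' @slot pValue two-sided add-one empirical p-value.
#' @slot ciLow,ciHigh empirical quantile interval of the null sample at the
#'   chosen significance level (type-7 linear interpolation).
#' @slot verdict "positive", "negative" or "random".
#' @slot params list of all run parameters (B, epsilon, sigLevel, similarity,
#'   scheme, seed, Monte-Carlo standard error of the p-value).
#' @seealso [computeVAIndex()]
#' @export
setClass("VAResult",
  representation(
    alpha = "numeric",
    d = "numeric",
    xiBarG = "numeric",
    mXi = "numeric",
    sigmaRand = "numeric",
    pValue = "numeric",
    ciLow = "numeric",
    ciHigh = "numeric",
    verdict = "character",
    params = "list"
  )
)

setValidity("VAResult", function(object) {
  msg <- character()
  if (abs(object@alpha) >= 1) msg <- c(msg, "alpha must lie strictly in (-1, 1)")
  if (!object@verdict %in% c("positive", "negative", "random"))
    msg <- c(msg, "verdict must be positive, negative or random")
  if (sign(object@alpha) != sign(object@d))
    msg <- c(msg, "sign(alpha) must equal sign(d)")
  if (object@pValue <= 0 || object@pValue > 1)
    msg <- c(msg, "pValue must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' SyntheticConfig: parameters of the planted-partition benchmark generator
#'
#' Describes one synthetic study condition: a planted-partition graph
#' (k groups, within/between edge propensities pIn/pOut, exactly targetM
#' edges) whose nodes carry multivariate-normal attributes with group-shifted
#' means and covariance Sigma built from per-dimension variance \code{s},
#' off-diagonal correlation \code{c} and off-diagonal density
#' \code{deltaDensity}.
#'
#' @slot n node count.
#' @slot targetM number of edges (sampled without replacement, exact).
#' @slot q attribute dimension.
#' @slot kGroups number of planted groups (must be <= q).
#' @slot pIn,pOut within/between-group edge propensities in [0, 1].
#' @slot s per-dimension attribute variance (diagonal of Sigma).
#' @slot c correlation placed on the selected off-diagonals of Sigma.
#' @slot deltaDensity fraction of off-diagonal entries of Sigma set nonzero.
#' @slot meanSeparation pairwise distance between group mean vectors, in
#'   units of sqrt(s).
#' @seealso [syntheticConfig()], [generateNetwork()]
#' @export
setClass("SyntheticConfig",
  representation(
    n = "integer", targetM = "integer", q = "integer", kGroups = "integer",
    pIn = "numeric", pOut = "numeric", s = "numeric", c = "numeric",
    deltaDensity = "numeric", meanSeparation = "numeric"
  )
)

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (object@n < 2L) msg <- c(msg, "n must be >= 2")
  if (object@targetM < 1L) msg <- c(msg, "targetM must be >= 1")
  if (object@q < 1L) msg <- c(msg, "q must be >= 1")
  if (object@kGroups < 2L) msg <- c(msg, "kGroups must be >= 2")
  if (object@kGroups > object@q)
    msg <- c(msg, "kGroups must be <= q (group means sit on orthogonal axes)")
  if (object@pIn < 0 || object@pIn > 1 || object@pOut < 0 || object@pOut > 1)
    msg <- c(msg, "pIn and pOut must lie in [0, 1]")
  if (object@s <= 0) msg <- c(msg, "s must be > 0")
  if (abs(object@c) >= 1) msg <- c(msg, "|c| must be < 1")
  if (object@deltaDensity < 0 || object@deltaDensity > 1)
    msg <- c(msg, "deltaDensity must lie in [0, 1]")
  if (object@meanSeparation < 0) msg <- c(msg, "meanSeparation must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param n,targetM,q,kGroups,pIn,pOut,s,c,deltaDensity,meanSeparation see
#'   the slot documentation of [SyntheticConfig-class].
#' @return a validated \code{SyntheticConfig}.
#' @examples
#' syntheticConfig(n = 50, targetM = 100, q = 3, pIn = 0.9, pOut = 0.1)
#' @rdname SyntheticConfig-class
#' @export
syntheticConfig <- function(n = 200, targetM = 800, q = 5, kGroups = 2,
                            pIn = 0.5, pOut = 0.5, s = 1, c = 0,
                            deltaDensity = 0, meanSeparation = 3) {
  new("SyntheticConfig", n = as.integer(n), targetM = as.integer(targetM),
      q = as.integer(q), kGroups = as.integer(kGroups),
      pIn = as.numeric(pIn), pOut = as.numeric(pOut), s = as.numeric(s),
      c = as.numeric(c), deltaDensity = as.numeric(deltaDensity),
      meanSeparation = as.numeric(meanSeparation))
}

#' SyntheticNetwork: a generated attributed network with known ground truth
#'
#' @slot graph the generated [AttributedGraph].
#' @slot labels integer vector of planted group labels (one per node).
#' @slot rTrue ground-truth assortativity: the categorical assortativity of
#'   the planted labels measured on the realized graph.
#' @slot config the [SyntheticConfig] used.
#' @slot seed seed used for generation.
#' @seealso [generateNetwork()]
#' @export
setClass("SyntheticNetwork",
  representation(
    graph = "AttributedGraph",
    labels = "integer",
    rTrue = "numeric",
    config = "SyntheticConfig",
    seed = "integer"
  )
)

setValidity("SyntheticNetwork", function(object) {
  msg <- character()
  if (length(object@labels) != length(object@graph@nodeIds))
    msg <- c(msg, "labels must cover all nodes")
  if (!is.finite(object@rTrue) || abs(object@rTrue) > 1 + 1e-12)
    msg <- c(msg, "rTrue must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})
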