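#' Accessors for AttributedGraph and NullSample objects
#'
#' Standard read-only views of the data containers: node identifiers, the
#' canonical edge matrix, the attribute matrix, counts and the degree
#' sequence; for null samples, the vector of randomized mean similarities and
#' the pooled edge-level similarity dispersion.
#'
#' @param x an [AttributedGraph] or [NullSample].
#' @return \code{nodeIds}: character vector; \code{edgeMatrix}: m x 2 integer
#'   matrix (i < j per row); \code{nodeAttributes}: n x q numeric matrix with
#'   nodeIds as rownames; \code{numNodes}, \code{numEdges}, \code{attrDim}:
#'   single integers; \code{degreeSequence}: named integer vector summing to
#'   2m; \code{xiMeans}: numeric vector of length B; \code{sigmaRand}: single
#'   non-negative number.
#' @examples
#' g <- exampleGraph()
#' numNodes(g); numEdges(g); degreeSequence(g)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' @rdname accessors
#' @export
setGeneric("edgeMatrix", function(x) standardGeneric("edgeMatrix"))

#' @rdname accessors
#' @export
setGeneric("nodeAttributes", function(x) standardGeneric("nodeAttributes"))

#' @rdname accessors
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @rdname accessors
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @rdname accessors
#' @export
setGeneric("attrDim", function(x) standardGeneric("attrDim"))

#' @rdname accessors
#' @export
setGeneric("degreeSequence", function(x) standardGeneric("degreeSequence"))

#' @rdname accessors
#' @export
setGeneric("xiMeans", function(x) standardGeneric("xiMeans"))

#' @rdname accessors
#' @export
setGeneric("sigmaRand", function(x) standardGeneric("sigmaRand"))

#' @rdname accessors
#' @export
setMethod("nodeIds", "AttributedGraph", function(x) x@nodeIds)

#' @rdname accessors
#' @export
setMethod("edgeMatrix", "AttributedGraph", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("nodeAttributes", "AttributedGraph", function(x) x@attributes)

#' @rdname accessors
#' @export
setMethod("numNodes", "AttributedGraph", function(x) length(x@nodeIds))

#' @rdname accessors
#' @export
setMethod("numEdges", "AttributedGraph", function(x) nrow(x@edges))

#' @rdname accessors
#' @export
setMethod("attrDim", "AttributedGraph", function(x) ncol(x@attributes))

#' @rdname accessors
#' @export
setMethod("degreeSequence", "AttributedGraph", function(x) {
  n <- length(x@nodeIds)
  deg <- tabulate(c(x@edges[, 1L], x@edges[, 2L]), nbins = n)
  names(deg) <- x@nodeIds
  deg
})

#' @rdname accessors
#' @export
setMethod("xiMeans", "NullSample", function(x) x@xiMeans)

#' @rdname accessors
#' @export
setMethod("sigmaRand", "NullSample", function(x) x@sigmaRand)

setMethod("show", "AttributedGraph", function(object) {
  cat("AttributedGraph:", length(object@nodeIds), "nodes,",
      nrow(object@edges), "edges, q =", ncol(object@attributes),
      "attribute dimensions\n")
  ids <- object@nodeIds
  cat("  nodes:", paste(utils::head(ids, 5L), collapse = ", "),
      if (length(ids) > 5L) "...\n" else "\n")
})

setMethod("show", "NullSample", function(object) {
  cat("NullSample: B =", object@B, "randomizations (",
      class(object@scheme), ", ", object@similarity, " similarity )\n")
  cat(sprintf("  mean(Xi) = %.6g, sd(Xi) = %.6g, sigma_rand = %.6g\n",
              mean(object@xiMeans), stats::sd(object@xiMeans),
              object@sigmaRand))
})

setMethod("show", "VAResult", function(object) {
  cat("VA-index result\n")
  cat(sprintf("  alpha      = %.4f  (verdict: %s)\n", object@alpha,
              object@verdict))
  cat(sprintf("  d          = %.4f\n", object@d))
  cat(sprintf("  xi_bar_G   = %.6g   null mean = %.6g   sigma_rand = %.6g\n",
              object@xiBarG, object@mXi, object@sigmaRand))
  cat(sprintf("  p-value    = %.4g   null %g%% interval = [%.6g, %.6g]\n",
              object@pValue, 100 * (1 - object@params$sigLevel),
              object@ciLow, object@ciHigh))
  cat(sprintf("  B = %d, epsilon = %g, similarity = %s, seed = %d\n",
              object@params$B, object@params$epsilon,
              object@params$similarity, object@params$seed))
})

setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf(
    "SyntheticConfig: n = %d, m = %d, q = %d, k = %d, pIn/pOut = %g/%g\n",
    object@n, object@targetM, object@q, object@kGroups, object@pIn,
    object@pOut))
  cat(sprintf("  Sigma: s = %g, c = %g, deltaDensity = %g; meanSeparation = %g\n",
              object@s, object@c, object@deltaDensity, object@meanSeparation))
})

setMethod("show", "SyntheticNetwork", function(object) {
  cat("SyntheticNetwork with planted labels (",
      length(unique(object@labels)), "groups ), r_true =",
      round(object@rTrue, 4), "\n")
  show(object@graph)
})

#' Planted group labels of a synthetic network
#' @param x a [SyntheticNetwork].
#' @return integer vector of group labels, one per node.
#' @export
setGeneric("plantedLabels", function(x) standardGeneric("plantedLabels"))

#' @rdname plantedLabels
#' @export
setMethod("plantedLabels", "SyntheticNetwork", function(x) x@labels)

#' Ground-truth assortativity of a synthetic network
#' @param x a [SyntheticNetwork].
#' @return the categorical assortativity of the planted labels on the
#'   realized graph.
#' @export
setGeneric("rTrue", function(x) standardGeneric("rTrue"))

#' @rdname rTrue
#' @export
setMethod("rTrue", "SyntheticNetwork", function(x) x@rTrue)
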