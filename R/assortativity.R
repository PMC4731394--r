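#' Scalar assortativity coefficient
#'
#' The classic assortativity coefficient of a single real-valued node
#' attribute: the normalized covariance of the attribute values at the two
#' ends of an edge,
#' \deqn{r = \frac{\sum_{ij}(A_{ij} - k_i k_j / 2m) x_i x_j}
#'               {\sum_{ij}(k_i \delta_{ij} - k_i k_j / 2m) x_i x_j},}
#' with sums over ordered node pairs and \eqn{\delta_{ij}} the Kronecker
#' delta. It equals the Pearson correlation of the attribute over the 2m
#' ordered edge endpoints, is bounded in [-1, 1] and is invariant to affine
#' transforms of the attribute. Computed by edge iteration in O(m) via the
#' algebraically identical form
#' \code{(2*sum(x_a x_b) - (sum k x)^2/2m) / (sum k x^2 - (sum k x)^2/2m)}.
#'
#' @param graph an [AttributedGraph].
#' @param values one real value per node: a numeric vector of length n (in
#'   node order, or named by node id), or the name/index of an attribute
#'   column. Defaults to the first attribute column.
#' @return the coefficient, in [-1, 1].
#' @examples
#' g <- exampleGraph()
#' scalarAssortativity(g, 1)
#' @export
scalarAssortativity <- function(graph, values = 1L) {
  x <- .resolveValues(graph, values)
  e <- graph@edges
  m <- nrow(e)
  if (m < 1L) stop("assortativity requires at least one edge", call. = FALSE)
  deg <- tabulate(c(e[, 1L], e[, 2L]), nbins = length(x))
  skx <- sum(deg * x)
  num <- 2 * sum(x[e[, 1L]] * x[e[, 2L]]) - skx^2 / (2 * m)
  den <- sum(deg * x^2) - skx^2 / (2 * m)
  if (abs(den) <= 1e-12 * max(1, sum(deg * x^2)))
    stop("assortativity undefined: attribute is constant over edge endpoints",
         call. = FALSE)
  num / den
}

.resolveValues <- function(graph, values) {
  n <- length(graph@nodeIds)
  if (is.character(values) && length(values) == 1L &&
      values %in% colnames(graph@attributes))
    return(graph@attributes[, values])
  if (is.numeric(values) && length(values) == 1L &&
      values == as.integer(values) && values >= 1 &&
      values <= ncol(graph@attributes))
    return(graph@attributes[, as.integer(values)])
  if (length(values) != n)
    stop("values must have one entry per node", call. = FALSE)
  if (!is.null(names(values))) {
    idx <- match(graph@nodeIds, names(values))
    if (anyNA(idx)) stop("values are missing some node ids", call. = FALSE)
    values <- values[idx]
  }
  if (!all(is.finite(values))) stop("values must be finite", call. = FALSE)
  as.numeric(values)
}

#' Categorical (mixing-matrix) assortativity
#'
#' Assortativity of a categorical node label, from the label mixing matrix e
#' over ordered edge endpoints: \code{(sum(diag(e)) - sum(a*b)) / (1 -
#' sum(a*b))} where a, b are the marginals. Equals 1 iff every edge joins
#' same-label nodes; used as the ground truth r_true of the synthetic
#' benchmark (the planted labels on the realized graph).
#'
#' @param graph an [AttributedGraph].
#' @param labels one category per node (factor/character/integer), in node
#'   order or named by node id.
#' @return the coefficient.
#' @export
categoricalAssortativity <- function(graph, labels) {
  n <- length(graph@nodeIds)
  if (length(labels) != n)
    stop("labels must have one entry per node", call. = FALSE)
  if (!is.null(names(labels))) {
    idx <- match(graph@nodeIds, names(labels))
    if (anyNA(idx)) stop("labels are missing some node ids", call. = FALSE)
    labels <- labels[idx]
  }
  labels <- as.factor(labels)
  e <- graph@edges
  la <- labels[e[, 1L]]; lb <- labels[e[, 2L]]
  used <- union(levels(droplevels(la)), levels(droplevels(lb)))
  if (length(used) < 2L)
    stop("assortativity undefined: a single label among edge endpoints",
         call. = FALSE)
  # mixing matrix over ordered endpoints (each edge in both orientations)
  mix <- table(factor(c(as.character(la), as.character(lb)), levels = used),
               factor(c(as.character(lb), as.character(la)), levels = used))
  mix <- mix / sum(mix)
  ab <- sum(rowSums(mix) * colSums(mix))
  (sum(diag(mix)) - ab) / (1 - ab)
}

#' Per-dimension baseline assortativity for vector attributes
#'
#' The baseline the VA-index is compared against: the scalar assortativity
#' coefficient r_i of each of the q attribute dimensions, averaged:
#' \code{r_base = mean(r_1, ..., r_q)}. Columns whose assortativity is
#' undefined (constant over edge endpoints) are skipped with a warning and
#' excluded from the mean.
#'
#' @param graph an [AttributedGraph].
#' @return for \code{baselineVectorAssortativity}: the mean coefficient; for
#'   \code{perDimensionAssortativity}: the vector of per-column coefficients
#'   (NA where undefined).
#' @examples
#' g <- exampleGraph()
#' baselineVectorAssortativity(g)
#' perDimensionAssortativity(g)
#' @rdname baseline
#' @export
baselineVectorAssortativity <- function(graph) {
  ri <- perDimensionAssortativity(graph)
  if (all(is.na(ri)))
    stop("all attribute columns are constant: baseline assortativity undefined",
         call. = FALSE)
  if (anyNA(ri))
    warning(sum(is.na(ri)), " constant attribute column(s) skipped in r_base")
  mean(ri, na.rm = TRUE)
}

#' @rdname baseline
#' @export
perDimensionAssortativity <- function(graph) {
  q <- ncol(graph@attributes)
  vapply(seq_len(q), function(j) {
    tryCatch(scalarAssortativity(graph, graph@attributes[, j]),
             error = function(e) NA_real_)
  }, numeric(1))
}
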