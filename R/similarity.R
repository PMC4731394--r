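#' Pairwise vector similarity measures
#'
#' The three similarity kinds used to score how alike two attribute vectors
#' are on an edge:
#' \describe{
#'   \item{cosine}{\code{dot(x, y) / (||x|| ||y||)}, in [-1, 1]. An all-zero
#'     vector has no direction; its similarity to anything is returned as 0
#'     (the uninformative value) with a warning, so sparse attribute tables
#'     (e.g. empty activity profiles) do not abort a run.}
#'   \item{correlation}{Pearson correlation across the q elements of the two
#'     vectors (one number per node pair), in [-1, 1]; requires q >= 2. A
#'     constant vector is returned as similarity 0 with a warning.}
#'   \item{euclidean}{\code{1 / (1 + ||x - y||_2)}, in (0, 1]: bounded,
#'     monotone decreasing in distance, and free of data-dependent
#'     normalization constants.}
#' }
#'
#' @param x,y numeric vectors of equal length.
#' @param kind one of \code{"cosine"}, \code{"correlation"},
#'   \code{"euclidean"}.
#' @return a single similarity value.
#' @examples
#' cosineSimilarity(c(1, 2), c(2, 1))        # 0.8
#' correlationSimilarity(1:3, 3:1)           # -1
#' euclideanSimilarity(c(0, 0), c(3, 4))     # 1/6
#' pairSimilarity("cosine", c(1, 2), c(2, 1))
#' @name similarity
NULL

.checkPair <- function(x, y, minLen = 1L) {
  if (!is.numeric(x) || !is.numeric(y)) stop("x and y must be numeric", call. = FALSE)
  if (length(x) != length(y))
    stop("vectors must have equal length (", length(x), " vs ", length(y), ")",
         call. = FALSE)
  if (length(x) < minLen)
    stop("vectors must have length >= ", minLen, call. = FALSE)
  invisible(NULL)
}

#' @rdname similarity
#' @export
cosineSimilarity <- function(x, y) {
  .checkPair(x, y, 1L)
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    warning("cosine similarity of an all-zero vector is undefined; returning 0")
    return(0)
  }
  sum(x * y) / (nx * ny)
}

#' @rdname similarity
#' @export
correlationSimilarity <- function(x, y) {
  .checkPair(x, y, 2L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("correlation similarity of a constant vector is undefined; returning 0")
    return(0)
  }
  stats::cor(x, y)
}

#' @rdname similarity
#' @export
euclideanSimilarity <- function(x, y) {
  .checkPair(x, y, 1L)
  1 / (1 + sqrt(sum((x - y)^2)))
}

#' @rdname similarity
#' @export
pairSimilarity <- function(kind, x, y) {
  kind <- .matchSimilarity(kind)
  switch(kind,
    cosine = cosineSimilarity(x, y),
    correlation = correlationSimilarity(x, y),
    euclidean = euclideanSimilarity(x, y)
  )
}

.matchSimilarity <- function(kind) {
  if (identical(kind, "euclidean_inverse")) kind <- "euclidean"
  match.arg(kind, c("cosine", "correlation", "euclidean"))
}

# Precompute per-node transforms so that edge-level similarities over many
# randomized edge sets reduce to row indexing + rowSums. For cosine the rows
# are L2-normalized (zero rows -> 0); for correlation rows are centered and
# scaled by sd*sqrt(q-1) so that rowSums of products IS the Pearson r
# (constant rows -> 0); euclidean keeps the raw matrix.
.simPrep <- function(X, kind) {
  kind <- .matchSimilarity(kind)
  if (kind == "cosine") {
    nrm <- sqrt(rowSums(X^2))
    zero <- nrm == 0
    if (any(zero)) {
      warning(sum(zero), " all-zero attribute vector(s): cosine similarity",
              " involving them is set to 0")
      nrm[zero] <- 1
    }
    list(kind = kind, M = X / nrm)
  } else if (kind == "correlation") {
    q <- ncol(X)
    if (q < 2L) stop("correlation similarity requires q >= 2", call. = FALSE)
    ctr <- X - rowMeans(X)
    ss <- sqrt(rowSums(ctr^2))
    zero <- ss == 0
    if (any(zero)) {
      warning(sum(zero), " constant attribute vector(s): correlation",
              " similarity involving them is set to 0")
      ss[zero] <- 1
    }
    list(kind = kind, M = ctr / ss)
  } else {
    list(kind = kind, M = X)
  }
}

# similarity of each edge (rows of an integer index matrix) under a prep
.edgeSims <- function(prep, idx) {
  a <- idx[, 1L]; b <- idx[, 2L]
  if (prep$kind == "euclidean") {
    d <- sqrt(rowSums((prep$M[a, , drop = FALSE] - prep$M[b, , drop = FALSE])^2))
    unname(1 / (1 + d))
  } else {
    unname(rowSums(prep$M[a, , drop = FALSE] * prep$M[b, , drop = FALSE]))
  }
}
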