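#' Build the attribute covariance matrix of the synthetic generator
#'
#' A q x q symmetric matrix with \code{s} on the diagonal and \code{c * s} on
#' a uniformly chosen fraction \code{deltaDensity} of the q(q-1)/2
#' off-diagonal pairs (the rest 0). If the construction is not positive
#' semi-definite (possible for large \code{c} with high density), a minimal
#' ridge \code{(|lambda_min| + 1e-8 s) I} is added and a message is emitted.
#' Uses the current RNG state to choose the off-diagonal pairs.
#'
#' @param q attribute dimension.
#' @param s diagonal variance (> 0).
#' @param c correlation value placed on the selected off-diagonals (|c| < 1).
#' @param deltaDensity fraction of off-diagonal pairs set nonzero, in [0, 1].
#' @return a q x q covariance matrix.
#' @examples
#' buildSigma(2, s = 2, c = 0.5, deltaDensity = 1)  # [[2,1],[1,2]]
#' @export
buildSigma <- function(q, s, c = 0, deltaDensity = 0) {
  stopifnot(q >= 1, s > 0, abs(c) < 1, deltaDensity >= 0, deltaDensity <= 1)
  Sigma <- diag(s, q)
  nPairs <- q * (q - 1L) / 2L
  k <- round(deltaDensity * nPairs)
  if (k > 0) {
    pairs <- which(upper.tri(Sigma), arr.ind = TRUE)
    sel <- pairs[sample.int(nPairs, k), , drop = FALSE]
    Sigma[sel] <- c * s
    Sigma[sel[, 2:1, drop = FALSE]] <- c * s
    lmin <- min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values)
    if (lmin < 1e-8 * s) {
      ridge <- abs(lmin) + 1e-8 * s
      Sigma <- Sigma + diag(ridge, q)
      message("covariance not positive definite; ridge ", signif(ridge, 3),
              " added to the diagonal")
    }
  }
  Sigma
}

#' Generate a planted-partition attributed network
#'
#' One synthetic study instance: nodes are split evenly into
#' \code{kGroups} latent groups; exactly \code{targetM} distinct edges are
#' drawn without replacement from all node pairs, weighted \code{pIn} for
#' same-group and \code{pOut} for different-group pairs; each node's
#' attribute vector is drawn from a multivariate normal whose mean depends on
#' its group (group means sit on orthogonal coordinate axes, scaled so every
#' pair of means is \code{meanSeparation * sqrt(s)} apart) with covariance
#' from [buildSigma()]. The ground truth \code{rTrue} is the categorical
#' assortativity of the planted labels measured on the realized graph, not a
#' target of the sampler.
#'
#' @param config a [SyntheticConfig].
#' @param seed integer seed; if \code{NULL} one is drawn and reported.
#' @return a [SyntheticNetwork].
#' @examples
#' net <- generateNetwork(syntheticConfig(n = 40, targetM = 80, q = 3,
#'                                        pIn = 0.9, pOut = 0.1), seed = 1)
#' rTrue(net)
#' @export
generateNetwork <- function(config, seed = NULL) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  seed <- .resolveSeed(seed)
  n <- config@n; m <- config@targetM; q <- config@q; k <- config@kGroups
  nPairs <- n * (n - 1) / 2
  if (m > nPairs)
    stop("targetM exceeds the number of distinct node pairs", call. = FALSE)
  withr::with_seed(seed, {
    labels <- sort(rep_len(seq_len(k), n))
    pairs <- which(upper.tri(matrix(FALSE, n, n)), arr.ind = TRUE)
    same <- labels[pairs[, 1L]] == labels[pairs[, 2L]]
    w <- ifelse(same, config@pIn, config@pOut)
    if (sum(w > 0) < m)
      stop("fewer than targetM node pairs have positive edge propensity",
           call. = FALSE)
    sel <- sample.int(nPairs, m, prob = w)
    edges <- pairs[sel, , drop = FALSE]
    edges <- cbind(pmin.int(edges[, 1L], edges[, 2L]),
                   pmax.int(edges[, 1L], edges[, 2L]))
    storage.mode(edges) <- "integer"
    dimnames(edges) <- NULL

    Sigma <- buildSigma(q, config@s, config@c, config@deltaDensity)
    # orthogonal-axis group means: pairwise distance meanSeparation*sqrt(s)
    scale <- config@meanSeparation * sqrt(config@s) / sqrt(2)
    mu <- matrix(0, k, q)
    mu[cbind(seq_len(k), seq_len(k))] <- scale
    X <- matrix(0, n, q)
    for (g in seq_len(k)) {
      rows <- which(labels == g)
      Xg <- MASS::mvrnorm(length(rows), mu = mu[g, ], Sigma = Sigma)
      X[rows, ] <- matrix(Xg, nrow = length(rows))
    }
    ids <- paste0("n", seq_len(n))
    rownames(X) <- ids
    colnames(X) <- paste0("f", seq_len(q))
    graph <- new("AttributedGraph", nodeIds = ids, edges = edges,
                 attributes = X)
  })
  rT <- categoricalAssortativity(graph, labels)
  new("SyntheticNetwork", graph = graph, labels = as.integer(labels),
      rTrue = rT, config = config, seed = seed)
}
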