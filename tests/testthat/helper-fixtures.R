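# Fixture builders shared across tests. All randomness is seeded by callers.

# random simple graph (connected not guaranteed) with iid normal attributes
randomAttributedGraph <- function(n, m, q = 3, seed = NULL) {
  build <- function() {
    pairs <- which(upper.tri(matrix(FALSE, n, n)), arr.ind = TRUE)
    sel <- sample.int(nrow(pairs), m)
    idx <- pairs[sel, , drop = FALSE]
    ids <- paste0("v", seq_len(n))
    edges <- cbind(ids[pmin(idx[, 1], idx[, 2])], ids[pmax(idx[, 1], idx[, 2])])
    X <- matrix(rnorm(n * q), n, q, dimnames = list(ids, paste0("f", seq_len(q))))
    attributedGraph(edges, X, nodeIds = ids)
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

# two disjoint edges 1-2, 3-4: perfectly assortative for x = (1,1,-1,-1)
disjointPairGraph <- function() {
  X <- matrix(c(1, 1, -1, -1), 4, 1, dimnames = list(c("1", "2", "3", "4"), "x"))
  attributedGraph(cbind(c("1", "3"), c("2", "4")), X)
}

# complete bipartite K_{2,2} across two label groups
bipartiteGraph <- function() {
  ids <- c("a1", "a2", "b1", "b2")
  e <- cbind(c("a1", "a1", "a2", "a2"), c("b1", "b2", "b1", "b2"))
  X <- matrix(rnorm(4), 4, 1, dimnames = list(ids, "x"))
  attributedGraph(e, X, nodeIds = ids)
}

# Pearson correlation of a scalar attribute over the 2m ORDERED edge
# endpoints: the textbook definition the O(m) formula must reproduce
endpointCorrelation <- function(graph, x) {
  e <- edgeMatrix(graph)
  stats::cor(x[c(e[, 1], e[, 2])], x[c(e[, 2], e[, 1])])
}

# star K_{1,k}: admits no valid double-edge swap
starGraph <- function(k = 4) {
  ids <- c("hub", paste0("leaf", seq_len(k)))
  e <- cbind(rep("hub", k), paste0("leaf", seq_len(k)))
  X <- matrix(seq_len(k + 1), k + 1, 1, dimnames = list(ids, "x"))
  attributedGraph(e, X, nodeIds = ids)
}

cycleGraph <- function(k = 6) {
  ids <- paste0("c", seq_len(k))
  e <- cbind(ids, ids[c(2:k, 1)])
  X <- matrix(rnorm(k), k, 1, dimnames = list(ids, "x"))
  attributedGraph(e, X, nodeIds = ids)
}
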