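#' Read an undirected edge list from a delimited file
#'
#' Reads a two-column (source, target) edge list. Self-loops are dropped and
#' duplicate undirected edges collapsed, with a message reporting the counts.
#' Node order is first-appearance order (scanning each row source-then-target).
#'
#' @param path path to a TSV/CSV file (or a connection).
#' @param delimiter field delimiter; by default inferred from the file
#'   extension (".csv" = comma, otherwise tab).
#' @param hasHeader logical; is the first row a header? Default \code{FALSE}.
#' @return a list with \code{edges} (character matrix, one undirected edge
#'   per row), \code{nodeIds} (character, first-appearance order),
#'   \code{selfLoopsDropped} and \code{duplicatesCollapsed} counts.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("a\tb", "b\ta", "c\tc", "a\tc"), f)
#' el <- readEdgeList(f)
#' el$edges
#' @export
readEdgeList <- function(path, delimiter = NULL, hasHeader = FALSE) {
  if (is.null(delimiter)) {
    delimiter <- if (is.character(path) && grepl("\\.csv$", path, ignore.case = TRUE))
      "," else "\t"
  }
  raw <- tryCatch(
    utils::read.table(path, sep = delimiter, header = hasHeader,
                      colClasses = "character", comment.char = "",
                      quote = "\"", fill = FALSE,
                      blank.lines.skip = TRUE, strip.white = TRUE),
    error = function(e) stop("malformed edge list: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (ncol(raw) < 2L)
    stop("each edge-list row must have at least 2 columns", call. = FALSE)
  src <- raw[[1L]]
  tgt <- raw[[2L]]
  bad <- which(!nzchar(src) | !nzchar(tgt))
  if (length(bad))
    stop("malformed edge list: empty node id on data row ", bad[1L],
         call. = FALSE)
  nodeIds <- unique(as.vector(rbind(src, tgt)))
  loops <- src == tgt
  nLoops <- sum(loops)
  src <- src[!loops]; tgt <- tgt[!loops]
  key <- ifelse(src < tgt, paste(src, tgt, sep = "\r"),
                paste(tgt, src, sep = "\r"))
  dup <- duplicated(key)
  nDup <- sum(dup)
  src <- src[!dup]; tgt <- tgt[!dup]
  if (length(src) == 0L)
    stop("no edges remain after removing self-loops and duplicates",
         call. = FALSE)
  if (nLoops > 0L || nDup > 0L)
    message(nLoops, " self-loop(s) dropped, ", nDup,
            " duplicate edge(s) collapsed")
  list(edges = cbind(source = src, target = tgt), nodeIds = nodeIds,
       selfLoopsDropped = nLoops, duplicatesCollapsed = nDup)
}

#' Read a node attribute table
#'
#' Reads a delimited table with a header row: one id column plus q >= 1
#' numeric attribute columns. No imputation is performed; missing or
#' non-numeric cells and duplicated ids are errors.
#'
#' @param path path to a CSV/TSV file with a header row.
#' @param idColumn name or index of the node-id column (default 1).
#' @param delimiter field delimiter; inferred from the extension by default.
#' @return numeric matrix with node ids as rownames and the attribute columns
#'   (q = number of non-id columns).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("id,f1,f2", "a,1,0", "b,0,1"), f)
#' readAttributes(f)
#' @export
readAttributes <- function(path, idColumn = 1L, delimiter = NULL) {
  if (is.null(delimiter)) {
    delimiter <- if (is.character(path) && grepl("\\.tsv$|\\.txt$", path,
                                                 ignore.case = TRUE))
      "\t" else ","
  }
  raw <- utils::read.table(path, sep = delimiter, header = TRUE,
                           colClasses = "character", comment.char = "",
                           quote = "\"", check.names = FALSE)
  if (is.character(idColumn)) {
    idColumn <- match(idColumn, colnames(raw))
    if (is.na(idColumn)) stop("id column not found in header", call. = FALSE)
  }
  ids <- raw[[idColumn]]
  if (anyDuplicated(ids))
    stop("duplicate node id(s) in attribute table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  vals <- raw[, -idColumn, drop = FALSE]
  if (ncol(vals) < 1L)
    stop("attribute table needs at least one numeric column besides the id",
         call. = FALSE)
  mat <- suppressWarnings(vapply(vals, as.numeric, numeric(nrow(raw))))
  if (nrow(raw) == 1L) mat <- matrix(mat, nrow = 1L, dimnames = list(NULL, colnames(vals)))
  if (anyNA(mat)) {
    badCol <- colnames(vals)[which(colSums(is.na(mat)) > 0)][1L]
    stop("missing or non-numeric value in attribute column '", badCol, "'",
         call. = FALSE)
  }
  rownames(mat) <- ids
  mat
}

#' Write an edge list / attribute table (round-trip safe)
#'
#' Plain-text writers matching [readEdgeList()] and [readAttributes()], used
#' for exporting randomized or synthetic networks.
#'
#' @param graph an [AttributedGraph].
#' @param path output file path; extension selects the delimiter as in the
#'   readers.
#' @return the path, invisibly.
#' @rdname writers
#' @export
writeEdgeList <- function(graph, path) {
  delimiter <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  e <- graph@edges
  df <- data.frame(source = graph@nodeIds[e[, 1L]],
                   target = graph@nodeIds[e[, 2L]])
  utils::write.table(df, path, sep = delimiter, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writers
#' @export
writeAttributes <- function(graph, path) {
  delimiter <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  a <- graph@attributes
  cn <- colnames(a)
  if (is.null(cn)) cn <- paste0("f", seq_len(ncol(a)))
  df <- data.frame(id = rownames(a), a, check.names = FALSE)
  colnames(df) <- c("id", cn)
  utils::write.table(df, path, sep = delimiter, row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Assemble an AttributedGraph from edges and an attribute table
#'
#' Validating constructor. Attribute-only nodes (present in the table but not
#' in the graph) are dropped with a warning; graph nodes without an attribute
#' row are an error.
#'
#' @param edges a 2-column character matrix/data.frame of undirected edges
#'   (node ids), or the list returned by [readEdgeList()].
#' @param attributes numeric matrix with node ids as rownames, as returned by
#'   [readAttributes()].
#' @param nodeIds optional character vector fixing the node order; defaults
#'   to first-appearance order in \code{edges}, then any attribute-only nodes
#'   are dropped.
#' @return a validated [AttributedGraph].
#' @examples
#' e <- cbind(c("a", "a"), c("b", "c"))
#' x <- matrix(rnorm(6), 3, 2, dimnames = list(c("a", "b", "c"), NULL))
#' attributedGraph(e, x)
#' @export
attributedGraph <- function(edges, attributes, nodeIds = NULL) {
  if (is.list(edges) && !is.data.frame(edges) && !is.null(edges$edges)) {
    if (is.null(nodeIds)) nodeIds <- edges$nodeIds
    edges <- edges$edges
  }
  edges <- as.matrix(edges)
  storage.mode(edges) <- "character"
  if (ncol(edges) != 2L) stop("edges must have two columns", call. = FALSE)
  if (is.null(nodeIds))
    nodeIds <- unique(as.vector(t(edges)))
  missingAttr <- setdiff(nodeIds, rownames(attributes))
  if (length(missingAttr))
    stop("graph node(s) without attributes: ",
         paste(missingAttr, collapse = ", "), call. = FALSE)
  extra <- setdiff(rownames(attributes), nodeIds)
  if (length(extra)) {
    warning(length(extra),
            " node(s) present only in the attribute table were dropped: ",
            paste(utils::head(extra, 5L), collapse = ", "),
            if (length(extra) > 5L) ", ..." else "")
  }
  attr <- attributes[nodeIds, , drop = FALSE]
  storage.mode(attr) <- "double"
  idx <- cbind(match(edges[, 1L], nodeIds), match(edges[, 2L], nodeIds))
  if (anyNA(idx))
    stop("edge endpoint not among node ids", call. = FALSE)
  idx <- .canonicalEdges(idx)
  new("AttributedGraph", nodeIds = nodeIds, edges = idx, attributes = attr)
}

# canonical (i < j, deduplicated, self-loop-free) integer edge matrix
.canonicalEdges <- function(idx) {
  idx <- cbind(pmin.int(idx[, 1L], idx[, 2L]), pmax.int(idx[, 1L], idx[, 2L]))
  idx <- idx[idx[, 1L] != idx[, 2L], , drop = FALSE]
  if (nrow(idx)) {
    key <- idx[, 1L] + (max(idx) + 1) * as.double(idx[, 2L])
    idx <- idx[!duplicated(key), , drop = FALSE]
  }
  storage.mode(idx) <- "integer"
  dimnames(idx) <- NULL
  idx
}

# AttributedGraph with the same nodes/attributes but a new integer edge matrix
.replaceEdges <- function(graph, idx) {
  new("AttributedGraph", nodeIds = graph@nodeIds, edges = idx,
      attributes = graph@attributes)
}

#' Read an attributed graph from GraphML
#'
#' Optional convenience reader: imports a GraphML file via igraph and maps
#' its numeric vertex attributes to attribute columns by name. The edge list
#' + CSV pair is the canonical interface.
#'
#' @param path path to a GraphML file.
#' @param attributeNames which vertex attributes to use as columns; by
#'   default all numeric vertex attributes (in GraphML key order).
#' @return an [AttributedGraph].
#' @export
readGraphML <- function(path, attributeNames = NULL) {
  g <- igraph::read_graph(path, format = "graphml")
  g <- igraph::as_undirected(g, mode = "collapse")
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  ids <- igraph::vertex_attr(g, "name")
  if (is.null(ids)) ids <- as.character(seq_len(igraph::vcount(g)))
  if (is.null(attributeNames)) {
    attributeNames <- setdiff(igraph::vertex_attr_names(g), "name")
    isNum <- vapply(attributeNames,
                    function(a) is.numeric(igraph::vertex_attr(g, a)), logical(1))
    attributeNames <- attributeNames[isNum]
  }
  if (length(attributeNames) == 0L)
    stop("GraphML file has no numeric vertex attributes", call. = FALSE)
  attr <- vapply(attributeNames, function(a) as.numeric(igraph::vertex_attr(g, a)),
                 numeric(length(ids)))
  attr <- matrix(attr, nrow = length(ids),
                 dimnames = list(ids, attributeNames))
  idx <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(idx) <- "integer"
  new("AttributedGraph", nodeIds = ids, edges = .canonicalEdges(idx),
      attributes = attr)
}

#' A small packaged example graph
#'
#' Six nodes in two attribute "camps" with mostly within-camp edges; used in
#' examples and smoke tests.
#'
#' @return an [AttributedGraph] with n = 6, m = 7, q = 2.
#' @examples
#' exampleGraph()
#' @export
exampleGraph <- function() {
  edgesFile <- system.file("extdata", "toy_edges.tsv", package = "vamix")
  attrsFile <- system.file("extdata", "toy_attrs.csv", package = "vamix")
  attributedGraph(readEdgeList(edgesFile), readAttributes(attrsFile))
}
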