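#' @import methods
#' @importFrom stats cor cov kmeans rnorm runif sd
#' @importFrom utils read.table write.table combn
NULL

#' TimeSeriesMatrix: regional BOLD time series for one subject
#'
#' Rows are time points, columns are brain regions. Pearson correlation
#' between columns defines the subject's functional connectivity, so at
#' least three time points are required and no region may be constant.
#'
#' @slot values numeric matrix, T time points x n regions.
#' @slot regionNames character vector of n region labels.
#' @export
setClass("TimeSeriesMatrix",
  representation(values = "matrix", regionNames = "character"),
  validity = function(object) {
    v <- object@values
    if (!is.numeric(v)) return("values must be a numeric matrix")
    if (nrow(v) < 3L)
      return("at least 3 time points are required for Pearson correlation")
    if (ncol(v) != length(object@regionNames))
      return("regionNames length must equal the number of columns")
    sds <- apply(v, 2L, sd)
    if (any(sds == 0)) {
      bad <- object@regionNames[sds == 0]
      return(paste0("zero-variance region(s): ", paste(bad, collapse = ", ")))
    }
    TRUE
  })

#' WeightedNetwork: symmetric connectivity matrix with region labels
#'
#' The full (dense) functional connectivity network of one subject. The
#' diagonal carries no information and is stored as zero; all downstream
#' operations ignore it.
#'
#' @slot weights symmetric numeric n x n matrix, zero diagonal.
#' @slot regionNames character vector of n region labels.
#' @export
setClass("WeightedNetwork",
  representation(weights = "matrix", regionNames = "character"),
  validity = function(object) {
    w <- object@weights
    if (nrow(w) != ncol(w)) return("weights must be square")
    if (length(object@regionNames) != nrow(w))
      return("regionNames length must equal matrix dimension")
    if (!isTRUE(all.equal(w, t(w), tolerance = 1e-10, check.attributes = FALSE)))
      return("weights must be symmetric")
    if (any(diag(w) != 0)) return("diagonal must be stored as 0")
    TRUE
  })

#' TreeNetwork: loopless connected spanning subgraph
#'
#' A spanning tree over n nodes: exactly n - 1 edges, connected, acyclic.
#' Edges are stored as a 2-column integer matrix of node indices
#' (smaller index first) together with the weight each edge carried in
#' the originating network; the 0/1 adjacency matrix is kept consistent.
#'
#' @slot nodes character vector of n node labels.
#' @slot edges integer matrix, (n-1) x 2, node indices with edges[,1] < edges[,2].
#' @slot edgeWeights numeric vector of length n-1 (weights in the source network).
#' @slot adjacency binary symmetric n x n matrix.
#' @export
setClass("TreeNetwork",
  representation(nodes = "character", edges = "matrix",
                 edgeWeights = "numeric", adjacency = "matrix"),
  validity = function(object) {
    n <- length(object@nodes)
    e <- object@edges
    if (nrow(e) != n - 1L) return(sprintf("a tree on %d nodes needs %d edges, got %d",
                                          n, n - 1L, nrow(e)))
    if (ncol(e) != 2L) return("edges must have two columns")
    if (length(object@edgeWeights) != nrow(e))
      return("edgeWeights length must match the edge count")
    a <- object@adjacency
    if (!all(dim(a) == c(n, n))) return("adjacency dimension mismatch")
    if (!all(a %in% c(0, 1))) return("adjacency must be 0/1")
    if (!identical(unname(a), unname(t(a)))) return("adjacency must be symmetric")
    a2 <- matrix(0L, n, n)
    a2[e] <- 1L; a2[e[, c(2L, 1L), drop = FALSE]] <- 1L
    if (!all(a == a2)) return("adjacency inconsistent with edge set")
    if (!.isConnected(a)) return("tree must be connected")
    # connected + (n-1) edges implies acyclic, but check explicitly
    if (sum(a) / 2 != n - 1L) return("edge count in adjacency differs from n-1")
    TRUE
  })

#' SimilarityMatrix: pairwise network similarities for a cohort
#'
#' Symmetric N x N matrix with unit diagonal and entries in [0, 1]
#' (similarity 0 = nothing shared, 1 = same network).
#'
#' @slot values symmetric numeric matrix with unit diagonal, entries in [0, 1].
#' @slot subjectIds character vector of N subject identifiers.
#' @export
setClass("SimilarityMatrix",
  representation(values = "matrix", subjectIds = "character"),
  validity = function(object) {
    v <- object@values
    if (nrow(v) != ncol(v)) return("values must be square")
    if (length(object@subjectIds) != nrow(v))
      return("subjectIds length must equal matrix dimension")
    if (!isTRUE(all.equal(v, t(v), tolerance = 1e-8, check.attributes = FALSE)))
      return("values must be symmetric")
    if (any(abs(diag(v) - 1) > 1e-8)) return("diagonal must be 1")
    if (any(v < -1e-10) || any(v > 1 + 1e-8))
      return("entries must lie in [0, 1]")
    TRUE
  })

#' ClusteringResult: cluster labels and optional consistency score
#'
#' @slot labels integer vector of cluster indices in 0..m-1.
#' @slot m integer, number of clusters.
#' @slot consistency numeric in [0, 1], or NA when no classes were supplied.
#' @slot delta,h,d the similarity parameters used (NA when not applicable).
#' @slot subjectIds character vector parallel to labels.
#' @export
setClass("ClusteringResult",
  representation(labels = "integer", m = "integer", consistency = "numeric",
                 delta = "numeric", h = "numeric", d = "numeric",
                 subjectIds = "character"),
  validity = function(object) {
    if (any(object@labels < 0L | object@labels >= object@m))
      return("labels must lie in [0, m)")
    if (length(object@subjectIds) != length(object@labels))
      return("subjectIds length must match labels")
    cons <- object@consistency
    if (!is.na(cons) && (cons < 0 || cons > 1))
      return("consistency must lie in [0, 1]")
    TRUE
  })

setMethod("show", "TimeSeriesMatrix", function(object) {
  cat(sprintf("TimeSeriesMatrix: %d time points x %d regions\n",
              nrow(object@values), ncol(object@values)))
})

setMethod("show", "WeightedNetwork", function(object) {
  w <- object@weights
  off <- w[upper.tri(w)]
  cat(sprintf("WeightedNetwork: %d nodes; off-diagonal weights in [%.3f, %.3f]\n",
              nrow(w), min(off), max(off)))
})

setMethod("show", "TreeNetwork", function(object) {
  n <- length(object@nodes)
  cat(sprintf("TreeNetwork: %d nodes, %d edges (spanning tree)\n", n, n - 1L))
})

setMethod("show", "SimilarityMatrix", function(object) {
  v <- object@values
  off <- if (nrow(v) > 1L) v[upper.tri(v)] else numeric(0)
  cat(sprintf("SimilarityMatrix: %d subjects", nrow(v)))
  if (length(off)) cat(sprintf("; off-diagonal range [%.4f, %.4f]", min(off), max(off)))
  cat("\n")
})

setMethod("show", "ClusteringResult", function(object) {
  cat(sprintf("ClusteringResult: %d subjects in %d clusters", length(object@labels), object@m))
  if (!is.na(object@consistency))
    cat(sprintf("; consistency %.4f", object@consistency))
  cat("\n")
})

# ---- constructors -----------------------------------------------------------

#' Create a TimeSeriesMatrix
#'
#' @param values numeric matrix, time points in rows, regions in columns.
#' @param regionNames optional region labels; defaults to `R001..Rnnn`.
#' @return A [TimeSeriesMatrix-class] object.
#' @export
TimeSeriesMatrix <- function(values, regionNames = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(regionNames)) {
    regionNames <- colnames(values)
    if (is.null(regionNames)) regionNames <- defaultRegionNames(ncol(values))
  }
  new("TimeSeriesMatrix", values = values, regionNames = as.character(regionNames))
}

#' Create a WeightedNetwork
#'
#' The diagonal is zeroed on construction; small asymmetries are not
#' repaired and cause rejection.
#'
#' @param weights symmetric numeric matrix.
#' @param regionNames optional node labels; defaults to `R001..Rnnn`.
#' @return A [WeightedNetwork-class] object.
#' @export
WeightedNetwork <- function(weights, regionNames = NULL) {
  weights <- as.matrix(weights)
  storage.mode(weights) <- "double"
  diag(weights) <- 0
  if (is.null(regionNames)) {
    regionNames <- colnames(weights)
    if (is.null(regionNames)) regionNames <- defaultRegionNames(ncol(weights))
  }
  new("WeightedNetwork", weights = weights, regionNames = as.character(regionNames))
}

#' Create a TreeNetwork from an edge list
#'
#' @param nodes character vector of node labels.
#' @param edges 2-column matrix of node indices (1-based) or of node labels.
#' @param edgeWeights optional numeric edge weights (default 1).
#' @return A [TreeNetwork-class] object.
#' @export
TreeNetwork <- function(nodes, edges, edgeWeights = NULL) {
  nodes <- as.character(nodes)
  n <- length(nodes)
  edges <- as.matrix(edges)
  if (is.character(edges)) {
    idx <- matrix(match(edges, nodes), ncol = 2L)
    if (anyNA(idx)) stop("edge refers to a node label not in `nodes`")
    edges <- idx
  }
  storage.mode(edges) <- "integer"
  # canonical order: smaller index first, rows sorted
  edges <- t(apply(edges, 1L, sort))
  dimnames(edges) <- NULL
  if (is.null(edgeWeights)) edgeWeights <- rep(1, nrow(edges))
  ord <- order(edges[, 1L], edges[, 2L])
  edges <- edges[ord, , drop = FALSE]
  edgeWeights <- as.numeric(edgeWeights)[ord]
  adj <- matrix(0L, n, n)
  adj[edges] <- 1L
  adj[edges[, c(2L, 1L), drop = FALSE]] <- 1L
  new("TreeNetwork", nodes = nodes, edges = edges,
      edgeWeights = edgeWeights, adjacency = adj)
}

# ---- accessors --------------------------------------------------------------

#' @describeIn TreeNetwork-class number of nodes
#' @param x object
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))
setMethod("nNodes", "TreeNetwork", function(x) length(x@nodes))
setMethod("nNodes", "WeightedNetwork", function(x) nrow(x@weights))
setMethod("nNodes", "TimeSeriesMatrix", function(x) ncol(x@values))

#' Extract the adjacency matrix of a tree network
#' @param x a TreeNetwork
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))
setMethod("adjacency", "TreeNetwork", function(x) x@adjacency)

#' Extract the weight matrix of a weighted network
#' @param x a WeightedNetwork
#' @export
setGeneric("connectivity", function(x) standardGeneric("connectivity"))
setMethod("connectivity", "WeightedNetwork", function(x) {
  w <- x@weights
  dimnames(w) <- list(x@regionNames, x@regionNames)
  w
})

#' Edge list of a tree network
#' @param x a TreeNetwork
#' @return data.frame with columns node_a, node_b, weight.
#' @export
setGeneric("treeEdges", function(x) standardGeneric("treeEdges"))
setMethod("treeEdges", "TreeNetwork", function(x) {
  data.frame(node_a = x@nodes[x@edges[, 1L]],
             node_b = x@nodes[x@edges[, 2L]],
             weight = x@edgeWeights,
             stringsAsFactors = FALSE)
})

#' Similarity values as a plain matrix
#' @param x a SimilarityMatrix
#' @export
setGeneric("simValues", function(x) standardGeneric("simValues"))
setMethod("simValues", "SimilarityMatrix", function(x) {
  v <- x@values
  dimnames(v) <- list(x@subjectIds, x@subjectIds)
  v
})

#' Subject identifiers
#' @param x a SimilarityMatrix or ClusteringResult
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))
setMethod("subjectIds", "SimilarityMatrix", function(x) x@subjectIds)
setMethod("subjectIds", "ClusteringResult", function(x) x@subjectIds)

#' Cluster labels of a clustering result
#' @param x a ClusteringResult
#' @return integer vector of 0-based cluster indices, named by subject.
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
setMethod("clusterLabels", "ClusteringResult", function(x) {
  stats::setNames(x@labels, x@subjectIds)
})

#' Consistency score of a clustering result
#' @param x a ClusteringResult
#' @export
setGeneric("consistency", function(x) standardGeneric("consistency"))
setMethod("consistency", "ClusteringResult", function(x) x@consistency)

# ---- internal helpers -------------------------------------------------------

defaultRegionNames <- function(n) sprintf("R%03d", seq_len(n))

# connectivity of a 0/1 adjacency matrix by BFS from node 1
.isConnected <- function(adj) {
  n <- nrow(adj)
  if (n == 0L) return(FALSE)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- which(adj[v, ] != 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}
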