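#' Pearson correlation network from regional time series
#'
#' Computes the full functional connectivity network of one subject:
#' every pair of regions is connected with their Pearson correlation as
#' edge weight. The diagonal is stored as zero and ignored downstream.
#'
#' @param ts a [TimeSeriesMatrix-class] (or a plain numeric matrix,
#'   time points in rows, regions in columns).
#' @return A [WeightedNetwork-class] with weights in \[-1, 1\].
#' @examples
#' set.seed(1)
#' ts <- TimeSeriesMatrix(matrix(rnorm(200), 20, 10))
#' net <- correlationNetwork(ts)
#' @export
correlationNetwork <- function(ts) {
  if (!is(ts, "TimeSeriesMatrix")) ts <- TimeSeriesMatrix(ts)
  validObject(ts)  # enforces T >= 3 and nonzero variance
  w <- cor(ts@values)
  diag(w) <- 0
  # clamp rounding excursions outside [-1, 1]
  w[w > 1] <- 1; w[w < -1] <- -1
  w <- (w + t(w)) / 2
  WeightedNetwork(w, ts@regionNames)
}

#' Maximum-weight spanning tree by descending-order Kruskal
#'
#' Reduces a full connectivity network to its spanning-tree backbone:
#' off-diagonal weights are sorted in descending order and edges are
#' linked greedily, skipping any edge that would close a loop, until all
#' nodes are connected (n - 1 edges). This keeps the strongest
#' connections without any threshold choice. Equal weights are processed
#' in lexicographic order of (smaller node index, larger node index);
#' negative weights carry no special treatment and simply sort last. An
#' exactly zero weight encodes an absent edge (the edge-list reader's
#' convention), so sparse inputs can be genuinely disconnected.
#'
#' @param net a [WeightedNetwork-class].
#' @return A [TreeNetwork-class]; `edgeWeights` holds the correlation
#'   weight of each retained edge.
#' @examples
#' w <- matrix(c(0, .9, .2, .9, 0, .5, .2, .5, 0), 3, 3)
#' tr <- buildSpanningTree(WeightedNetwork(w))
#' treeEdges(tr)
#' @export
buildSpanningTree <- function(net) {
  stopifnot(is(net, "WeightedNetwork"))
  w <- net@weights
  n <- nrow(w)
  if (n < 2L) stop("a spanning tree needs at least 2 nodes")
  ij <- which(upper.tri(w), arr.ind = TRUE)
  dimnames(ij) <- NULL
  wt <- w[ij]
  # an exactly zero weight encodes an absent edge (edge-list convention)
  ij <- ij[wt != 0, , drop = FALSE]
  wt <- wt[wt != 0]
  # descending weight; ties by (smaller index, larger index)
  ord <- order(-wt, ij[, 1L], ij[, 2L])
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  keep <- integer(0)
  for (k in ord) {
    ru <- find(ij[k, 1L]); rv <- find(ij[k, 2L])
    if (ru != rv) {
      parent[ru] <- rv
      keep <- c(keep, k)
      if (length(keep) == n - 1L) break
    }
  }
  if (length(keep) < n - 1L) {
    comp <- vapply(seq_len(n), find, integer(1))
    sizes <- table(comp)
    stop(sprintf("input graph is disconnected: %d components (sizes %s)",
                 length(sizes), paste(sizes, collapse = ", ")))
  }
  TreeNetwork(net@regionNames, ij[keep, , drop = FALSE], wt[keep])
}

#' Default-mode-network atlas preset (32 bilateral AAL regions)
#'
#' The bundled node set used to label spanning-tree brain networks: 16
#' AAL structures of the default mode network, left/right, giving 32
#' node labels (e.g. `PCG.L`, `PCG.R`). Labels only; no coordinates.
#'
#' @return Character vector of 32 region labels.
#' @examples
#' length(dmnRegions())
#' @export
dmnRegions <- function() {
  path <- system.file("extdata", "dmn_aal32.txt", package = "mstClust",
                      mustWork = TRUE)
  readLines(path)
}

#' Reduce a cohort of subject inputs to spanning-tree networks
#'
#' Convenience wrapper used by the command-line interface: time-series
#' subjects go through [correlationNetwork()] first, connectivity-matrix
#' subjects are tree-reduced directly with [buildSpanningTree()].
#'
#' @param objs named list of [TimeSeriesMatrix-class] or
#'   [WeightedNetwork-class] objects (as from [readSubjectInputs()]).
#' @return Named list of [TreeNetwork-class] objects.
#' @export
asTreeCohort <- function(objs) {
  lapply(objs, function(o) {
    if (is(o, "TimeSeriesMatrix")) o <- correlationNetwork(o)
    buildSpanningTree(o)
  })
}
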