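#' Normalized node betweenness
#'
#' For each node i, the fraction of ordered pairs (h, j) of *other*
#' nodes whose shortest path(s) pass through i:
#' \deqn{b_i = \frac{1}{(n-1)(n-2)} \sum_{h \ne j,\; h,j \ne i}
#'       \rho_{hj}^{(i)} / \rho_{hj}}
#' where \eqn{\rho_{hj}} counts shortest paths from h to j and
#' \eqn{\rho_{hj}^{(i)}} those passing through i. On a tree every pair
#' has a unique path, so \eqn{\rho_{hj} = 1}; the path-count denominator
#' is kept so the same computation is valid on general graphs. The
#' ordered-pair normalization puts the center of a star at exactly 1 and
#' every leaf at 0.
#'
#' @param tree a [TreeNetwork-class], or any 0/1 symmetric adjacency
#'   matrix of a connected graph with n >= 3 nodes.
#' @return Numeric vector of per-node betweenness in \[0, 1\], named by node.
#' @examples
#' star <- TreeNetwork(letters[1:5], cbind(1, 2:5))
#' nodeBetweenness(star)  # center 1, leaves 0
#' @export
nodeBetweenness <- function(tree) {
  if (is(tree, "TreeNetwork")) {
    adj <- tree@adjacency
    labels <- tree@nodes
  } else {
    adj <- as.matrix(tree)
    labels <- rownames(adj)
    if (is.null(labels)) labels <- defaultRegionNames(nrow(adj))
  }
  n <- nrow(adj)
  if (n < 3L) stop("betweenness requires n >= 3 (normalization (n-1)(n-2) is zero)")
  sp <- .shortestPathCounts(adj)
  dist <- sp$dist; sigma <- sp$sigma
  if (any(!is.finite(dist))) stop("graph must be connected")
  b <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (h in seq_len(n)) {
      if (h == i) next
      for (j in seq_len(n)) {
        if (j == i || j == h) next
        # shortest paths h->j through i: counts multiply when i sits on
        # a shortest path (distance additivity)
        if (dist[h, i] + dist[i, j] == dist[h, j]) {
          acc <- acc + (sigma[h, i] * sigma[i, j]) / sigma[h, j]
        }
      }
    }
    b[i] <- acc / ((n - 1) * (n - 2))
  }
  stats::setNames(b, labels)
}

# BFS from every source: hop distances and shortest-path counts sigma.
.shortestPathCounts <- function(adj) {
  n <- nrow(adj)
  dist <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  nbrs <- lapply(seq_len(n), function(v) which(adj[v, ] != 0))
  for (s in seq_len(n)) {
    dist[s, s] <- 0
    sigma[s, s] <- 1
    frontier <- s
    dcur <- 0
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        for (u in nbrs[[v]]) {
          if (!is.finite(dist[s, u])) {
            dist[s, u] <- dcur + 1
            nxt <- c(nxt, u)
            sigma[s, u] <- sigma[s, u] + sigma[s, v]
          } else if (dist[s, u] == dcur + 1) {
            sigma[s, u] <- sigma[s, u] + sigma[s, v]
          }
        }
      }
      frontier <- unique(nxt)
      dcur <- dcur + 1
    }
  }
  list(dist = dist, sigma = sigma)
}

#' Cosine attribute similarity between two betweenness vectors
#'
#' \deqn{s_{att}(G,H) = \frac{\sum_m b_m(G) b_m(H)}
#'   {\sqrt{\sum_m b_m(G)^2}\sqrt{\sum_m b_m(H)^2}}}
#' Since betweenness is nonnegative the value lies in \[0, 1\], with 1
#' for identical (or proportional) attribute profiles.
#'
#' @param bG,bH numeric vectors of equal length, neither all zero.
#' @return Scalar cosine similarity in \[0, 1\].
#' @export
attributeSimilarity <- function(bG, bH) {
  if (length(bG) != length(bH)) stop("betweenness vectors must have equal length")
  nG <- sqrt(sum(bG^2)); nH <- sqrt(sum(bH^2))
  if (nG == 0 || nH == 0)
    stop("cosine similarity undefined for an all-zero betweenness vector")
  s <- sum(bG * bH) / (nG * nH)
  min(max(s, 0), 1)
}

#' Attribute similarity matrix for a cohort of tree networks
#'
#' Pairwise cosine similarity of node-betweenness vectors for every pair
#' of subjects. All networks must share the node count and node order.
#'
#' @param trees list of [TreeNetwork-class] objects.
#' @param subjectIds optional character vector of subject identifiers
#'   (defaults to names of `trees` or `S001..`).
#' @return A [SimilarityMatrix-class] (unit diagonal, symmetric).
#' @export
attributeSimilarityMatrix <- function(trees, subjectIds = NULL) {
  subjectIds <- .cohortIds(trees, subjectIds)
  .checkSameNodes(trees, subjectIds)
  B <- vapply(trees, nodeBetweenness, numeric(nNodes(trees[[1L]])))
  N <- length(trees)
  S <- diag(1, N)
  if (N > 1L) {
    for (g in seq_len(N - 1L)) {
      for (h in seq((g + 1L), N)) {
        S[g, h] <- S[h, g] <- attributeSimilarity(B[, g], B[, h])
      }
    }
  }
  new("SimilarityMatrix", values = S, subjectIds = subjectIds)
}

.cohortIds <- function(objs, subjectIds) {
  if (is.null(subjectIds)) subjectIds <- names(objs)
  if (is.null(subjectIds)) subjectIds <- sprintf("S%03d", seq_along(objs))
  as.character(subjectIds)
}

.checkSameNodes <- function(trees, subjectIds) {
  ref <- trees[[1L]]@nodes
  ok <- vapply(trees, function(t) identical(t@nodes, ref), logical(1))
  if (!all(ok))
    stop("node sets differ across subjects: ",
         paste(subjectIds[!ok], collapse = ", "))
  invisible(TRUE)
}
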