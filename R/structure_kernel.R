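#' Nested hop-distance sub-networks around a node
#'
#' For radii j = 1..h, the induced subgraph on all nodes within hop
#' distance j of the anchor node. Node sets are nested and, once j
#' reaches the tree diameter, equal the whole node set. These multi-level
#' neighborhoods are what the sub-network kernel compares node by node.
#'
#' @param tree a [TreeNetwork-class].
#' @param nodeIndex integer anchor node (1-based).
#' @param h maximum radius, h >= 1.
#' @param weighted if TRUE the subgraph adjacency carries the tree's
#'   edge weights instead of 0/1 entries.
#' @return List of h elements, each `list(nodes = <indices>, adjacency = <matrix>)`.
#' @export
extractSubnetworks <- function(tree, nodeIndex, h, weighted = FALSE) {
  stopifnot(is(tree, "TreeNetwork"))
  if (h < 1L) stop("h must be >= 1")
  n <- nNodes(tree)
  if (nodeIndex < 1L || nodeIndex > n) stop("nodeIndex out of range")
  adj <- tree@adjacency
  dists <- .bfsDistances(adj, nodeIndex)
  wadj <- if (weighted) .weightedAdjacency(tree) else adj
  lapply(seq_len(h), function(j) {
    members <- which(dists <= j)
    list(nodes = members,
         adjacency = wadj[members, members, drop = FALSE])
  })
}

.bfsDistances <- function(adj, source) {
  n <- nrow(adj)
  dist <- rep(Inf, n)
  dist[source] <- 0
  frontier <- source
  dcur <- 0
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      nb <- which(adj[v, ] != 0 & !is.finite(dist))
      dist[nb] <- dcur + 1
      nxt <- c(nxt, nb)
    }
    frontier <- unique(nxt)
    dcur <- dcur + 1
  }
  dist
}

.weightedAdjacency <- function(tree) {
  n <- nNodes(tree)
  w <- matrix(0, n, n)
  w[tree@edges] <- tree@edgeWeights
  w[tree@edges[, c(2L, 1L), drop = FALSE]] <- tree@edgeWeights
  w
}

#' Krylov covariance descriptor of a sub-network
#'
#' Summarizes a (sub-)network's connectivity profile by the covariance
#' structure of normalized power iterations: with W the adjacency
#' matrix, e the all-ones vector and N the node count, the vectors
#' \deqn{u_i = N \, W^i e / \lVert W^i e \rVert_1,\quad i = 1..d}
#' span the d-order Krylov subspace; the descriptor is the d x d sample
#' covariance matrix of (u_1, ..., u_d) over node positions, plus
#' `ridge` on the diagonal so that log-determinants exist even for
#' regular subgraphs (whose power vectors are constant).
#'
#' @param adjacency square symmetric matrix (binary or weighted), >= 2 nodes.
#' @param d number of power iterations, >= 1.
#' @param ridge nonnegative diagonal regularization (default 1e-6).
#' @return d x d symmetric positive-definite matrix (for ridge > 0).
#' @examples
#' krylovCovariance(matrix(c(0, 1, 1, 0), 2, 2), d = 2)  # = ridge * I
#' @export
krylovCovariance <- function(adjacency, d, ridge = 1e-6) {
  W <- as.matrix(adjacency)
  nsub <- nrow(W)
  if (nsub != ncol(W) || nsub < 2L) stop("adjacency must be square with >= 2 nodes")
  if (d < 1L) stop("d must be >= 1")
  if (ridge < 0) stop("ridge must be >= 0")
  U <- matrix(0, nsub, d)
  v <- rep(1, nsub)
  for (i in seq_len(d)) {
    v <- as.vector(W %*% v)
    l1 <- sum(abs(v))
    if (l1 == 0) stop("power iterate has zero l1 norm (empty adjacency?)")
    U[, i] <- nsub * v / l1
  }
  C <- cov(U)               # sample covariance, denominator nsub - 1
  C <- (C + t(C)) / 2
  C + diag(ridge, d)
}

#' Log-det similarity between two covariance descriptors
#'
#' Compares two sub-network descriptors through their log-determinants:
#' with A = (C_G + C_H) / 2,
#' \deqn{g = \exp\left(-\tfrac{1}{2}\,(\log|A| - \log|C_G| - \log|C_H|)\right)}
#' (variant `"as_printed"`, the default). The variant `"s_divergence"`
#' replaces the exponent by the S-divergence
#' \eqn{\log|A| - \tfrac12\log|C_G| - \tfrac12\log|C_H|}, which is zero
#' for identical descriptors so self-similarity is exactly 1 before any
#' normalization. Log-determinants come from a Cholesky factorization; a
#' factorization failure is treated as a non-positive-definite input.
#'
#' @param cG,cH symmetric positive-definite matrices of equal size.
#' @param variant `"as_printed"` or `"s_divergence"`.
#' @return Positive scalar, symmetric in its arguments.
#' @export
pairSimilarity <- function(cG, cH, variant = c("as_printed", "s_divergence")) {
  variant <- match.arg(variant)
  if (!all(dim(cG) == dim(cH))) stop("descriptors must have the same dimension d")
  ldG <- .logDet(cG); ldH <- .logDet(cH)
  ldA <- .logDet((cG + cH) / 2)
  expo <- if (variant == "as_printed") ldA - ldG - ldH else ldA - 0.5 * ldG - 0.5 * ldH
  exp(-0.5 * expo)
}

.logDet <- function(M) {
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch))
    stop("covariance descriptor is not positive definite; increase `ridge`")
  2 * sum(log(diag(ch)))
}

#' Sub-network kernel between two tree networks
#'
#' The structure similarity of two networks sharing a node set: for each
#' node i and radius j = 1..h, compare the Krylov covariance descriptors
#' of the two networks' radius-j sub-networks around i with
#' [pairSimilarity()], average over radii (per-node similarity f), then
#' average over nodes:
#' \deqn{k(G,H) = \frac{1}{n}\sum_i \frac{1}{h}\sum_{j=1}^h g(G_i^j, H_i^j)}
#'
#' @param treeG,treeH [TreeNetwork-class] objects with identical node order.
#' @param h maximum sub-network radius (>= 1).
#' @param d number of power iterations (>= 1).
#' @param ridge diagonal regularization for the descriptors.
#' @param variant see [pairSimilarity()].
#' @param weighted use weighted subgraph adjacency (default binary).
#' @return Positive scalar; symmetric in G and H.
#' @export
subnetworkKernel <- function(treeG, treeH, h, d, ridge = 1e-6,
                             variant = c("as_printed", "s_divergence"),
                             weighted = FALSE) {
  variant <- match.arg(variant)
  if (!identical(treeG@nodes, treeH@nodes))
    stop("networks must share the same node set and order")
  dG <- .treeDescriptors(treeG, h, d, ridge, weighted)
  dH <- .treeDescriptors(treeH, h, d, ridge, weighted)
  .kernelFromDescriptors(dG, dH, variant)
}

# per-node, per-radius descriptors and cached log-determinants
.treeDescriptors <- function(tree, h, d, ridge, weighted = FALSE) {
  n <- nNodes(tree)
  lapply(seq_len(n), function(i) {
    subs <- extractSubnetworks(tree, i, h, weighted)
    lapply(subs, function(s) {
      C <- krylovCovariance(s$adjacency, d, ridge)
      list(C = C, logdet = .logDet(C))
    })
  })
}

.kernelFromDescriptors <- function(dG, dH, variant) {
  n <- length(dG)
  h <- length(dG[[1L]])
  total <- 0
  for (i in seq_len(n)) {
    fi <- 0
    for (j in seq_len(h)) {
      a <- dG[[i]][[j]]; b <- dH[[i]][[j]]
      ldA <- .logDet((a$C + b$C) / 2)
      expo <- if (variant == "as_printed") ldA - a$logdet - b$logdet
              else ldA - 0.5 * a$logdet - 0.5 * b$logdet
      fi <- fi + exp(-0.5 * expo)
    }
    total <- total + fi / h
  }
  total / n
}

#' Normalize a raw similarity matrix to unit diagonal
#'
#' Cosine-style normalization
#' \deqn{s_{norm}(X,Y) = s(X,Y) / \sqrt{s(X,X)\, s(Y,Y)}}
#' applied entry-wise; the raw structure-kernel matrix becomes a proper
#' similarity matrix with unit self-similarity. A matrix that already
#' has unit diagonal is unchanged.
#'
#' @param raw square numeric matrix (or [SimilarityMatrix-class]) with
#'   strictly positive diagonal.
#' @param subjectIds subject identifiers (taken from `raw` when it is a
#'   SimilarityMatrix or has dimnames).
#' @return A [SimilarityMatrix-class].
#' @export
normalizeSimilarity <- function(raw, subjectIds = NULL) {
  if (is(raw, "SimilarityMatrix")) {
    subjectIds <- raw@subjectIds
    raw <- raw@values
  }
  raw <- as.matrix(raw)
  if (is.null(subjectIds)) {
    subjectIds <- rownames(raw)
    if (is.null(subjectIds)) subjectIds <- sprintf("S%03d", seq_len(nrow(raw)))
  }
  dg <- diag(raw)
  if (any(dg <= 0))
    stop("nonpositive self-similarity for subject(s): ",
         paste(subjectIds[dg <= 0], collapse = ", "))
  sc <- 1 / sqrt(dg)
  v <- raw * tcrossprod(sc)
  v <- (v + t(v)) / 2
  diag(v) <- 1
  v <- pmin(pmax(v, 0), 1)  # clip floating-point excursions
  new("SimilarityMatrix", values = unname(v), subjectIds = subjectIds)
}

#' Structure similarity matrix for a cohort of tree networks
#'
#' All pairwise sub-network kernel values, normalized to unit diagonal
#' with [normalizeSimilarity()]. Descriptors are computed once per
#' subject and reused across pairs.
#'
#' @inheritParams subnetworkKernel
#' @param trees list of [TreeNetwork-class] objects with a common node set.
#' @param subjectIds optional subject identifiers.
#' @return A [SimilarityMatrix-class] with entries in (0, 1\].
#' @export
structureSimilarityMatrix <- function(trees, h, d, ridge = 1e-6,
                                      variant = c("as_printed", "s_divergence"),
                                      weighted = FALSE, subjectIds = NULL) {
  variant <- match.arg(variant)
  subjectIds <- .cohortIds(trees, subjectIds)
  .checkSameNodes(trees, subjectIds)
  desc <- lapply(trees, .treeDescriptors, h = h, d = d, ridge = ridge,
                 weighted = weighted)
  N <- length(trees)
  raw <- matrix(0, N, N)
  for (g in seq_len(N)) {
    for (hh in g:N) {
      raw[g, hh] <- raw[hh, g] <- .kernelFromDescriptors(desc[[g]], desc[[hh]], variant)
    }
  }
  normalizeSimilarity(raw, subjectIds)
}
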