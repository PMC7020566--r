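# Independent brute-force oracles used across the suite. These are
# deliberately naive (explicit loops, base det(), igraph for distances)
# and share no code with the package internals they check.

# random tree by uniform random attachment, labels shuffled
randomTree <- function(n, labels = sprintf("R%03d", seq_len(n))) {
  perm <- sample.int(n)
  edges <- cbind(perm[vapply(2:n, function(v) sample.int(v - 1L, 1L), integer(1))],
                 perm[2:n])
  TreeNetwork(labels, edges)
}

# Pearson correlation of two vectors from the definition
oraclePearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# unique h->j path in a tree via parent pointers from BFS
.treePath <- function(adj, from, to) {
  n <- nrow(adj)
  parent <- rep(NA_integer_, n)
  seen <- logical(n); seen[from] <- TRUE
  queue <- from
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (u in which(adj[v, ] != 0)) if (!seen[u]) {
      seen[u] <- TRUE; parent[u] <- v; queue <- c(queue, u)
    }
  }
  path <- to
  while (path[1L] != from) path <- c(parent[path[1L]], path)
  path
}

# normalized betweenness by exhaustive enumeration of all ordered pairs
# and their unique tree paths
oracleTreeBetweenness <- function(tree) {
  adj <- adjacency(tree)
  n <- nrow(adj)
  b <- numeric(n)
  for (h in seq_len(n)) for (j in seq_len(n)) {
    if (h == j) next
    interior <- setdiff(.treePath(adj, h, j), c(h, j))
    b[interior] <- b[interior] + 1
  }
  b / ((n - 1) * (n - 2))
}

# exhaustive maximum-weight spanning tree: try every (n-1)-subset of edges
oracleMaxSpanningTree <- function(w) {
  n <- nrow(w)
  ij <- which(upper.tri(w), arr.ind = TRUE)
  best <- NULL; bestW <- -Inf
  for (sel in asplit(combn(nrow(ij), n - 1L), 2L)) {
    adj <- matrix(0L, n, n)
    adj[ij[sel, , drop = FALSE]] <- 1L
    adj <- adj + t(adj)
    # connected + n-1 edges  <=>  spanning tree
    reach <- (diag(n) + adj)
    for (k in seq_len(n)) reach <- sign(reach %*% reach)
    if (all(reach > 0)) {
      tw <- sum(w[ij[sel, , drop = FALSE]])
      if (tw > bestW) { bestW <- tw; best <- ij[sel, , drop = FALSE] }
    }
  }
  best[order(best[, 1L], best[, 2L]), , drop = FALSE]
}

# naive sub-network kernel: explicit per-node, per-radius loops, igraph
# distances, explicit power iterations, hand-computed covariances and
# base-R determinants
oracleSubnetworkKernel <- function(treeG, treeH, h, d, ridge = 1e-6,
                                   variant = "as_printed") {
  descr <- function(tree, i, j) {
    g <- igraph::graph_from_adjacency_matrix(adjacency(tree), mode = "undirected")
    dist <- as.vector(igraph::distances(g, v = i))
    members <- which(dist <= j)
    W <- adjacency(tree)[members, members, drop = FALSE]
    ns <- length(members)
    U <- matrix(0, ns, d)
    v <- rep(1, ns)
    for (p in seq_len(d)) {
      v <- as.vector(W %*% v)
      U[, p] <- ns * v / sum(abs(v))
    }
    Uc <- sweep(U, 2L, colMeans(U))
    C <- crossprod(Uc) / (ns - 1)
    C + diag(ridge, d)
  }
  n <- nrow(adjacency(treeG))
  total <- 0
  for (i in seq_len(n)) {
    fi <- 0
    for (j in seq_len(h)) {
      cG <- descr(treeG, i, j); cH <- descr(treeH, i, j)
      A <- (cG + cH) / 2
      expo <- if (variant == "as_printed") log(det(A)) - log(det(cG)) - log(det(cH))
              else log(det(A)) - 0.5 * log(det(cG)) - 0.5 * log(det(cH))
      fi <- fi + exp(-0.5 * expo)
    }
    total <- total + fi / h
  }
  total / n
}

.allPerms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in .allPerms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

# brute-force consistency: maximum matched count over every one-to-one
# pairing of clusters with classes
oracleConsistency <- function(labels, classes) {
  tab <- table(factor(labels), factor(classes))
  k1 <- nrow(tab); k2 <- ncol(tab)
  best <- 0
  if (k1 <= k2) {
    for (p in .allPerms(seq_len(k2)))
      best <- max(best, sum(tab[cbind(seq_len(k1), p[seq_len(k1)])]))
  } else {
    for (p in .allPerms(seq_len(k1)))
      best <- max(best, sum(tab[cbind(p[seq_len(k2)], seq_len(k2))]))
  }
  best / length(labels)
}

# random symmetric positive-definite matrix
randomPD <- function(d) {
  A <- matrix(rnorm(d * d), d, d)
  crossprod(A) + diag(0.1, d)
}
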