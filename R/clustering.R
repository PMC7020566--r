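#' Fuse attribute and structure similarity
#'
#' Convex combination of the two (already normalized) similarity
#' matrices: \eqn{s = \delta\, s_{att} + (1-\delta)\, s_{str}}. The
#' weight delta trades off the node-attribute view (betweenness
#' profiles) against the topological view (sub-network kernel); delta = 1
#' and delta = 0 recover the attribute-only and kernel-only methods.
#'
#' @param sAtt,sStr [SimilarityMatrix-class] objects with identical
#'   subject order and unit diagonal.
#' @param delta fusion weight in \[0, 1\].
#' @return A [SimilarityMatrix-class].
#' @export
fuseSimilarities <- function(sAtt, sStr, delta) {
  stopifnot(is(sAtt, "SimilarityMatrix"), is(sStr, "SimilarityMatrix"))
  if (delta < 0 || delta > 1) stop("delta must lie in [0, 1]")
  if (!identical(sAtt@subjectIds, sStr@subjectIds) ||
      !all(dim(sAtt@values) == dim(sStr@values)))
    stop("similarity matrices must share shape and subject order")
  v <- delta * sAtt@values + (1 - delta) * sStr@values
  diag(v) <- 1
  new("SimilarityMatrix", values = v, subjectIds = sAtt@subjectIds)
}

#' Normalized spectral clustering of a similarity matrix
#'
#' Ng-Jordan-Weiss style clustering: with D the diagonal of row sums,
#' form \eqn{L = D^{-1/2} S D^{-1/2}}, take the eigenvectors of the m
#' largest eigenvalues as columns of X, renormalize each row of X to
#' unit length and run k-means (50 restarts, fixed seed) on the rows.
#' Eigenvalues are sorted in decreasing order; each eigenvector's sign
#' is fixed so its first nonzero component is positive, making the
#' embedding reproducible. A row of X that is exactly zero is left
#' unnormalized (with a warning) rather than divided by zero.
#'
#' @param S a [SimilarityMatrix-class] (all row sums must be positive).
#' @param m number of clusters, 2 <= m <= N.
#' @param seed integer seed controlling the k-means restarts.
#' @return A [ClusteringResult-class] with labels in 0..m-1.
#' @export
spectralCluster <- function(S, m = 2L, seed = 1L) {
  stopifnot(is(S, "SimilarityMatrix"))
  V <- S@values
  N <- nrow(V)
  if (m < 2L || m > N) stop("m must satisfy 2 <= m <= N")
  rs <- rowSums(V)
  if (any(rs <= 0))
    stop("zero (or negative) row sum for subject(s): ",
         paste(S@subjectIds[rs <= 0], collapse = ", "))
  dscale <- 1 / sqrt(rs)
  L <- V * tcrossprod(dscale)
  eig <- eigen(L, symmetric = TRUE)
  X <- eig$vectors[, seq_len(m), drop = FALSE]
  # deterministic sign: first nonzero component positive
  for (k in seq_len(m)) {
    nz <- which(abs(X[, k]) > 1e-12)
    if (length(nz) && X[nz[1L], k] < 0) X[, k] <- -X[, k]
  }
  rn <- sqrt(rowSums(X^2))
  zero <- rn < .Machine$double.eps
  if (any(zero)) {
    warning(sum(zero), " all-zero embedding row(s) left unnormalized")
    rn[zero] <- 1
  }
  Y <- X / rn
  set.seed(seed)
  km <- kmeans(Y, centers = m, nstart = 50L, iter.max = 300L)
  new("ClusteringResult",
      labels = as.integer(km$cluster - 1L), m = as.integer(m),
      consistency = NA_real_, delta = NA_real_, h = NA_real_, d = NA_real_,
      subjectIds = S@subjectIds)
}

#' Clustering consistency against diagnostic classes
#'
#' The best achievable agreement between cluster labels and class
#' labels under a one-to-one cluster-to-class assignment:
#' \deqn{\mathrm{consistency} = \frac{1}{n}\max \sum T(C_m, L_p)}
#' where \eqn{T(C_m, L_p)} counts subjects in cluster m belonging to
#' class p, and the maximum runs over non-overlapping cluster/class
#' pairings (solved exhaustively over assignments). For two clusters
#' this is \eqn{\max(T_{11}+T_{22},\; T_{12}+T_{21})/n}.
#'
#' @param labels integer (or factor) cluster labels.
#' @param classes integer (or factor) diagnostic classes, same length.
#' @return Scalar in \[0, 1\]; invariant to relabeling either vector.
#' @export
clusteringConsistency <- function(labels, classes) {
  if (is(labels, "ClusteringResult")) labels <- labels@labels
  if (length(labels) != length(classes))
    stop("labels and classes must have equal length")
  n <- length(labels)
  if (n < 1L) stop("empty label vector")
  tab <- table(factor(labels), factor(classes))
  k1 <- nrow(tab); k2 <- ncol(tab)
  # assign the smaller side injectively into the larger
  if (k1 <= k2) {
    best <- max(vapply(.injections(k2, k1), function(p)
      sum(tab[cbind(seq_len(k1), p)]), numeric(1)))
  } else {
    best <- max(vapply(.injections(k1, k2), function(p)
      sum(tab[cbind(p, seq_len(k2))]), numeric(1)))
  }
  best / n
}

# all injective maps 1..k -> 1..m (k <= m), as a list of index vectors
.injections <- function(m, k) {
  if (k == 0L) return(list(integer(0)))
  out <- list()
  rec <- function(prefix, remaining) {
    if (length(prefix) == k) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (v in remaining) rec(c(prefix, v), setdiff(remaining, v))
  }
  rec(integer(0), seq_len(m))
  out
}

#' End-to-end clustering of a tree-network cohort
#'
#' Runs the full similarity pipeline at fixed parameters: betweenness
#' cosine attribute similarity, sub-network kernel structure similarity,
#' delta-weighted fusion, and normalized spectral clustering. When
#' diagnostic classes are supplied the clustering consistency is filled
#' in on the result.
#'
#' @param trees list of [TreeNetwork-class] objects (common node set).
#' @param classes optional integer vector of diagnostic classes.
#' @param delta fusion weight in \[0, 1\] (default 0.5).
#' @param h sub-network radius (default 2).
#' @param d power-iteration count (default 3).
#' @param ridge descriptor regularization (default 1e-6).
#' @param m number of clusters (default 2).
#' @param seed k-means seed.
#' @param variant kernel variant, see [pairSimilarity()].
#' @param subjectIds optional subject identifiers.
#' @return A [ClusteringResult-class].
#' @export
clusterCohort <- function(trees, classes = NULL, delta = 0.5, h = 2L, d = 3L,
                          ridge = 1e-6, m = 2L, seed = 1L,
                          variant = c("as_printed", "s_divergence"),
                          subjectIds = NULL) {
  variant <- match.arg(variant)
  subjectIds <- .cohortIds(trees, subjectIds)
  sAtt <- attributeSimilarityMatrix(trees, subjectIds)
  sStr <- structureSimilarityMatrix(trees, h = h, d = d, ridge = ridge,
                                    variant = variant, subjectIds = subjectIds)
  S <- fuseSimilarities(sAtt, sStr, delta)
  res <- spectralCluster(S, m = m, seed = seed)
  cons <- if (is.null(classes)) NA_real_ else clusteringConsistency(res@labels, classes)
  initialize(res, consistency = cons, delta = as.numeric(delta),
             h = as.numeric(h), d = as.numeric(d))
}

#' Supervised evaluation sweep over delta, h and d
#'
#' Grid search of the fusion weight delta and the kernel parameters h
#' and d, scoring each grid point by clustering consistency against the
#' supplied diagnostic classes. Because the score uses the diagnostic
#' labels, this is a supervised evaluation protocol (model exploration),
#' not an unsupervised analysis; single-parameter [clusterCohort()] is
#' the primary unsupervised mode.
#'
#' @param trees list of [TreeNetwork-class] objects.
#' @param classes integer vector of diagnostic classes (required).
#' @param deltaGrid,hGrid,dGrid non-empty numeric grids; defaults are
#'   delta in 0.1..0.9 (step 0.1), h in 1..3, d in 3..8.
#' @param ridge,m,seed,variant as in [clusterCohort()].
#' @param subjectIds optional subject identifiers.
#' @return List with `table` (data.frame of delta, h, d, consistency,
#'   one row per grid point) and `best` (the first row attaining the
#'   maximum consistency).
#' @export
parameterSweep <- function(trees, classes,
                           deltaGrid = seq(0.1, 0.9, by = 0.1),
                           hGrid = 1:3, dGrid = 3:8,
                           ridge = 1e-6, m = 2L, seed = 1L,
                           variant = c("as_printed", "s_divergence"),
                           subjectIds = NULL) {
  variant <- match.arg(variant)
  if (is.null(classes)) stop("classes are required for the evaluation sweep")
  if (!length(deltaGrid) || !length(hGrid) || !length(dGrid))
    stop("all parameter grids must be non-empty")
  subjectIds <- .cohortIds(trees, subjectIds)
  sAtt <- attributeSimilarityMatrix(trees, subjectIds)
  rows <- vector("list", length(deltaGrid) * length(hGrid) * length(dGrid))
  r <- 0L
  for (h in hGrid) {
    for (d in dGrid) {
      sStr <- structureSimilarityMatrix(trees, h = h, d = d, ridge = ridge,
                                        variant = variant, subjectIds = subjectIds)
      for (delta in deltaGrid) {
        S <- fuseSimilarities(sAtt, sStr, delta)
        res <- spectralCluster(S, m = m, seed = seed)
        cons <- clusteringConsistency(res@labels, classes)
        r <- r + 1L
        rows[[r]] <- data.frame(delta = delta, h = h, d = d, consistency = cons)
      }
    }
  }
  tab <- do.call(rbind, rows)
  list(table = tab, best = tab[which.max(tab$consistency), , drop = FALSE])
}
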