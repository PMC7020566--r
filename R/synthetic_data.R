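#' Specification of a synthetic cohort with planted group structure
#'
#' Defines a cohort of subjects split into groups whose tree-network
#' templates differ by hub placement and dispersion. `effect` scales how
#' far the group templates diverge (0 = identical templates, 1 =
#' maximal: a dominant-hub star versus a fully dispersed path);
#' `noise` is the per-edge probability that a subject's copy of its
#' template has that edge relocated elsewhere (expected fraction of
#' rewired edges).
#'
#' @slot nNodes integer >= 4, nodes per network.
#' @slot nPerGroup integer >= 2, subjects per group.
#' @slot nGroups integer >= 1.
#' @slot effect numeric in \[0, 1\], topological divergence between templates.
#' @slot noise numeric >= 0, within-group edge-relocation rate.
#' @slot seed integer seed; same spec + seed gives an identical cohort.
#' @slot mode `"tree"` or `"timeseries"`.
#' @export
setClass("CohortSpec",
  representation(nNodes = "integer", nPerGroup = "integer", nGroups = "integer",
                 effect = "numeric", noise = "numeric", seed = "integer",
                 mode = "character"),
  validity = function(object) {
    if (object@nNodes < 4L) return("nNodes must be >= 4")
    if (object@nPerGroup < 2L) return("nPerGroup must be >= 2")
    if (object@nGroups < 1L) return("nGroups must be >= 1")
    if (object@effect < 0 || object@effect > 1) return("effect must lie in [0, 1]")
    if (object@noise < 0 || object@noise > 1) return("noise must lie in [0, 1]")
    if (!object@mode %in% c("tree", "timeseries"))
      return("mode must be 'tree' or 'timeseries'")
    TRUE
  })

#' Create a CohortSpec
#'
#' Defaults mirror a two-group resting-state study at desk scale: 32
#' network nodes (the bundled DMN preset size) and 20 subjects per group.
#'
#' @param nNodes,nPerGroup,nGroups,effect,noise,seed,mode see
#'   [CohortSpec-class].
#' @return A [CohortSpec-class] object.
#' @export
cohortSpec <- function(nNodes = 32L, nPerGroup = 20L, nGroups = 2L,
                       effect = 0.8, noise = 0.05, seed = 1L, mode = "tree") {
  new("CohortSpec", nNodes = as.integer(nNodes), nPerGroup = as.integer(nPerGroup),
      nGroups = as.integer(nGroups), effect = as.numeric(effect),
      noise = as.numeric(noise), seed = as.integer(seed), mode = as.character(mode))
}

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf("CohortSpec: %d groups x %d subjects, %d nodes, effect %.2f, noise %.2f, mode %s\n",
              object@nGroups, object@nPerGroup, object@nNodes,
              object@effect, object@noise, object@mode))
})

# Template tree for group g: a dominant-hub star whose first r hub edges
# are relocated into a chain, so larger r means a more dispersed
# (path-like) topology. r grows linearly from 0 (group 0) to
# round(effect * (n-1)) (last group).
.groupTemplate <- function(n, group, nGroups, effect) {
  rmax <- round(effect * (n - 1))
  r <- if (nGroups > 1L) round(group / (nGroups - 1) * rmax) else 0L
  r <- min(r, n - 2L)  # keep at least one star edge to anchor the chain
  if (r == 0L) {
    edges <- cbind(1L, 2:n)
  } else {
    chain <- 2:(r + 1L)                      # relocated nodes, chained
    starLeaves <- (r + 2L):n                 # still attached to the hub
    edges <- rbind(cbind(1L, starLeaves),
                   cbind(n, chain[1L]),      # chain hangs off the last leaf
                   if (r > 1L) cbind(chain[-r], chain[-1L]))
  }
  TreeNetwork(defaultRegionNames(n), edges)
}

# Relocate one tree edge: remove it, then reconnect the two components
# with a uniformly chosen cross pair different from the removed edge.
.relocateEdge <- function(edges, n, which, maxTry = 50L) {
  u <- edges[which, 1L]; v <- edges[which, 2L]
  adj <- matrix(0L, n, n)
  e2 <- edges[-which, , drop = FALSE]
  adj[e2] <- 1L; adj[e2[, c(2L, 1L), drop = FALSE]] <- 1L
  compU <- which(is.finite(.bfsDistances(adj, u)))
  compV <- setdiff(seq_len(n), compU)
  for (k in seq_len(maxTry)) {
    a <- compU[sample.int(length(compU), 1L)]
    b <- compV[sample.int(length(compV), 1L)]
    if (!(min(a, b) == min(u, v) && max(a, b) == max(u, v))) {
      edges[which, ] <- c(min(a, b), max(a, b))
      return(edges)
    }
  }
  stop("edge relocation failed after ", maxTry, " attempts")
}

#' Generate a cohort of tree networks with planted group topology
#'
#' One template tree per group (see [CohortSpec-class]); each subject is
#' its group template with every edge independently relocated with
#' probability `noise` (the relocation reconnects the two components at
#' a random cross pair, so the result is always a spanning tree).
#' Betweenness profiles and sub-network descriptors are both sensitive
#' to the planted hub/dispersion contrast, so the cohort exercises the
#' full attribute + structure pipeline.
#'
#' @param spec a [CohortSpec-class] with `mode = "tree"`.
#' @return List with `trees` (list of [TreeNetwork-class]), `classes`
#'   (integer group index per subject, 0-based), and `subjectIds`.
#' @examples
#' coh <- plantedTreeCohort(cohortSpec(nNodes = 8, nPerGroup = 3, seed = 42))
#' table(coh$classes)
#' @export
plantedTreeCohort <- function(spec) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  if (spec@mode != "tree") stop("spec mode must be 'tree'")
  set.seed(spec@seed)
  n <- spec@nNodes
  templates <- lapply(seq_len(spec@nGroups) - 1L, .groupTemplate,
                      n = n, nGroups = spec@nGroups, effect = spec@effect)
  trees <- list(); classes <- integer(0); ids <- character(0)
  for (g in seq_len(spec@nGroups) - 1L) {
    tmplEdges <- templates[[g + 1L]]@edges
    for (s in seq_len(spec@nPerGroup)) {
      edges <- tmplEdges
      hit <- which(runif(nrow(edges)) < spec@noise)
      for (k in hit) edges <- .relocateEdge(edges, n, k)
      trees[[length(trees) + 1L]] <- TreeNetwork(defaultRegionNames(n), edges)
      classes <- c(classes, g)
      ids <- c(ids, sprintf("G%d_S%02d", g, s))
    }
  }
  names(trees) <- ids
  list(trees = trees, classes = classes, subjectIds = ids)
}

#' Generate a cohort of regional time series with planted correlation
#'
#' Per group, a target correlation matrix whose strongest entries trace
#' the group's template tree: node signals follow a Gaussian tree-Markov
#' process in which each edge carries correlation `edgeCor`, so the
#' correlation between two regions is `edgeCor` to the power of their
#' hop distance and the maximum-weight spanning tree of the exact
#' correlation matrix is the template itself. Subjects draw `tsLength`
#' time points from a zero-mean multivariate normal with that
#' correlation and receive independent observation noise (`obsNoise`
#' standard deviations) as subject-level jitter. A target matrix that
#' fails positive definiteness is repaired by eigenvalue clipping with
#' a warning.
#'
#' @param spec a [CohortSpec-class] with `mode = "timeseries"`.
#' @param tsLength time points per subject (default `5 * nNodes`).
#' @param edgeCor correlation carried by each template edge (default 0.7).
#' @param obsNoise observation-noise standard deviation (default 0.1).
#' @return List with `series` (list of [TimeSeriesMatrix-class]),
#'   `classes`, and `subjectIds`.
#' @export
plantedTimeseriesCohort <- function(spec, tsLength = 5L * spec@nNodes,
                                    edgeCor = 0.7, obsNoise = 0.1) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  if (spec@mode != "timeseries") stop("spec mode must be 'timeseries'")
  if (tsLength < 3L) stop("tsLength must be >= 3")
  set.seed(spec@seed)
  n <- spec@nNodes
  targets <- lapply(seq_len(spec@nGroups) - 1L, function(g) {
    tmpl <- .groupTemplate(n, g, spec@nGroups, spec@effect)
    D <- vapply(seq_len(n), function(v) .bfsDistances(tmpl@adjacency, v),
                numeric(n))
    .makePositiveDefinite(edgeCor^D)
  })
  series <- list(); classes <- integer(0); ids <- character(0)
  for (g in seq_len(spec@nGroups) - 1L) {
    Sg <- targets[[g + 1L]]
    for (s in seq_len(spec@nPerGroup)) {
      x <- MASS::mvrnorm(tsLength, mu = rep(0, n), Sigma = Sg)
      x <- x + matrix(rnorm(tsLength * n, sd = obsNoise), tsLength, n)
      series[[length(series) + 1L]] <- TimeSeriesMatrix(x, defaultRegionNames(n))
      classes <- c(classes, g)
      ids <- c(ids, sprintf("G%d_S%02d", g, s))
    }
  }
  names(series) <- ids
  list(series = series, classes = classes, subjectIds = ids)
}

.makePositiveDefinite <- function(M, floorEig = 1e-8) {
  eig <- eigen(M, symmetric = TRUE)
  if (min(eig$values) > floorEig) return(M)
  warning("target correlation not positive definite; clipping eigenvalues")
  v <- pmax(eig$values, floorEig)
  M2 <- eig$vectors %*% (v * t(eig$vectors))
  # restore unit diagonal after clipping
  s <- 1 / sqrt(diag(M2))
  M2 * tcrossprod(s)
}
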