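.simMat <- function(v, ids = sprintf("S%03d", seq_len(nrow(v)))) {
  new("SimilarityMatrix", values = v, subjectIds = ids)
}

test_that("fusion is the element-wise convex combination", {
  a <- matrix(c(1, .8, .8, 1), 2, 2)
  s <- matrix(c(1, .4, .4, 1), 2, 2)
  sA <- .simMat(a); sS <- .simMat(s)
  expect_equal(simValues(fuseSimilarities(sA, sS, 1)), simValues(sA))
  expect_equal(simValues(fuseSimilarities(sA, sS, 0)), simValues(sS))
  expect_equal(unname(simValues(fuseSimilarities(sA, sS, 0.5))[1, 2]), 0.6)
  expect_error(fuseSimilarities(sA, sS, 1.2), "delta")
  expect_error(fuseSimilarities(sA, .simMat(s, c("x", "y")), .5), "subject order")
})

test_that("fusion preserves symmetry, unit diagonal and [0,1] range", {
  set.seed(31)
  for (delta in c(0, 0.3, 0.7, 1)) {
    r1 <- matrix(runif(25), 5, 5); v1 <- (r1 + t(r1)) / 2; diag(v1) <- 1
    r2 <- matrix(runif(25), 5, 5); v2 <- (r2 + t(r2)) / 2; diag(v2) <- 1
    f <- simValues(fuseSimilarities(.simMat(v1), .simMat(v2), delta))
    expect_identical(unname(f), unname(t(f)))
    expect_equal(unname(diag(f)), rep(1, 5))
    expect_true(all(f >= 0 & f <= 1))
  }
})

test_that("spectral clustering separates block-diagonal similarity exactly", {
  v <- matrix(0, 10, 10)
  v[1:4, 1:4] <- 1
  v[5:10, 5:10] <- 1
  truth <- rep(c(0, 1), c(4, 6))
  for (seed in 0:9) {
    res <- spectralCluster(.simMat(v), m = 2, seed = seed)
    expect_equal(clusteringConsistency(res, truth), 1)
  }
})

test_that("spectral clustering handles the fully tied degenerate case", {
  v <- matrix(1, 6, 6)
  res <- spectralCluster(.simMat(v), m = 2, seed = 1)
  expect_length(res@labels, 6L)
  expect_true(all(res@labels %in% 0:1))
})

test_that("planted noisy two-block similarity is recovered", {
  set.seed(33)
  n <- 12
  truth <- rep(0:1, each = 6)
  v <- ifelse(outer(truth, truth, "=="), 0.9, 0.1)
  eps <- matrix(runif(n * n, -0.05, 0.05), n, n)
  v <- pmin(pmax(v + (eps + t(eps)) / 2, 0), 1)
  diag(v) <- 1
  res <- spectralCluster(.simMat(v), m = 2, seed = 4)
  expect_equal(clusteringConsistency(res, truth), 1)
})

test_that("spectral clustering is reproducible and validates input", {
  set.seed(34)
  r <- matrix(runif(49), 7, 7); v <- (r + t(r)) / 2; diag(v) <- 1
  S <- .simMat(v)
  r1 <- spectralCluster(S, m = 3, seed = 11)
  r2 <- spectralCluster(S, m = 3, seed = 11)
  expect_identical(r1@labels, r2@labels)
  expect_error(spectralCluster(S, m = 8), "m must")
  expect_error(spectralCluster(S, m = 1), "m must")
})

test_that("consistency metric matches hand counts and label permutations", {
  expect_equal(clusteringConsistency(c(0, 1, 0, 1), c(0, 1, 0, 1)), 1)
  expect_equal(clusteringConsistency(c(0, 1, 0, 1), c(1, 0, 1, 0)), 1)
  # confusion [[30,10],[5,25]]: best pairing scores (30+25)/70
  labels <- rep(c(0, 0, 1, 1), c(30, 10, 5, 25))
  classes <- rep(c(0, 1, 0, 1), c(30, 10, 5, 25))
  expect_equal(clusteringConsistency(labels, classes), 55 / 70)
  expect_error(clusteringConsistency(1:3, 1:4), "equal length")
})

test_that("consistency equals the brute-force assignment oracle", {
  set.seed(35)
  for (rep in 1:50) {
    m <- sample(2:4, 1)
    n <- sample(10:40, 1)
    labels <- sample(0:(m - 1), n, replace = TRUE)
    classes <- sample(0:(sample(2:4, 1) - 1), n, replace = TRUE)
    expect_equal(clusteringConsistency(labels, classes),
                 oracleConsistency(labels, classes))
  }
})

test_that("end-to-end clustering recovers a strong planted contrast", {
  coh <- plantedTreeCohort(cohortSpec(nNodes = 16, nPerGroup = 6,
                                      effect = 0.8, noise = 0.05, seed = 2))
  res <- clusterCohort(coh$trees, coh$classes, delta = 0.5, h = 2, d = 3, seed = 1)
  expect_gte(consistency(res), 0.9)
  expect_equal(res@delta, 0.5)
})

test_that("singleton sweep equals one end-to-end run and grids multiply", {
  coh <- plantedTreeCohort(cohortSpec(nNodes = 10, nPerGroup = 4,
                                      effect = 0.8, noise = 0.05, seed = 9))
  sw <- parameterSweep(coh$trees, coh$classes, deltaGrid = 0.5,
                       hGrid = 2, dGrid = 3, seed = 1)
  expect_equal(nrow(sw$table), 1L)
  ref <- clusterCohort(coh$trees, coh$classes, delta = 0.5, h = 2, d = 3, seed = 1)
  expect_equal(sw$table$consistency, consistency(ref))
  expect_equal(sw$best$consistency, consistency(ref))

  sw2 <- parameterSweep(coh$trees, coh$classes, deltaGrid = c(0.3, 0.6),
                        hGrid = 1:2, dGrid = c(2, 3), seed = 1)
  expect_equal(nrow(sw2$table), 2 * 2 * 2)
  expect_error(parameterSweep(coh$trees, coh$classes, deltaGrid = numeric(0)),
               "non-empty")
})

test_that("attribute-only endpoint of the delta grid separates a hub contrast", {
  coh <- plantedTreeCohort(cohortSpec(nNodes = 16, nPerGroup = 5,
                                      effect = 1, noise = 0.02, seed = 12))
  sw <- parameterSweep(coh$trees, coh$classes, deltaGrid = c(0, 1),
                       hGrid = 1, dGrid = 2, seed = 1)
  consAtt <- sw$table$consistency[sw$table$delta == 1]
  consStr <- sw$table$consistency[sw$table$delta == 0]
  expect_equal(consAtt, 1)           # betweenness profiles alone suffice
  expect_gte(consAtt, consStr)
})

test_that("the full default grid has 9 x 3 x 6 rows", {
  coh <- plantedTreeCohort(cohortSpec(nNodes = 8, nPerGroup = 3,
                                      effect = 0.8, noise = 0, seed = 4))
  sw <- parameterSweep(coh$trees, coh$classes, seed = 1)
  expect_equal(nrow(sw$table), 162L)
  expect_true(all(sw$table$consistency >= 0 & sw$table$consistency <= 1))
})
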