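test_that("hop-distance sub-networks are the expected nested balls", {
  star <- TreeNetwork(letters[1:5], cbind(1, 2:5))
  s1 <- extractSubnetworks(star, 1, 1)
  expect_equal(s1[[1]]$nodes, 1:5)                    # whole star at radius 1
  expect_equal(sum(s1[[1]]$adjacency) / 2, 4)

  path5 <- TreeNetwork(letters[1:5], cbind(1:4, 2:5))
  s2 <- extractSubnetworks(path5, 1, 2)
  expect_equal(s2[[1]]$nodes, 1:2)
  expect_equal(s2[[2]]$nodes, 1:3)

  # at h >= diameter every ball saturates to the full tree
  set.seed(13)
  tr <- randomTree(9)
  full <- extractSubnetworks(tr, 4, 8)[[8]]
  expect_equal(full$nodes, 1:9)
  expect_equal(unname(full$adjacency), unname(adjacency(tr)))
})

test_that("sub-network node sets grow monotonically with radius", {
  set.seed(14)
  for (rep in 1:5) {
    tr <- randomTree(10)
    i <- sample(10, 1)
    subs <- extractSubnetworks(tr, i, 4)
    for (j in 1:3) expect_true(all(subs[[j]]$nodes %in% subs[[j + 1]]$nodes))
    expect_true(all(vapply(subs, function(s) i %in% s$nodes, logical(1))))
  }
  expect_error(extractSubnetworks(randomTree(5), 1, 0), "h must be")
})

test_that("regular graphs yield ridge-only covariance descriptors", {
  # single edge: power vectors are constant
  pair <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(krylovCovariance(pair, d = 2, ridge = 1e-6), diag(1e-6, 2))
  # 4-cycle is 2-regular
  c4 <- matrix(0, 4, 4)
  for (e in list(c(1, 2), c(2, 3), c(3, 4), c(4, 1)))
    c4[e[1], e[2]] <- c4[e[2], e[1]] <- 1
  expect_equal(krylovCovariance(c4, d = 3, ridge = 1e-4), diag(1e-4, 3))
})

test_that("P3 descriptor matches a transparent step-by-step computation", {
  p3 <- matrix(0, 3, 3)
  p3[1, 2] <- p3[2, 1] <- p3[2, 3] <- p3[3, 2] <- 1
  d <- 2; ridge <- 1e-6
  # u1 = 3 * We / |We|_1 ; u2 = 3 * W^2 e / |W^2 e|_1
  e <- rep(1, 3)
  w1 <- p3 %*% e          # (1, 2, 1)
  w2 <- p3 %*% w1         # (2, 2, 2)
  u1 <- 3 * w1 / sum(w1)
  u2 <- 3 * w2 / sum(w2)
  cov12 <- sum((u1 - mean(u1)) * (u2 - mean(u2))) / 2
  expected <- matrix(c(sum((u1 - mean(u1))^2) / 2 + ridge, cov12,
                       cov12, sum((u2 - mean(u2))^2) / 2 + ridge), 2, 2)
  expect_equal(krylovCovariance(p3, d, ridge), expected, tolerance = 1e-12)
})

test_that("descriptor rejects malformed inputs", {
  expect_error(krylovCovariance(matrix(0, 1, 1), 2), ">= 2 nodes")
  expect_error(krylovCovariance(matrix(0, 3, 3), 2), "zero l1 norm")
  expect_error(krylovCovariance(matrix(c(0, 1, 1, 0), 2, 2), d = 0), "d must be")
})

test_that("pair similarity matches the log-det formula", {
  I3 <- diag(3)
  expect_equal(pairSimilarity(I3, I3), 1)
  set.seed(8)
  # identical descriptors: as-printed form reduces to |C|^(1/2)
  C <- randomPD(3)
  expect_equal(pairSimilarity(C, C), sqrt(det(C)), tolerance = 1e-10)
  # s-divergence form has exact unit self-similarity
  expect_equal(pairSimilarity(C, C, variant = "s_divergence"), 1, tolerance = 1e-12)
  # two distinct PD matrices against an independent evaluation
  A <- randomPD(3); B <- randomPD(3)
  expected <- exp(-0.5 * (log(det((A + B) / 2)) - log(det(A)) - log(det(B))))
  expect_equal(pairSimilarity(A, B), expected, tolerance = 1e-10)
  expect_equal(pairSimilarity(A, B), pairSimilarity(B, A))
  expect_error(pairSimilarity(diag(c(1, -1)), diag(2)), "positive definite")
})

test_that("sub-network kernel equals the naive loop oracle", {
  set.seed(17)
  t1 <- randomTree(8); t2 <- randomTree(8)
  k <- subnetworkKernel(t1, t2, h = 2, d = 2)
  expect_equal(k, oracleSubnetworkKernel(t1, t2, h = 2, d = 2), tolerance = 1e-10)
  expect_equal(k, subnetworkKernel(t2, t1, h = 2, d = 2))   # symmetry
})

test_that("identical regular networks give kernel exactly 1", {
  # s-divergence form: unit self-similarity for any descriptor
  set.seed(18)
  tr <- randomTree(7)
  expect_equal(subnetworkKernel(tr, tr, h = 2, d = 2, variant = "s_divergence"),
               1, tolerance = 1e-12)
  # as-printed form: identical 1-regular toy with ridge 1 makes every
  # descriptor the identity, so every g (hence k) is exactly 1
  pairTree <- TreeNetwork(c("a", "b"), cbind(1, 2))
  expect_equal(subnetworkKernel(pairTree, pairTree, h = 2, d = 2, ridge = 1), 1)
})

test_that("normalization gives unit diagonal and leaves normalized input alone", {
  out <- simValues(normalizeSimilarity(matrix(c(4, 2, 2, 1), 2, 2)))
  expect_equal(unname(out), matrix(1, 2, 2))
  out2 <- simValues(normalizeSimilarity(matrix(c(2, 1, 1, 2), 2, 2)))
  expect_equal(unname(out2), matrix(c(1, .5, .5, 1), 2, 2))
  m <- matrix(c(1, .3, .3, 1), 2, 2)
  expect_equal(unname(simValues(normalizeSimilarity(m))), m)
  expect_error(normalizeSimilarity(matrix(c(0, 0, 0, 1), 2, 2)), "nonpositive")
})

test_that("structure similarity matrix is normalized and matches pairwise kernels", {
  set.seed(19)
  trees <- replicate(3, randomTree(7), simplify = FALSE)
  sm <- structureSimilarityMatrix(trees, h = 2, d = 2)
  v <- simValues(sm)
  expect_equal(unname(diag(v)), rep(1, 3))
  expect_true(all(v > 0 & v <= 1))
  raw <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3)
    raw[i, j] <- subnetworkKernel(trees[[i]], trees[[j]], h = 2, d = 2)
  expected <- raw / sqrt(diag(raw) %o% diag(raw))
  expect_equal(unname(v), expected, tolerance = 1e-10)
  # trivial cohorts
  expect_equal(unname(simValues(structureSimilarityMatrix(trees[1], h = 1, d = 2))),
               matrix(1, 1, 1))
  dup <- structureSimilarityMatrix(list(trees[[1]], trees[[1]]), h = 2, d = 2)
  expect_equal(unname(simValues(dup)), matrix(1, 2, 2), tolerance = 1e-10)
})

test_that("structure similarity is invariant to joint node relabeling", {
  set.seed(23)
  t1 <- randomTree(8); t2 <- randomTree(8)
  perm <- sample(8)
  relabel <- function(tr, perm) {
    e <- tr@edges
    TreeNetwork(tr@nodes, cbind(perm[e[, 1]], perm[e[, 2]]))
  }
  k1 <- subnetworkKernel(t1, t2, h = 2, d = 3)
  k2 <- subnetworkKernel(relabel(t1, perm), relabel(t2, perm), h = 2, d = 3)
  expect_equal(k1, k2, tolerance = 1e-10)
})
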