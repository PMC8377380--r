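test_that("similarity-to-distance transform is the unit complement", {
  b <- randomBlockMatrix(10, 2)
  d <- similarityToDistance(b$matrix)
  expect_identical(unname(diag(d)), rep(0, 10))
  expect_equal(d, 1 - simValues(b$matrix), ignore_attr = TRUE)
  aff <- DrugSimMatrix(simValues(b$matrix) * 2, scale = "affinity")
  expect_error(similarityToDistance(aff), "unit-scale")
})

test_that("spectral clustering recovers exact blocks and is deterministic", {
  blk <- rep(1:2, each = 10)
  v <- outer(blk, blk, function(a, b) ifelse(a == b, 1, 0))
  ids <- sprintf("d%02d", 1:20)
  dimnames(v) <- list(ids, ids)
  m <- DrugSimMatrix(v)
  cl <- spectralCluster(m, 2, seed = 1)
  expect_identical(unname(clusterLabels(cl)),
                   as.integer(factor(blk, levels = unique(blk))))
  cl2 <- spectralCluster(m, 2, seed = 1)
  expect_identical(clusterLabels(cl), clusterLabels(cl2))
  # two zero-linked components cannot host 4 clusters... they can; but 5
  # clusters on 2 x 10 identical points cannot exceed distinct rows
  expect_error(spectralCluster(m, 21, seed = 1), "k must satisfy")
})

test_that("disconnected graphs with more components than k are rejected", {
  v <- as.matrix(Matrix::bdiag(matrix(1, 3, 3), matrix(1, 3, 3),
                               matrix(1, 3, 3)))
  ids <- letters[1:9]
  dimnames(v) <- list(ids, ids)
  m <- DrugSimMatrix(v)
  expect_error(spectralCluster(m, 2, seed = 1), "connected components")
  expect_identical(numClusters(spectralCluster(m, 3, seed = 1)), 3L)
})

test_that("Dunn index matches hand computation and scale invariance", {
  pts <- c(0, 1, 10, 11)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(letters[1:4], letters[1:4])
  asg <- ClusterAssignment(c(1, 1, 2, 2), drugs = letters[1:4])
  expect_identical(dunnIndex(d, asg), 9)
  expect_identical(dunnIndex(5 * d, asg), 9)
  one <- ClusterAssignment(c(1, 1, 1, 1), drugs = letters[1:4])
  expect_error(dunnIndex(d, one), "two clusters")
  singl <- ClusterAssignment(1:4, drugs = letters[1:4])
  expect_error(dunnIndex(d, singl), "singletons")
})

test_that("silhouette matches hand computation and limiting cases", {
  pts <- c(0, 1, 10, 11)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(letters[1:4], letters[1:4])
  asg <- ClusterAssignment(c(1, 1, 2, 2), drugs = letters[1:4])
  # outer points (0, 11): a = 1, b = (10 + 11)/2 -> 9.5/10.5
  # inner points (1, 10): a = 1, b = (9 + 10)/2  -> 8.5/9.5
  want <- (9.5 / 10.5 + 8.5 / 9.5) / 2
  expect_equal(silhouetteMean(d, asg), want, tolerance = 1e-12)
  # two tight clusters at distance 1: a = 0, b = 1 -> 1
  tight <- matrix(1, 4, 4) - diag(1, 4)
  tight[1, 2] <- tight[2, 1] <- tight[3, 4] <- tight[4, 3] <- 0
  dimnames(tight) <- list(letters[1:4], letters[1:4])
  expect_identical(silhouetteMean(tight, asg), 1)
})

test_that("random labels on a tight cloud give near-zero silhouette", {
  set.seed(20)
  n <- 24
  pts <- rnorm(n, sd = 0.01)
  d <- as.matrix(dist(pts))
  ids <- sprintf("p%02d", 1:n)
  dimnames(d) <- list(ids, ids)
  vals <- replicate(20, {
    silhouetteMean(d, ClusterAssignment(sample(1:2, n, replace = TRUE),
                                        drugs = ids))
  })
  expect_lte(mean(vals), 0.1)
})

test_that("validity indices agree with brute-force oracles", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(8:30, 1)
    pts <- matrix(rnorm(n * 2), n)
    d <- as.matrix(dist(pts))
    ids <- sprintf("p%02d", seq_len(n))
    dimnames(d) <- list(ids, ids)
    lab <- sample(1:3, n, replace = TRUE)
    lab[1:3] <- 1:3                     # ensure all clusters present
    asg <- ClusterAssignment(lab, drugs = ids)
    expect_equal(silhouetteMean(d, asg), silhouetteOracle(d, lab),
                 tolerance = 1e-12)
    if (max(tabulate(lab)) >= 2)
      expect_equal(dunnIndex(d, asg), dunnOracle(d, lab), tolerance = 1e-12)
  }
})

test_that("silhouette agrees with the cluster package on a random instance", {
  set.seed(13)
  n <- 25
  pts <- matrix(rnorm(n * 2), n)
  d <- as.matrix(dist(pts))
  ids <- sprintf("p%02d", 1:n)
  dimnames(d) <- list(ids, ids)
  lab <- sample(1:3, n, replace = TRUE)
  lab[1:3] <- 1:3
  ours <- silhouetteMean(d, ClusterAssignment(lab, drugs = ids))
  ref <- mean(cluster::silhouette(lab, dmatrix = d)[, "sil_width"])
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("connectivity counts split neighborhoods as specified", {
  # n = 2, L = 1, points apart in different clusters -> 1/1 + 1/1 = 2
  d <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  asg <- ClusterAssignment(c(1, 2), drugs = c("a", "b"))
  expect_identical(clusterConnectivity(d, asg, L = 1), 2)
  # pure components: zero
  b <- randomBlockMatrix(20, 2, within = 0.95, between = 0.05)
  db <- similarityToDistance(b$matrix)
  pure <- ClusterAssignment(b$labels)
  expect_identical(clusterConnectivity(db, pure, L = 5), 0)
  # correcting one mislabeled boundary point cannot increase connectivity
  wrong <- b$labels
  wrong[1] <- 2
  bad <- clusterConnectivity(db, ClusterAssignment(wrong), L = 5)
  expect_gte(bad, clusterConnectivity(db, pure, L = 5))
  expect_error(clusterConnectivity(d, asg, L = 2), "smaller")
})

test_that("selectK scans the range and applies the declared tie-breaks", {
  b <- randomBlockMatrix(36, 2)
  sel <- suppressWarnings(selectK(b$matrix, kRange = 2:6, seed = 2))
  expect_identical(sel$k, 2L)
  expect_identical(sel$profile$k, 2:6)
  expect_identical(nrow(sel$profile), 5L)
  expect_error(selectK(b$matrix, kRange = integer()), "empty")
  # tie-break: equal silhouette resolved by larger Dunn, then smaller k
  prof <- data.frame(k = c(3L, 4L), silhouette = c(0.8, 0.8),
                     dunn = c(2, 1))
  ord <- order(-prof$silhouette, -prof$dunn, prof$k)
  expect_identical(prof$k[ord][1], 3L)
})
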