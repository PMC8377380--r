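test_that("NMI reproduces its defining cases", {
  expect_identical(nmi(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_identical(nmi(c(0, 0, 1, 1), c(1, 1, 0, 0)), 1)   # relabeling
  expect_identical(nmi(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)   # independent
  expect_identical(nmi(c(1, 1, 1), c(1, 2, 3)), 0)         # H(X) = 0
  expect_error(nmi(1:3, 1:4), "length")
})

test_that("NMI matches the contingency-table oracle on random labelings", {
  set.seed(23)
  for (i in 1:200) {
    n <- sample(5:50, 1)
    x <- sample(1:4, n, replace = TRUE)
    y <- sample(1:3, n, replace = TRUE)
    expect_equal(nmi(x, y), max(min(nmiOracle(x, y), 1), 0),
                 tolerance = 1e-12)
  }
})

test_that("ATC overlap rate counts intersecting first-level sets", {
  reg <- smallRegistry()
  # d1 {N,A} vs d2 {A} -> overlap; d3 {C} vs d4 {N} -> none
  pairs <- data.frame(a = c("d1", "d3", "d1", "d2"),
                      b = c("d2", "d4", "d4", "d3"))
  expect_identical(as.numeric(aor(pairs, reg)), 0.5)
  # order of pairs and of drugs within a pair is irrelevant
  swapped <- data.frame(a = pairs$b, b = pairs$a)[c(3, 1, 4, 2), ]
  expect_identical(as.numeric(aor(swapped, reg)), 0.5)
  # pairs touching the ATC-less d5 are excluded, not scored
  withd5 <- rbind(pairs, data.frame(a = "d5", b = "d1"))
  expect_message(r <- aor(withd5, reg), "excluded")
  expect_identical(as.numeric(r), 0.5)
  expect_identical(attr(r, "n_excluded"), 1L)
  expect_error(aor(pairs[0, ], reg), "empty")
})

test_that("superclass overlap rate uses label equality", {
  reg <- smallRegistry()
  pairs <- data.frame(a = c("d1", "d3", "d1"), b = c("d2", "d4", "d3"))
  # x==x, y==y, x!=y -> 2/3
  expect_equal(as.numeric(sor(pairs, reg)), 2 / 3, tolerance = 1e-12)
})

test_that("Rogers-Tanimoto agreement matches enumeration", {
  ids <- c("w", "x", "y", "z")
  p1 <- ClusterAssignment(c(1, 1, 2, 2), drugs = ids)
  p2 <- ClusterAssignment(c(1, 2, 1, 2), drugs = ids)
  expect_identical(rogersTanimoto(p1, p1), 1)
  expect_identical(rogersTanimoto(p1, p2), 0.2)
  # relabeling invariance
  p2b <- ClusterAssignment(c(2, 1, 2, 1), drugs = ids)
  expect_identical(rogersTanimoto(p1, p2b), 0.2)
  expect_error(
    rogersTanimoto(p1, ClusterAssignment(c(1, 2), drugs = c("w", "q"))),
    "different drug sets")
})

test_that("Rogers-Tanimoto matches the all-pairs oracle on random partitions", {
  set.seed(17)
  for (i in 1:30) {
    n <- sample(5:25, 1)
    ids <- sprintf("d%02d", seq_len(n))
    l1 <- sample(1:4, n, replace = TRUE); l1[1:4] <- 1:4
    l2 <- sample(1:3, n, replace = TRUE); l2[1:3] <- 1:3
    expect_equal(
      rogersTanimoto(ClusterAssignment(l1, drugs = ids),
                     ClusterAssignment(l2, drugs = ids)),
      rtOracle(l1, l2), tolerance = 1e-12)
  }
})

test_that("the sliding-bin overlap curve behaves on constructed rankings", {
  reg <- smallRegistry()
  # score 1 iff the pair shares a first-level code
  pairs <- data.frame(
    drug_a = c("d1", "d1", "d1", "d2", "d3", "d4"),
    drug_b = c("d2", "d4", "d3", "d3", "d4", "d6"))
  levels <- atcFirstLevels(reg)
  share <- mapply(function(a, b)
    as.numeric(length(intersect(levels[[a]], levels[[b]])) > 0),
    pairs$drug_a, pairs$drug_b)
  ranked <- pairs[order(-share), ]
  ranked$score <- sort(share, decreasing = TRUE)
  curve <- aorCurve(ranked, reg, binSize = 2, step = 1)
  expect_identical(nrow(curve), 5L)
  expect_identical(curve$aor[1], 1)
  expect_true(all(diff(curve$aor) <= 1e-12))
  # window-count arithmetic: 4 pairs, bin 2, step 1 -> 3 bins
  expect_identical(nrow(aorCurve(ranked[1:4, ], reg, binSize = 2, step = 1)),
                   3L)
  expect_error(aorCurve(ranked, reg, binSize = 10, step = 1), "too short")
  expect_error(aorCurve(ranked[order(ranked$score), ], reg,
                        binSize = 2, step = 1), "descending")
})

test_that("a shuffled ranking fluctuates around the global overlap rate", {
  set.seed(3)
  uni <- simulateUniverse(universeSpec(nDrugs = 48L, nClusters = 4L), seed = 3)
  ranked <- topPairs(buildProfileDSN(uni$sideEffects), uni$registry)
  global <- as.numeric(suppressMessages(aor(ranked[c("drug_a", "drug_b")],
                                            uni$registry)))
  devs <- replicate(20, {
    sh <- ranked[sample(nrow(ranked)), ]
    sh$score <- sort(sh$score, decreasing = TRUE)   # scores become ranks only
    curve <- aorCurve(sh, uni$registry, binSize = 200, step = 200)
    mean(curve$aor) - global
  })
  expect_lt(abs(mean(devs)), 0.1)
})
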