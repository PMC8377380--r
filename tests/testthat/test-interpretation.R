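test_that("edge attribution implements the margin rule", {
  expect_identical(attributeEdge(c(chem = 0.9, target = 0.5, side = 0.4)),
                   "chem")
  expect_setequal(attributeEdge(c(chem = 0.5, target = 0.5, side = 0.5)),
                  c("chem", "target", "side"))
  expect_identical(attributeEdge(c(a = 0.55, b = 0.52, c = 0.30)),
                   c("a", "b"))
  # scale invariance of the relative rule
  set.seed(2)
  for (i in 1:50) {
    s <- stats::setNames(runif(3), c("x", "y", "z"))
    expect_identical(attributeEdge(s), attributeEdge(17.3 * s))
  }
  # absolute variant differs where the ratio rule would not fire
  expect_identical(attributeEdge(c(a = 0.92, b = 0.80), relative = FALSE),
                   "a")
  expect_error(attributeEdge(c(a = -1, b = 1)), "non-negative")
  expect_error(attributeEdge(c(0.1, 0.2)), "named")
})

test_that("contribution fractions partition the retained edges", {
  ids <- c("a", "b", "c", "d")
  mk <- function(vals) {
    m <- matrix(0, 4, 4, dimnames = list(ids, ids))
    m[upper.tri(m)] <- vals
    m <- m + t(m); diag(m) <- 1
    DrugSimMatrix(m)
  }
  # per-edge view scores chosen so attribution is known by hand
  side   <- mk(c(0.9, 0.1, 0.5, 0.1, 0.1, 0.3))
  chem   <- mk(c(0.5, 0.6, 0.5, 0.1, 0.4, 0.3))
  target <- mk(c(0.4, 0.1, 0.5, 0.1, 0.1, 0.3))
  fused  <- mk(rep(0.5, 6))
  asg <- ClusterAssignment(c(1, 1, 2, 2), drugs = ids)
  res <- contributionSummary(list(side = side, chem = chem, target = target),
                             fused, asg, topFrac = 1)
  expect_identical(nrow(res$edges), 6L)
  byPair <- stats::setNames(res$edges$category,
                            paste(res$edges$drug_a, res$edges$drug_b))
  expect_identical(unname(byPair["a b"]), "side")          # 0.9 vs 0.5
  expect_identical(unname(byPair["a c"]), "chem")          # 0.6 vs 0.1
  expect_identical(unname(byPair["b c"]), "chem+side+target")  # all 0.5
  expect_identical(unname(byPair["a d"]), "chem+side+target")  # all 0.1
  expect_identical(unname(byPair["b d"]), "chem")          # 0.4 vs 0.1
  expect_identical(unname(byPair["c d"]), "chem+side+target")  # all 0.3
  # fractions sum to one in every scope that has edges
  for (sc in unique(res$summary$scope)) {
    fr <- res$summary$fraction[res$summary$scope == sc]
    if (!all(is.na(fr))) expect_equal(sum(fr), 1, tolerance = 1e-12)
  }
  allCats <- c("chem", "side", "target", "chem+side", "chem+target",
               "side+target", "chem+side+target")
  expect_setequal(unique(res$summary$category), allCats)
  # a uniform attribution fills one category completely
  uni <- contributionSummary(list(side = side, chem = side, target = side),
                             fused, asg, topFrac = 1)
  allScope <- subset(uni$summary, scope == "all")
  expect_identical(allScope$fraction[allScope$category == "chem+side+target"],
                   1)
})

test_that("enrichment score and hypergeometric tail match closed forms", {
  expect_identical(enrichmentScore(5, 10, 20, 100), 2.5)
  expect_identical(enrichmentScore(0, 10, 20, 100), 0)
  expect_identical(enrichmentScore(10, 10, 100, 100), 1)
  expect_error(enrichmentScore(1, 0, 5, 10), "positive")
  expect_equal(hypergeomP(2, 2, 2, 4), 1 / 6, tolerance = 1e-12)
  expect_identical(hypergeomP(0, 5, 3, 10), 1)
  expect_identical(hypergeomP(4, 5, 3, 10), 0)   # impossible event
  expect_error(hypergeomP(1, 5, 11, 10), "impossible counts")
})

test_that("hypergeometric tail matches exhaustive draw enumeration", {
  set.seed(12)
  for (i in 1:40) {
    N <- sample(4:12, 1)
    n <- sample(1:(N - 1), 1)
    m <- sample(1:(N - 1), 1)
    k <- sample(0:min(m, n), 1)
    expect_equal(hypergeomP(k, n, m, N), hyperOracle(k, n, m, N),
                 tolerance = 1e-12)
  }
})

test_that("es exceeds 1 exactly when the in-cluster rate beats the base rate", {
  set.seed(6)
  for (i in 1:100) {
    N <- sample(20:200, 1)
    n <- sample(2:(N - 1), 1)
    m <- sample(1:(N - 1), 1)
    k <- sample(0:min(m, n), 1)
    expect_identical(enrichmentScore(k, n, m, N) > 1, k / n > m / N)
  }
})

test_that("cluster annotation computes per-term records with BH correction", {
  lab <- rep(1:2, each = 10)
  ids <- sprintf("d%02d", 1:20)
  asg <- ClusterAssignment(lab, drugs = ids)
  vocab <- stats::setNames(
    c(as.list(rep("N", 10)), as.list(rep("C", 10))), ids)
  vocab$d01 <- c("N", "A")           # multi-label drug counts once per term
  enr <- annotateClusters(asg, vocab)
  n_row <- subset(enr, cluster == 1 & term == "N")
  expect_identical(n_row$k, 10L)
  expect_identical(n_row$m, 10L)
  expect_identical(n_row$es, 2)
  expect_equal(n_row$p, 1 / choose(20, 10), tolerance = 1e-12)
  expect_true(n_row$significant)
  absent <- subset(enr, cluster == 1 & term == "C")
  expect_identical(absent$k, 0L)
  expect_identical(absent$es, 0)
  expect_identical(absent$p, 1)
  expect_false(absent$significant)
  a_row <- subset(enr, cluster == 1 & term == "A")
  expect_identical(a_row$k, 1L)
  expect_true(all(enr$q >= enr$p - 1e-15))
})

test_that("unexpected drugs are flagged against enriched cluster terms", {
  ids <- sprintf("d%02d", 1:20)
  asg <- ClusterAssignment(rep(1:2, each = 10), drugs = ids)
  codes <- c(rep("N01", 9), "M03", rep("C07", 9), "")
  reg <- DrugRegistry(ids, atc_codes = as.list(codes))
  enr <- annotateClusters(asg, atcVocabulary(reg))
  cand <- findUnexpectedDrugs(asg, enr, reg)
  expect_identical(cand$drug_id, "d10")     # the M drug inside the N cluster
  expect_identical(cand$proposed, "N")
  expect_identical(cand$own_codes, "M")
  # drugs with ATC intersecting the enriched set are not flagged,
  # and the ATC-less d20 is not flagged either
  expect_false(any(c("d01", "d20") %in% cand$drug_id))
})

test_that("top pairs rank deterministically and flag ATC discordance", {
  b <- randomBlockMatrix(6, 2, within = 0.8, between = 0.2)
  v <- simValues(b$matrix)
  v["d001", "d002"] <- v["d002", "d001"] <- 0.99
  m <- DrugSimMatrix(v)
  reg <- DrugRegistry(drugIds(m),
                      atc_codes = list("N01", "C01", "N02", "C02", "N03", ""))
  tp <- topPairs(m, reg, nTop = 5)
  expect_identical(tp$drug_a[1], "d001")
  expect_identical(tp$drug_b[1], "d002")
  expect_identical(tp$rank, 1:5)
  expect_false(tp$atc_overlap[1])          # N vs C
  # tie groups are ordered by canonical pair ids
  ties <- topPairs(m, reg)
  same <- ties[ties$score == 0.8, ]
  expect_identical(same[order(same$drug_a, same$drug_b), "rank"], same$rank)
  # concordance flags agree with the overlap-rate predicate
  lv <- atcFirstLevels(reg)
  manual <- mapply(function(a, b) {
    la <- lv[[a]]; lb <- lv[[b]]
    if (!length(la) || !length(lb)) NA else length(intersect(la, lb)) > 0
  }, ties$drug_a, ties$drug_b)
  expect_identical(ties$atc_overlap, unname(manual))
  expect_error(topPairs(m, nTop = 100), "exceeds")
})

test_that("the ATC repositioning graph averages spanning-pair scores", {
  ids <- c("a", "b", "c")
  v <- matrix(c(1, 0.9, 0.6, 0.9, 1, 0.3, 0.6, 0.3, 1), 3,
              dimnames = list(ids, ids))
  m <- DrugSimMatrix(v)
  reg <- DrugRegistry(ids, atc_codes = list("N01", "M01", c("M05", "N02")))
  g <- atcRepositioningGraph(m, reg, topFrac = 1)
  w <- function(x, y) {
    row <- g[g$code_a == min(x, y) & g$code_b == max(x, y), ]
    row$weight
  }
  # N-M spanning pairs: a-b (.9), a-c via M (.6), b-c via N (.3)
  expect_equal(w("N", "M"), mean(c(0.9, 0.6, 0.3)), tolerance = 1e-12)
  # within-N: a-c (.6); within-M: b-c (.3)
  expect_equal(w("N", "N"), 0.6, tolerance = 1e-12)
  expect_equal(w("M", "M"), 0.3, tolerance = 1e-12)
  single <- atcRepositioningGraph(m, DrugRegistry(ids,
    atc_codes = list("N01", "M01", "")), topFrac = 1 / 3)
  expect_identical(nrow(single), 1L)
})

test_that("property deviation and its Welch test behave", {
  dev <- propertyDeviation(c(1.4, 1.5, 1.6), c(0.9, 1.0, 1.1))
  expect_equal(dev$D, 0.5, tolerance = 1e-12)
  expect_identical(propertyDeviation(c(2, 2), c(2, 2))$D, 0)
  expect_error(propertyDeviation(1:3, c(-1, 0, 1)), "non-zero")
  # type-I error: identical distributions rarely significant
  set.seed(40)
  hits <- replicate(100, {
    propertyDeviation(rnorm(15, 5), rnorm(30, 5))$p < 0.05
  })
  expect_gte(mean(!hits), 0.9)
})
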