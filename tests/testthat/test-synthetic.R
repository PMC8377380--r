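test_that("universe specification validates its invariants", {
  expect_error(universeSpec(nDrugs = 10L, nClusters = 4L), "nDrugs / 4")
  expect_error(universeSpec(nDrugs = 120L, nClusters = 3L,
                            informative = list(side_effect = 1L,
                                               atom_pair = 1L, target = 2L)),
               "missing: 3")
  expect_error(universeSpec(seVocab = 50L, seSignature = 30L, nClusters = 2L,
                            nDrugs = 20L), "vocabulary")
  spec <- complementaryBenchmark()
  expect_identical(spec$nDrugs, 120L)
  expect_identical(spec$nClusters, 6L)
  expect_setequal(unlist(spec$informative), 1:6)
})

test_that("simulation is a pure function of spec and seed", {
  spec <- universeSpec(nDrugs = 24L, nClusters = 3L)
  u1 <- simulateUniverse(spec, seed = 99)
  u2 <- simulateUniverse(spec, seed = 99)
  expect_identical(u1$sideEffects@pairs, u2$sideEffects@pairs)
  expect_identical(u1$atomPairs@pairs, u2$atomPairs@pairs)
  expect_identical(as.character(u1$sequences), as.character(u2$sequences))
  expect_identical(atcCodes(u1$registry), atcCodes(u2$registry))
  expect_identical(clusterLabels(u1$truth), clusterLabels(u2$truth))
  u3 <- simulateUniverse(spec, seed = 100)
  expect_false(identical(u1$sideEffects@pairs, u3$sideEffects@pairs))
})

test_that("noiseless fully-informative universes are exactly recoverable", {
  spec <- universeSpec(nDrugs = 36L, nClusters = 3L, seDropout = 0,
                       seNoise = 0L, apDropout = 0, apNoise = 0L,
                       mutationRate = 0)
  uni <- simulateUniverse(spec, seed = 4)
  truth <- clusterLabels(uni$truth)
  for (dsn in list(buildProfileDSN(uni$sideEffects),
                   buildProfileDSN(uni$atomPairs))) {
    cl <- spectralCluster(dsn, 3, seed = 4)
    expect_equal(nmi(clusterLabels(cl)[names(truth)], truth), 1,
                 tolerance = 1e-12)
  }
  # within-cluster pairs all share the dominant code when label noise is 0
  ranked <- topPairs(buildProfileDSN(uni$sideEffects), uni$registry)
  within <- ranked[truth[ranked$drug_a] == truth[ranked$drug_b], ]
  expect_true(all(within$atc_overlap))
})

test_that("uninformative views cannot separate their clusters", {
  spec <- universeSpec(nDrugs = 48L, nClusters = 4L,
                       informative = list(side_effect = 1:2, atom_pair = 3:4,
                                          target = 1:4),
                       seDropout = 0, seNoise = 0L)
  uni <- simulateUniverse(spec, seed = 21)
  truth <- clusterLabels(uni$truth)
  dsn <- buildProfileDSN(uni$sideEffects)
  cl <- spectralCluster(dsn, 4, seed = 21)
  expect_lt(nmi(clusterLabels(cl)[names(truth)], truth), 1)
})

test_that("raising view noise degrades that view's recovery", {
  levels <- c(0.05, 0.45, 0.85)
  med <- vapply(levels, function(dr) {
    vals <- vapply(1:6, function(s) {
      spec <- universeSpec(nDrugs = 48L, nClusters = 3L, seDropout = dr,
                           seNoise = 10L)
      uni <- simulateUniverse(spec, seed = s)
      truth <- clusterLabels(uni$truth)
      cl <- spectralCluster(buildProfileDSN(uni$sideEffects), 3, seed = s)
      nmi(clusterLabels(cl)[names(truth)], truth)
    }, numeric(1))
    stats::median(vals)
  }, numeric(1))
  expect_true(all(diff(med) <= 1e-9))
  expect_lt(med[3], med[1])
})

test_that("label noise records ground-truth flips", {
  spec <- universeSpec(nDrugs = 60L, nClusters = 3L, atcNoise = 0.2)
  uni <- simulateUniverse(spec, seed = 8)
  fl <- uni$flips
  expect_gt(nrow(fl), 0)
  expect_true(all(fl$true_code != fl$observed_code))
  lv <- atcFirstLevels(uni$registry)
  expect_identical(vapply(fl$drug_id, function(d) lv[[d]], ""),
                   stats::setNames(fl$observed_code, fl$drug_id))
})

test_that("a simulated universe round-trips through the on-disk formats", {
  dir <- withr::local_tempdir()
  uni <- simulateUniverse(universeSpec(nDrugs = 16L, nClusters = 2L,
                                       atcNoise = 0.1), seed = 2)
  writeUniverse(uni, dir)
  reg <- readDrugRegistry(file.path(dir, "registry.tsv"))
  expect_identical(atcCodes(reg), atcCodes(uni$registry))
  se <- readFeatureProfiles(file.path(dir, "side_effects.tsv"),
                            kind = "side_effect")
  expect_identical(featureSets(se), featureSets(uni$sideEffects))
  tm <- readTargetMap(file.path(dir, "target_map.tsv"))
  expect_identical(tm, uni$targetMap)
  db <- readSequenceDB(file.path(dir, "sequences.fasta"))
  expect_identical(as.character(db), as.character(uni$sequences))
  tr <- readClusterAssignment(file.path(dir, "truth_clusters.tsv"))
  expect_identical(clusterLabels(tr), clusterLabels(uni$truth))
})
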