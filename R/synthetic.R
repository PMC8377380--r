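# Synthetic drug universes with planted cluster structure and per-view
# complementary noise, so every pipeline stage is testable end to end
# without external databases.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

#' Specify a synthetic drug universe
#'
#' Defines the statistical structure the simulator plants: drugs partitioned
#' into clusters; per-view informativeness (which planted clusters each data
#' view can separate — clusters a view is uninformative about draw their
#' features from the global background, so that view cannot tell them
#' apart); side-effect and atom-pair token vocabularies with per-cluster
#' signatures, signature dropout and per-drug noise tokens; a protein pool
#' with per-cluster anchor sequences mutated per drug; and an ATC assignment
#' rule mapping each cluster to a dominant first-level code, with a
#' label-noise rate that flips a drug's code to a random other letter
#' (creating ground-truth "unexpected drugs").
#'
#' @param nDrugs number of drugs (clusters are near-equal in size).
#' @param nClusters number of planted clusters; at most `nDrugs / 4` and at
#'   most 14 (one dominant ATC letter each).
#' @param informative named list with elements `side_effect`, `atom_pair`,
#'   `target`: integer vectors of cluster indices that view separates.
#'   Every cluster must be covered by at least one view.
#' @param seVocab,apVocab vocabulary sizes of the two token views.
#' @param seSignature,apSignature per-cluster signature sizes (disjoint
#'   across clusters; `nClusters * signature <= vocab` required).
#' @param seDropout,apDropout probability of dropping each signature token
#'   from a drug's profile.
#' @param seNoise,apNoise number of background noise tokens added per drug.
#' @param proteinLength length of the anchor protein sequences.
#' @param mutationRate per-residue mutation probability of a drug's copy of
#'   its cluster anchor.
#' @param atcNoise probability of flipping a drug's dominant ATC letter to a
#'   uniformly random other letter.
#' @return a `universe_spec` list.
#' @export
universeSpec <- function(nDrugs = 120L, nClusters = 6L,
                         informative = list(side_effect = seq_len(nClusters),
                                            atom_pair = seq_len(nClusters),
                                            target = seq_len(nClusters)),
                         seVocab = 400L, seSignature = 30L, seDropout = 0.25,
                         seNoise = 12L,
                         apVocab = 600L, apSignature = 30L, apDropout = 0.25,
                         apNoise = 12L,
                         proteinLength = 120L, mutationRate = 0.08,
                         atcNoise = 0) {
  nDrugs <- as.integer(nDrugs); nClusters <- as.integer(nClusters)
  if (nClusters > nDrugs / 4)
    stop("nClusters must be at most nDrugs / 4")
  if (nClusters > length(ATC_FIRST_LEVELS))
    stop("at most ", length(ATC_FIRST_LEVELS), " clusters supported")
  need <- c("side_effect", "atom_pair", "target")
  if (!all(need %in% names(informative)))
    stop("informative must name views ", paste(need, collapse = ", "))
  covered <- sort(unique(unlist(informative[need])))
  if (!all(seq_len(nClusters) %in% covered))
    stop("every cluster must be informative in at least one view; missing: ",
         paste(setdiff(seq_len(nClusters), covered), collapse = ", "))
  if (nClusters * seSignature > seVocab || nClusters * apSignature > apVocab)
    stop("signatures larger than the vocabulary allows")
  rates <- c(seDropout, apDropout, mutationRate, atcNoise)
  if (any(rates < 0) || any(rates > 1))
    stop("rates must lie in [0, 1]")
  structure(list(
    nDrugs = nDrugs, nClusters = nClusters, informative = informative[need],
    seVocab = as.integer(seVocab), seSignature = as.integer(seSignature),
    seDropout = seDropout, seNoise = as.integer(seNoise),
    apVocab = as.integer(apVocab), apSignature = as.integer(apSignature),
    apDropout = apDropout, apNoise = as.integer(apNoise),
    proteinLength = as.integer(proteinLength), mutationRate = mutationRate,
    atcNoise = atcNoise), class = "universe_spec")
}

#' The complementary three-view benchmark specification
#'
#' The canned universe used for the fusion recovery benchmark: 120 drugs in
#' 6 planted clusters, three views each able to separate only part of the
#' cluster structure (side effects: clusters 1-3; atom pairs: clusters 3-5;
#' targets: clusters 5, 6, 1) under moderate noise.  No single view can
#' recover the full partition; their union covers it.
#'
#' @param atcNoise ATC label-noise rate (0 for the clean benchmark; 0.1 for
#'   the unexpected-drug recovery experiment).
#' @return a `universe_spec` list.
#' @export
complementaryBenchmark <- function(atcNoise = 0) {
  universeSpec(nDrugs = 120L, nClusters = 6L,
               informative = list(side_effect = c(1L, 2L, 3L),
                                  atom_pair = c(3L, 4L, 5L),
                                  target = c(5L, 6L, 1L)),
               atcNoise = atcNoise)
}

sampleTokens <- function(prefix, vocabSize, idx) paste0(prefix, idx)

mutateSequence <- function(anchor, rate) {
  if (rate <= 0) return(anchor)
  chars <- strsplit(anchor, "")[[1L]]
  hit <- stats::runif(length(chars)) < rate
  if (any(hit))
    chars[hit] <- sample(AA_ALPHABET, sum(hit), replace = TRUE)
  paste(chars, collapse = "")
}

randomSequence <- function(len) {
  paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
}

tokenProfile <- function(signature, vocab, prefix, dropout, nNoise,
                         informative, baselineSize) {
  if (informative) {
    kept <- signature[stats::runif(length(signature)) >= dropout]
  } else {
    # background drug: same expected profile size, no cluster signal
    kept <- sampleTokens(prefix, vocab,
                         sample.int(vocab, baselineSize))
  }
  noise <- if (nNoise > 0)
    sampleTokens(prefix, vocab, sample.int(vocab, nNoise)) else character()
  unique(c(kept, noise))
}

#' Simulate a synthetic drug universe
#'
#' Generates, deterministically for a given seed, every input the pipeline
#' consumes: a drug registry with cluster-dominant ATC codes (plus optional
#' label-noise flips) and cluster superclass labels; side-effect and
#' atom-pair feature profiles with per-cluster signatures; a drug-target map
#' with per-drug mutated copies of per-cluster anchor proteins; and the
#' planted cluster assignment.  Views declared uninformative for a cluster
#' draw that cluster's features from the global background.
#'
#' @param spec a `universe_spec` from [universeSpec()].
#' @param seed integer seed; the output is a pure function of
#'   `(spec, seed)`.
#' @return list with elements `registry` ([DrugRegistry-class]),
#'   `sideEffects` and `atomPairs` ([FeatureProfileSet-class]), `targetMap`
#'   (named list), `sequences` (`AAStringSet`), `truth`
#'   ([ClusterAssignment-class]), `flips` (data.frame of label-noise flips:
#'   `drug_id`, `true_code`, `observed_code`) and `spec`.
#' @export
simulateUniverse <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "universe_spec"))
  withSeed(seed, {
    n <- spec$nDrugs; k <- spec$nClusters
    drugs <- sprintf("d%03d", seq_len(n))
    cluster <- rep(seq_len(k), length.out = n)
    cluster <- sort(cluster)

    seSig <- split(sampleTokens("se", spec$seVocab,
                                sample.int(spec$seVocab, k * spec$seSignature)),
                   rep(seq_len(k), each = spec$seSignature))
    apSig <- split(sampleTokens("ap", spec$apVocab,
                                sample.int(spec$apVocab, k * spec$apSignature)),
                   rep(seq_len(k), each = spec$apSignature))
    anchors <- vapply(seq_len(k), function(i)
      randomSequence(spec$proteinLength), character(1L))

    sePairs <- list(); apPairs <- list()
    targetMap <- stats::setNames(vector("list", n), drugs)
    seqs <- character(n)
    seBase <- spec$seSignature; apBase <- spec$apSignature
    for (i in seq_len(n)) {
      cl <- cluster[i]
      seSet <- tokenProfile(seSig[[cl]], spec$seVocab, "se", spec$seDropout,
                            spec$seNoise,
                            cl %in% spec$informative$side_effect, seBase)
      apSet <- tokenProfile(apSig[[cl]], spec$apVocab, "ap", spec$apDropout,
                            spec$apNoise,
                            cl %in% spec$informative$atom_pair, apBase)
      sePairs[[i]] <- data.frame(
        drug_id = drugs[i], feature = seSet,
        frequency = round(stats::runif(length(seSet), 0.01, 1), 3L))
      apPairs[[i]] <- data.frame(drug_id = drugs[i], feature = apSet,
                                 frequency = NA_real_)
      seqs[i] <- if (cl %in% spec$informative$target)
        mutateSequence(anchors[cl], spec$mutationRate)
      else randomSequence(spec$proteinLength)
      targetMap[[i]] <- paste0("P_", drugs[i])
    }
    names(seqs) <- paste0("P_", drugs)

    dominant <- ATC_FIRST_LEVELS[seq_len(k)]
    trueCode <- dominant[cluster]
    observed <- trueCode
    flip <- stats::runif(n) < spec$atcNoise
    for (i in which(flip))
      observed[i] <- sample(setdiff(ATC_FIRST_LEVELS, trueCode[i]), 1L)
    registry <- DrugRegistry(
      drugs, name = drugs,
      atc_codes = lapply(observed, function(code) paste0(code, "01")),
      superclass = paste0("class_", cluster))

    list(
      registry = registry,
      sideEffects = FeatureProfileSet(do.call(rbind, sePairs),
                                      kind = "side_effect", drugs = drugs),
      atomPairs = FeatureProfileSet(do.call(rbind, apPairs),
                                    kind = "atom_pair", drugs = drugs),
      targetMap = targetMap,
      sequences = Biostrings::AAStringSet(seqs),
      truth = ClusterAssignment(cluster, drugs = drugs, k = k),
      flips = data.frame(drug_id = drugs[flip],
                         true_code = trueCode[flip],
                         observed_code = observed[flip]),
      spec = spec)
  })
}

#' Build the three single-property networks of a simulated universe
#'
#' @param universe output of [simulateUniverse()].
#' @param scoring an [AlignmentScoring-class] for the target view.
#' @return named list of unit-scale [DrugSimMatrix-class] objects
#'   (`side_effect`, `atom_pair`, `target`), aligned on the universe drugs.
#' @export
buildUniverseViews <- function(universe, scoring = alignmentScoring()) {
  list(
    side_effect = buildProfileDSN(universe$sideEffects),
    atom_pair = buildProfileDSN(universe$atomPairs),
    target = buildTargetDSN(universe$targetMap, universe$sequences, scoring))
}

#' Write a simulated universe to a directory of core formats
#'
#' Emits `registry.tsv`, `side_effects.tsv`, `atom_pairs.tsv`,
#' `target_map.tsv`, `sequences.fasta` and `truth_clusters.tsv`.
#'
#' @param universe output of [simulateUniverse()].
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of written paths.
#' @export
writeUniverse <- function(universe, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    writeDrugRegistry(universe$registry, file.path(dir, "registry.tsv")),
    writeFeatureProfiles(universe$sideEffects,
                         file.path(dir, "side_effects.tsv")),
    writeFeatureProfiles(universe$atomPairs, file.path(dir, "atom_pairs.tsv")),
    writeTargetMap(universe$targetMap, file.path(dir, "target_map.tsv")),
    {
      fa <- file.path(dir, "sequences.fasta")
      Biostrings::writeXStringSet(universe$sequences, fa)
      fa
    },
    writeClusterAssignment(universe$truth,
                           file.path(dir, "truth_clusters.tsv")))
  invisible(paths)
}
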