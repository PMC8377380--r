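#' Filter side-effect terms by support and reported frequency
#'
#' Removes terms with essentially no evidence before similarity is computed:
#' a term is dropped from every profile when it occurs for at most `minCount`
#' drugs corpus-wide, or when a reported frequency attached to a (drug, term)
#' pair falls below `minFrequency`.  The frequency rule only fires for pairs
#' that actually carry frequency data; the count rule applies to all terms.
#' Defaults reproduce the conventional cleanup of side-effect resources:
#' singleton terms and frequencies below 0.1% go.
#'
#' Drugs whose profile becomes empty are retained in the drug universe (and
#' reported via a message), never silently dropped.
#'
#' @param profiles a [FeatureProfileSet-class] of kind `"side_effect"`.
#' @param minCount drop terms occurring for `<= minCount` drugs (default 1).
#' @param minFrequency drop pairs with frequency `< minFrequency`
#'   (default 0.001).
#' @return a filtered [FeatureProfileSet-class] over the same drug universe.
#' @export
filterSideEffectTerms <- function(profiles, minCount = 1L,
                                  minFrequency = 0.001) {
  stopifnot(is(profiles, "FeatureProfileSet"))
  if (profileKind(profiles) != "side_effect")
    stop("term filtering applies to side-effect profiles")
  p <- profiles@pairs
  if (!nrow(p))
    return(profiles)
  keep_pair <- is.na(p$frequency) | p$frequency >= minFrequency
  p <- p[keep_pair, , drop = FALSE]
  support <- table(p$feature[!duplicated(p[c("drug_id", "feature")])])
  rare <- names(support)[support <= minCount]
  p <- p[!p$feature %in% rare, , drop = FALSE]
  out <- FeatureProfileSet(p, kind = "side_effect", drugs = profiles@drugs)
  emptied <- setdiff(profiles@drugs, unique(p$drug_id))
  if (length(emptied))
    message(length(emptied), " drug(s) left with empty side-effect profiles ",
            "after term filtering: ", paste(utils::head(emptied, 10L), collapse = ", "),
            if (length(emptied) > 10L) ", ..." else "")
  out
}

#' Tanimoto coefficient of two feature sets
#'
#' \eqn{|a \cap b| / (|a| + |b| - |a \cap b|)}.  When both sets are empty the
#' coefficient is defined as 0: absence of evidence must not assert maximal
#' similarity.
#'
#' @param a,b character vectors treated as sets (duplicates ignored).
#' @return similarity in \[0, 1\].
#' @examples
#' tanimoto(c("x", "y", "z"), c("x", "q"))  # 1 / (3 + 2 - 1) = 0.25
#' @export
tanimoto <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (!length(a) && !length(b)) return(0)
  shared <- length(intersect(a, b))
  shared / (length(a) + length(b) - shared)
}

#' Build a profile-based drug similarity network
#'
#' Pairwise Tanimoto similarity over the per-drug feature sets of a profile
#' collection (side-effect terms or atom-pair tokens), giving a unit-scale
#' network with unit diagonal.
#'
#' @param profiles a [FeatureProfileSet-class], or a named list of character
#'   feature sets.
#' @return a unit-scale [DrugSimMatrix-class] in the profile drug order.
#' @export
buildProfileDSN <- function(profiles) {
  sets <- if (is(profiles, "FeatureProfileSet")) featureSets(profiles)
          else profiles
  drugs <- names(sets)
  if (is.null(drugs) || anyDuplicated(drugs))
    stop("profiles must be named by unique drug ids")
  n <- length(sets)
  if (n < 2L) stop("need at least two drugs")
  sets <- lapply(sets, unique)
  sizes <- lengths(sets)
  v <- diag(1, n)
  for (i in seq_len(n - 1L)) {
    si <- sets[[i]]
    for (j in seq((i + 1L), n)) {
      if (sizes[i] == 0L && sizes[j] == 0L) { v[i, j] <- v[j, i] <- 0; next }
      shared <- sum(si %in% sets[[j]])
      v[i, j] <- v[j, i] <- shared / (sizes[i] + sizes[j] - shared)
    }
  }
  dimnames(v) <- list(drugs, drugs)
  DrugSimMatrix(v, scale = "unit")
}

#' Atom-pair feature tokens of a structure
#'
#' Computes the set of atom-pair descriptors of a molecule given as SMILES —
#' each token encodes two typed heavy atoms plus their topological distance —
#' using the ChemmineR/ChemmineOB toolchain.  Deterministic for a given
#' structure; a molecule with fewer than two heavy atoms yields the empty set
#' (downstream Tanimoto treats it under its empty-set rule).
#'
#' Precomputed tokens can be supplied to [buildProfileDSN()] directly via a
#' feature-pair table instead, keeping the pipeline independent of a
#' chemistry toolkit.
#'
#' @param smiles a single SMILES string.
#' @return character vector of distinct atom-pair tokens (kind
#'   `"atom_pair"`).
#' @export
atomPairFeatures <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE))
    stop("atomPairFeatures needs the ChemmineR and ChemmineOB packages; ",
         "supply precomputed atom-pair tokens instead")
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(c(mol = smiles))),
    error = function(e) stop("unparsable SMILES '", smiles, "': ",
                             conditionMessage(e)))
  n_atoms <- tryCatch(nrow(ChemmineR::atomblock(sdf[[1L]])),
                      error = function(e) 0L)
  if (is.null(n_atoms) || n_atoms < 2L) return(character())
  ap <- tryCatch(
    suppressWarnings(ChemmineR::sdf2ap(sdf)),
    error = function(e) stop("unparsable SMILES '", smiles, "': ",
                             conditionMessage(e)))
  codes <- ChemmineR::ap(ap)[[1L]]
  # sdf2ap signals a failed compound as the single numeric code 1
  if (length(codes) == 1L && codes == 1)
    stop("unparsable SMILES '", smiles, "'")
  unique(paste0("ap:", format(codes, scientific = FALSE, trim = TRUE)))
}

#' Atom-pair profiles for a table of SMILES
#'
#' Vectorized convenience over [atomPairFeatures()].
#'
#' @param smiles named character vector of SMILES (names = drug ids).
#' @return a [FeatureProfileSet-class] of kind `"atom_pair"`.
#' @export
atomPairProfiles <- function(smiles) {
  if (is.null(names(smiles)) || anyDuplicated(names(smiles)))
    stop("SMILES must be named by unique drug ids")
  sets <- lapply(smiles, atomPairFeatures)
  pairs <- data.frame(
    drug_id = rep(names(sets), lengths(sets)),
    feature = unlist(sets, use.names = FALSE),
    stringsAsFactors = FALSE)
  FeatureProfileSet(pairs, kind = "atom_pair", drugs = names(smiles))
}
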