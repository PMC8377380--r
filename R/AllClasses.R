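#' @useDynLib dsnfuse, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

## First-level letters of the Anatomical Therapeutic Chemical classification.
ATC_FIRST_LEVELS <- c("A", "B", "C", "D", "G", "H", "J", "L",
                      "M", "N", "P", "R", "S", "V")

#' DrugRegistry: drug identities and label vocabularies
#'
#' Holds, per drug, the opaque identifier, a display name, the set of ATC
#' codes (each reducible to one of the 14 first-level letters) and an optional
#' chemical superclass label.  The registry is the source of the ATC label
#' vector used by partition evaluation ([nmi()], [aor()]) and of the term
#' vocabularies used by cluster enrichment ([annotateClusters()]).
#'
#' Drugs with an empty ATC set are legal registry members: they are excluded
#' from ATC-based metrics but never dropped from networks.
#'
#' @slot table data.frame with columns `drug_id`, `name`, `superclass`
#'   (`NA` allowed for superclass); one row per drug, `drug_id` unique.
#' @slot atc named list (names = `drug_id`) of character vectors of ATC codes;
#'   possibly empty vectors.
#' @export
setClass("DrugRegistry",
  representation(table = "data.frame", atc = "list"))

setValidity("DrugRegistry", function(object) {
  tab <- object@table
  msgs <- character()
  need <- c("drug_id", "name", "superclass")
  if (!all(need %in% names(tab)))
    return(paste("registry table must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(tab$drug_id)) {
    dup <- unique(tab$drug_id[duplicated(tab$drug_id)])
    msgs <- c(msgs, paste("duplicate drug_id:", paste(dup, collapse = ", ")))
  }
  if (!identical(sort(names(object@atc)), sort(as.character(tab$drug_id))))
    msgs <- c(msgs, "atc list names must match drug_id column")
  first <- substr(unlist(object@atc, use.names = FALSE), 1L, 1L)
  bad <- setdiff(unique(first), ATC_FIRST_LEVELS)
  if (length(bad))
    msgs <- c(msgs, paste("invalid ATC first level(s):", paste(bad, collapse = ", ")))
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' FeatureProfileSet: per-drug discrete feature sets
#'
#' A sparse collection of (drug, feature) pairs of a single kind — clinical
#' side-effect terms or chemical atom-pair tokens — optionally carrying a
#' frequency in \[0, 1\] per pair.  Feature sets feed the Tanimoto similarity
#' of [buildProfileDSN()].
#'
#' @slot kind `"side_effect"` or `"atom_pair"`.
#' @slot pairs data.frame with columns `drug_id`, `feature`, `frequency`
#'   (numeric, `NA` when unknown); no duplicated (drug, feature) pair.
#' @slot drugs character vector of drug ids in first-appearance order; may
#'   include drugs whose profile is empty (e.g. after term filtering).
#' @export
setClass("FeatureProfileSet",
  representation(kind = "character", pairs = "data.frame", drugs = "character"))

setValidity("FeatureProfileSet", function(object) {
  msgs <- character()
  if (length(object@kind) != 1L || !object@kind %in% c("side_effect", "atom_pair"))
    msgs <- c(msgs, "kind must be 'side_effect' or 'atom_pair'")
  p <- object@pairs
  if (!all(c("drug_id", "feature", "frequency") %in% names(p)))
    msgs <- c(msgs, "pairs must have columns drug_id, feature, frequency")
  else {
    if (anyDuplicated(p[c("drug_id", "feature")]))
      msgs <- c(msgs, "duplicated (drug_id, feature) pairs")
    fr <- p$frequency[!is.na(p$frequency)]
    if (length(fr) && (any(fr < 0) || any(fr > 1)))
      msgs <- c(msgs, "frequencies must lie in [0, 1]")
    if (!all(p$drug_id %in% object@drugs))
      msgs <- c(msgs, "pairs reference drugs absent from the drug vector")
  }
  if (anyDuplicated(object@drugs))
    msgs <- c(msgs, "duplicate drug ids")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' DrugSimMatrix: symmetric drug-by-drug similarity scores
#'
#' The common currency of every fusion, clustering and ranking stage.  Two
#' scales exist: `"unit"` matrices have entries in \[0, 1\] with unit diagonal
#' (the single-property networks); `"affinity"` matrices are the non-negative
#' symmetric outputs of network fusion, whose rows are not bounded by 1.
#'
#' @slot values square numeric matrix with identical row/column names (the
#'   drug ids, no duplicates); symmetric and non-negative.
#' @slot scale `"unit"` or `"affinity"`.
#' @export
setClass("DrugSimMatrix",
  representation(values = "matrix", scale = "character"))

setValidity("DrugSimMatrix", function(object) {
  v <- object@values
  msgs <- character()
  if (length(object@scale) != 1L || !object@scale %in% c("unit", "affinity"))
    msgs <- c(msgs, "scale must be 'unit' or 'affinity'")
  if (nrow(v) != ncol(v))
    return("matrix must be square")
  if (is.null(rownames(v)) || is.null(colnames(v)) ||
      !identical(rownames(v), colnames(v)))
    msgs <- c(msgs, "row and column names must be identical drug ids")
  else if (anyDuplicated(rownames(v)))
    msgs <- c(msgs, "duplicate drug ids")
  if (any(!is.finite(v)))
    msgs <- c(msgs, "entries must be finite")
  else {
    if (any(v < 0)) msgs <- c(msgs, "entries must be non-negative")
    if (max(abs(v - t(v))) > 1e-9) msgs <- c(msgs, "matrix must be symmetric")
    if (identical(object@scale, "unit")) {
      if (any(v > 1 + 1e-9)) msgs <- c(msgs, "unit-scale entries must be <= 1")
      if (nrow(v) && max(abs(diag(v) - 1)) > 1e-9)
        msgs <- c(msgs, "unit-scale diagonal must be 1")
    }
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' ClusterAssignment: drug-to-cluster labeling
#'
#' Maps every drug of a network to exactly one of `k` non-empty clusters
#' (integer labels `1..k`).  Compared against ATC labels by [nmi()] and
#' [rogersTanimoto()], and annotated by [annotateClusters()].
#'
#' @slot labels named integer vector; names are drug ids, values in `1..k`.
#' @slot k integer number of clusters.
#' @export
setClass("ClusterAssignment",
  representation(labels = "integer", k = "integer"))

setValidity("ClusterAssignment", function(object) {
  msgs <- character()
  lab <- object@labels
  k <- object@k
  if (length(k) != 1L || is.na(k) || k < 1L)
    return("k must be a single positive integer")
  if (is.null(names(lab)) || anyDuplicated(names(lab)))
    msgs <- c(msgs, "labels must be named by unique drug ids")
  if (any(is.na(lab)) || any(lab < 1L) || any(lab > k))
    msgs <- c(msgs, "labels must lie in 1..k")
  else if (length(lab) && !all(seq_len(k) %in% lab))
    msgs <- c(msgs, "every cluster 1..k must be non-empty")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' FusionResult: an integrated drug similarity network
#'
#' Wraps the fused matrix together with the method that produced it, the
#' parameters used and the ordered names of the input views, so downstream
#' attribution can recover which single-property networks fed the fusion.
#'
#' @slot fused [DrugSimMatrix-class] holding the integrated network.
#' @slot method one of `"snf"`, `"max"`, `"wavg"`, `"disjunction"`.
#' @slot params named list echoing the fusion parameters (eta/K/T or weights).
#' @slot views character vector of input view names, in input order.
#' @export
setClass("FusionResult",
  representation(fused = "DrugSimMatrix", method = "character",
                 params = "list", views = "character"))

setValidity("FusionResult", function(object) {
  if (length(object@method) != 1L ||
      !object@method %in% c("snf", "max", "wavg", "disjunction"))
    return("method must be one of snf, max, wavg, disjunction")
  TRUE
})

#' AlignmentScoring: parameters of the Smith-Waterman kernel
#'
#' Substitution matrix plus affine gap penalties for local protein alignment.
#' A gap of length L costs `gapOpen + (L - 1) * gapExtend` (the convention of
#' the EMBOSS water tool, whose defaults — BLOSUM62, 10, 0.5 — are also the
#' defaults here).
#'
#' @slot substitution numeric substitution matrix with single-letter residue
#'   dimnames; must cover every residue aligned.
#' @slot gapOpen positive penalty for opening a gap.
#' @slot gapExtend positive penalty per additional gap position.
#' @slot name display name of the substitution matrix.
#' @export
setClass("AlignmentScoring",
  representation(substitution = "matrix", gapOpen = "numeric",
                 gapExtend = "numeric", name = "character"))

setValidity("AlignmentScoring", function(object) {
  m <- object@substitution
  msgs <- character()
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    msgs <- c(msgs, "substitution matrix must have identical row/column names")
  if (length(object@gapOpen) != 1L || object@gapOpen <= 0)
    msgs <- c(msgs, "gapOpen must be a single positive number")
  if (length(object@gapExtend) != 1L || object@gapExtend <= 0)
    msgs <- c(msgs, "gapExtend must be a single positive number")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})
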