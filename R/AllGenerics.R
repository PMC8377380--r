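#' Drug identifiers of an object
#'
#' Ordered drug ids carried by a registry, profile set, similarity matrix or
#' cluster assignment.  Order is meaningful: readers preserve first-appearance
#' order, and fusion requires identical order across views.
#'
#' @param x a dsnfuse data object.
#' @return character vector of drug ids.
#' @export
setGeneric("drugIds", function(x) standardGeneric("drugIds"))

#' @rdname drugIds
#' @export
setMethod("drugIds", "DrugRegistry", function(x) x@table$drug_id)

#' @rdname drugIds
#' @export
setMethod("drugIds", "FeatureProfileSet", function(x) x@drugs)

#' @rdname drugIds
#' @export
setMethod("drugIds", "DrugSimMatrix", function(x) rownames(x@values))

#' @rdname drugIds
#' @export
setMethod("drugIds", "ClusterAssignment", function(x) names(x@labels))

#' Similarity values and scale
#'
#' `simValues()` returns the dense symmetric score matrix of a
#' [DrugSimMatrix-class]; `simScale()` returns its scale
#' (`"unit"` or `"affinity"`).
#'
#' @param x a [DrugSimMatrix-class].
#' @return numeric matrix, or a length-one character for `simScale`.
#' @export
setGeneric("simValues", function(x) standardGeneric("simValues"))

#' @rdname simValues
#' @export
setMethod("simValues", "DrugSimMatrix", function(x) x@values)

#' @rdname simValues
#' @export
setGeneric("simScale", function(x) standardGeneric("simScale"))

#' @rdname simValues
#' @export
setMethod("simScale", "DrugSimMatrix", function(x) x@scale)

#' Per-drug feature sets of a profile collection
#'
#' @param x a [FeatureProfileSet-class].
#' @return named list of character vectors (one set per drug, in drug order;
#'   empty profiles are zero-length elements).
#' @export
setGeneric("featureSets", function(x) standardGeneric("featureSets"))

#' @rdname featureSets
#' @export
setMethod("featureSets", "FeatureProfileSet", function(x) {
  sets <- split(x@pairs$feature, factor(x@pairs$drug_id, levels = x@drugs))
  lapply(sets, as.character)
})

#' @rdname featureSets
#' @export
setGeneric("profileKind", function(x) standardGeneric("profileKind"))

#' @rdname featureSets
#' @export
setMethod("profileKind", "FeatureProfileSet", function(x) x@kind)

#' Cluster labels and cluster count
#'
#' @param x a [ClusterAssignment-class].
#' @return `clusterLabels`: named integer vector of labels in `1..k`;
#'   `numClusters`: the integer `k`.
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname clusterLabels
#' @export
setMethod("clusterLabels", "ClusterAssignment", function(x) x@labels)

#' @rdname clusterLabels
#' @export
setGeneric("numClusters", function(x) standardGeneric("numClusters"))

#' @rdname clusterLabels
#' @export
setMethod("numClusters", "ClusterAssignment", function(x) x@k)

#' ATC codes, first-level reductions and superclasses of a registry
#'
#' `atcCodes()` returns the raw code sets, `atcFirstLevels()` their reduction
#' to unique first-level letters (the label used throughout evaluation and
#' enrichment), `superclasses()` the superclass label per drug (`NA` when
#' unknown).
#'
#' @param x a [DrugRegistry-class].
#' @return named list of character vectors, or a named character vector for
#'   `superclasses`.
#' @export
setGeneric("atcCodes", function(x) standardGeneric("atcCodes"))

#' @rdname atcCodes
#' @export
setMethod("atcCodes", "DrugRegistry", function(x) x@atc[x@table$drug_id])

#' @rdname atcCodes
#' @export
setGeneric("atcFirstLevels", function(x) standardGeneric("atcFirstLevels"))

#' @rdname atcCodes
#' @export
setMethod("atcFirstLevels", "DrugRegistry", function(x) {
  lapply(atcCodes(x), function(codes) unique(substr(codes, 1L, 1L)))
})

#' @rdname atcCodes
#' @export
setGeneric("superclasses", function(x) standardGeneric("superclasses"))

#' @rdname atcCodes
#' @export
setMethod("superclasses", "DrugRegistry", function(x) {
  stats::setNames(as.character(x@table$superclass), x@table$drug_id)
})

#' Components of a fusion result
#'
#' @param x a [FusionResult-class].
#' @return `fusedMatrix`: the integrated [DrugSimMatrix-class];
#'   `fusionMethod`: the method string; `fusionParams`: the parameter list;
#'   `fusionViews`: the ordered input view names.
#' @export
setGeneric("fusedMatrix", function(x) standardGeneric("fusedMatrix"))

#' @rdname fusedMatrix
#' @export
setMethod("fusedMatrix", "FusionResult", function(x) x@fused)

#' @rdname fusedMatrix
#' @export
setGeneric("fusionMethod", function(x) standardGeneric("fusionMethod"))

#' @rdname fusedMatrix
#' @export
setMethod("fusionMethod", "FusionResult", function(x) x@method)

#' @rdname fusedMatrix
#' @export
setGeneric("fusionParams", function(x) standardGeneric("fusionParams"))

#' @rdname fusedMatrix
#' @export
setMethod("fusionParams", "FusionResult", function(x) x@params)

#' @rdname fusedMatrix
#' @export
setGeneric("fusionViews", function(x) standardGeneric("fusionViews"))

#' @rdname fusedMatrix
#' @export
setMethod("fusionViews", "FusionResult", function(x) x@views)

setMethod("show", "DrugRegistry", function(object) {
  n <- nrow(object@table)
  n_atc <- sum(lengths(object@atc[object@table$drug_id]) > 0)
  cat("DrugRegistry with", n, "drugs (", n_atc, "with ATC codes )\n")
  if (n) {
    head_ids <- utils::head(object@table$drug_id, 5L)
    cat("  drugs:", paste(head_ids, collapse = ", "),
        if (n > 5L) "..." else "", "\n")
  }
})

setMethod("show", "FeatureProfileSet", function(object) {
  cat("FeatureProfileSet of kind", sQuote(object@kind), "\n")
  cat(" ", length(object@drugs), "drugs,",
      length(unique(object@pairs$feature)), "distinct features,",
      nrow(object@pairs), "pairs\n")
})

setMethod("show", "DrugSimMatrix", function(object) {
  n <- nrow(object@values)
  cat("DrugSimMatrix (", object@scale, " scale ) with ", n, " drugs\n", sep = "")
  if (n > 1) {
    off <- object@values[upper.tri(object@values)]
    cat(sprintf("  off-diagonal range: [%.4g, %.4g]\n", min(off), max(off)))
  }
})

setMethod("show", "ClusterAssignment", function(object) {
  cat("ClusterAssignment:", length(object@labels), "drugs in",
      object@k, "clusters\n")
  sizes <- tabulate(object@labels, object@k)
  cat("  cluster sizes:", paste(sizes, collapse = ", "), "\n")
})

setMethod("show", "FusionResult", function(object) {
  cat("FusionResult (method =", object@method, ") over views:",
      paste(object@views, collapse = ", "), "\n")
  show(object@fused)
})

setMethod("show", "AlignmentScoring", function(object) {
  cat("AlignmentScoring:", object@name,
      sprintf("(gapOpen = %g, gapExtend = %g)\n", object@gapOpen, object@gapExtend))
})
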