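#' Construct a DrugRegistry
#'
#' @param drug_id character vector of unique drug identifiers.
#' @param name display names (recycled drug_id if missing).
#' @param atc_codes list of character vectors of ATC codes (one element per
#'   drug, possibly empty), or a character vector of semicolon-separated
#'   codes.  Every code must start with a valid first-level letter.
#' @param superclass optional character vector of superclass labels (`NA`
#'   allowed).
#' @return a [DrugRegistry-class].
#' @examples
#' reg <- DrugRegistry(c("d1", "d2"), atc_codes = list("N02", c("A01", "C03")))
#' atcFirstLevels(reg)
#' @export
DrugRegistry <- function(drug_id, name = drug_id, atc_codes = NULL,
                         superclass = NA_character_) {
  drug_id <- as.character(drug_id)
  if (is.null(atc_codes)) atc_codes <- rep(list(character()), length(drug_id))
  if (is.character(atc_codes))
    atc_codes <- strsplit(atc_codes, ";", fixed = TRUE)
  atc_codes <- lapply(atc_codes, function(a) {
    a <- as.character(a[!is.na(a)])
    a[nzchar(trimws(a))]
  })
  if (length(atc_codes) != length(drug_id))
    stop("atc_codes must have one element per drug")
  names(atc_codes) <- drug_id
  tab <- data.frame(drug_id = drug_id,
                    name = as.character(rep_len(name, length(drug_id))),
                    superclass = as.character(rep_len(superclass, length(drug_id))),
                    stringsAsFactors = FALSE)
  new("DrugRegistry", table = tab, atc = atc_codes)
}

#' Construct a FeatureProfileSet
#'
#' @param pairs data.frame with columns `drug_id`, `feature` and optionally
#'   `frequency`.  Duplicated (drug, feature) pairs are collapsed with a
#'   warning (set semantics); the first frequency is kept.
#' @param kind `"side_effect"` or `"atom_pair"`.
#' @param drugs optional character vector fixing the drug universe/order;
#'   defaults to first-appearance order in `pairs`.  Drugs listed here but
#'   absent from `pairs` get empty profiles.
#' @return a [FeatureProfileSet-class].
#' @export
FeatureProfileSet <- function(pairs, kind = c("side_effect", "atom_pair"),
                              drugs = NULL) {
  kind <- match.arg(kind)
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (!all(c("drug_id", "feature") %in% names(pairs)))
    stop("pairs must have columns drug_id and feature")
  if (is.null(pairs$frequency)) pairs$frequency <- NA_real_
  pairs$drug_id <- as.character(pairs$drug_id)
  pairs$feature <- as.character(pairs$feature)
  pairs$frequency <- as.numeric(pairs$frequency)
  fr <- pairs$frequency[!is.na(pairs$frequency)]
  if (length(fr) && (any(fr < 0) || any(fr > 1)))
    stop("frequency values must lie in [0, 1]")
  dup <- duplicated(pairs[c("drug_id", "feature")])
  if (any(dup)) {
    warning(sum(dup), " duplicated (drug, feature) pair(s) collapsed")
    pairs <- pairs[!dup, , drop = FALSE]
  }
  if (is.null(drugs)) drugs <- unique(pairs$drug_id)
  drugs <- as.character(drugs)
  if (!all(pairs$drug_id %in% drugs))
    stop("pairs reference drugs absent from the supplied drug vector")
  rownames(pairs) <- NULL
  new("FeatureProfileSet", kind = kind,
      pairs = pairs[c("drug_id", "feature", "frequency")], drugs = drugs)
}

#' Construct a DrugSimMatrix
#'
#' Checks symmetry within `tol` and then symmetrizes exactly as
#' `(M + t(M)) / 2`.
#'
#' @param values square numeric matrix; dimnames taken from `drugs` if given.
#' @param drugs optional drug ids (defaults to existing rownames).
#' @param scale `"unit"` or `"affinity"`.
#' @param tol maximum tolerated asymmetry before an error is raised.
#' @return a [DrugSimMatrix-class].
#' @export
DrugSimMatrix <- function(values, drugs = rownames(values),
                          scale = c("unit", "affinity"), tol = 1e-9) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("similarity matrix must be square")
  if (is.null(drugs)) stop("drug ids required (rownames or 'drugs')")
  drugs <- as.character(drugs)
  if (length(drugs) != nrow(values)) stop("length(drugs) != nrow(values)")
  gap <- max(abs(values - t(values)), 0)
  if (gap > tol)
    stop(sprintf("matrix asymmetric beyond tolerance (max gap %.3g > %.3g)", gap, tol))
  values <- (values + t(values)) / 2
  dimnames(values) <- list(drugs, drugs)
  new("DrugSimMatrix", values = values, scale = scale)
}

#' Construct a ClusterAssignment
#'
#' @param labels vector of cluster labels, named by drug id (any label type;
#'   converted to integers `1..k` in order of first appearance if not already
#'   integer-like in that range).
#' @param drugs optional drug ids when `labels` is unnamed.
#' @param k optional number of clusters; defaults to `max(labels)` after
#'   integer coercion.
#' @return a [ClusterAssignment-class].
#' @export
ClusterAssignment <- function(labels, drugs = names(labels), k = NULL) {
  if (is.null(drugs)) stop("drug ids required (names of labels or 'drugs')")
  drugs <- as.character(drugs)
  if (length(drugs) != length(labels)) stop("length(drugs) != length(labels)")
  if (is.numeric(labels) && all(labels == as.integer(labels))) {
    lab <- as.integer(labels)
  } else {
    lab <- as.integer(factor(labels, levels = unique(labels)))
  }
  if (is.null(k)) k <- max(lab, 0L)
  names(lab) <- drugs
  new("ClusterAssignment", labels = lab, k = as.integer(k))
}
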