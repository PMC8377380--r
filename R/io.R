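#' Read a drug registry from TSV
#'
#' Expects tab-separated columns `drug_id`, `name`, `atc_codes`
#' (semicolon-separated, possibly empty) and `superclass`.  Row order is
#' preserved.  A duplicated `drug_id` or an ATC code whose first letter is not
#' a valid first-level letter is a hard error (the error names the offending
#' id / row).
#'
#' @param path path to the TSV file.
#' @return a [DrugRegistry-class].
#' @export
readDrugRegistry <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", na.strings = NULL,
                           quote = "", comment.char = "")
  need <- c("drug_id", "name", "atc_codes", "superclass")
  if (!all(need %in% names(tab)))
    stop("registry file must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$drug_id)) {
    dup <- unique(tab$drug_id[duplicated(tab$drug_id)])
    stop("duplicate drug_id in registry: ", paste(dup, collapse = ", "))
  }
  codes <- strsplit(tab$atc_codes, ";", fixed = TRUE)
  for (i in seq_along(codes)) {
    ci <- trimws(codes[[i]])
    ci <- ci[nzchar(ci)]
    bad <- ci[!substr(ci, 1L, 1L) %in% ATC_FIRST_LEVELS]
    if (length(bad))
      stop(sprintf("malformed ATC code '%s' in registry row %d", bad[1L], i))
    codes[[i]] <- ci
  }
  sc <- tab$superclass
  sc[!nzchar(sc)] <- NA_character_
  DrugRegistry(tab$drug_id, name = tab$name, atc_codes = codes, superclass = sc)
}

#' Write a drug registry to TSV
#'
#' @param registry a [DrugRegistry-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeDrugRegistry <- function(registry, path) {
  tab <- registry@table
  tab$atc_codes <- vapply(atcCodes(registry), paste, "", collapse = ";")
  tab$superclass[is.na(tab$superclass)] <- ""
  utils::write.table(tab[c("drug_id", "name", "atc_codes", "superclass")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read sparse feature profiles from TSV
#'
#' Expects two or three tab-separated columns: `drug_id`, `feature` and an
#' optional `frequency` in \[0, 1\].  Pairs are aggregated into per-drug sets
#' (duplicates collapse with a warning); drug order is first-appearance order.
#'
#' @param path path to the TSV file.
#' @param kind `"side_effect"` or `"atom_pair"`.
#' @return a [FeatureProfileSet-class].
#' @export
readFeatureProfiles <- function(path, kind = c("side_effect", "atom_pair")) {
  kind <- match.arg(kind)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           na.strings = c("NA", ""), quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("feature-profile file needs at least drug_id and feature columns")
  names(tab)[1:2] <- c("drug_id", "feature")
  if (ncol(tab) >= 3L) names(tab)[3L] <- "frequency"
  FeatureProfileSet(tab, kind = kind)
}

#' Write sparse feature profiles to TSV
#'
#' @param profiles a [FeatureProfileSet-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeFeatureProfiles <- function(profiles, path) {
  utils::write.table(profiles@pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a similarity matrix as dense TSV
#'
#' The on-disk format is a dense tab-separated matrix with a header row and a
#' leading `drug_id` column.  On read, the matrix must be square with matching
#' row/column ids, non-negative, and symmetric within `1e-9`; it is then
#' symmetrized exactly as `(M + t(M)) / 2`.  Values are written with 12
#' significant digits, so `readSimilarityMatrix(writeSimilarityMatrix(M))`
#' reproduces `M` to that precision.
#'
#' @param path file path.
#' @param scale matrix scale recorded in the returned object.
#' @return a [DrugSimMatrix-class] (reader) or `path`, invisibly (writer).
#' @export
readSimilarityMatrix <- function(path, scale = c("unit", "affinity")) {
  scale <- match.arg(scale)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "", check.names = FALSE,
                           stringsAsFactors = FALSE)
  ids <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m))
    stop("similarity matrix file is not square: ", nrow(m), " x ", ncol(m))
  if (!identical(ids, colnames(m)))
    stop("row ids and column header of the matrix file disagree")
  if (any(!is.finite(m))) stop("non-numeric or non-finite matrix entries")
  if (any(m < 0)) stop("negative matrix entries")
  rownames(m) <- ids
  DrugSimMatrix(m, scale = scale)   # symmetry check + exact symmetrization
}

#' @rdname readSimilarityMatrix
#' @param matrix a [DrugSimMatrix-class] to write.
#' @export
writeSimilarityMatrix <- function(matrix, path) {
  v <- simValues(matrix)
  out <- cbind(drug_id = rownames(v),
               as.data.frame(signif(v, 12), check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a cluster assignment as TSV
#'
#' Two tab-separated columns: `drug_id` and integer `cluster`.
#'
#' @param path file path.
#' @return a [ClusterAssignment-class] (reader) or `path`, invisibly (writer).
#' @export
readClusterAssignment <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  if (!all(c("drug_id", "cluster") %in% names(tab)))
    stop("cluster file must have columns drug_id and cluster")
  ClusterAssignment(as.integer(tab$cluster), drugs = as.character(tab$drug_id))
}

#' @rdname readClusterAssignment
#' @param assignment a [ClusterAssignment-class] to write.
#' @export
writeClusterAssignment <- function(assignment, path) {
  utils::write.table(
    data.frame(drug_id = drugIds(assignment),
               cluster = unname(clusterLabels(assignment))),
    path, sep = "\t", quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a drug-to-target map from TSV
#'
#' Two tab-separated columns: `drug_id`, `protein_id`.  Rows aggregate into
#' per-drug protein sets (first-appearance drug order).
#'
#' @param path file path.
#' @return named list of character vectors of protein ids.
#' @export
readTargetMap <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  if (!all(c("drug_id", "protein_id") %in% names(tab)))
    stop("target map must have columns drug_id and protein_id")
  drugs <- unique(as.character(tab$drug_id))
  sets <- split(as.character(tab$protein_id),
                factor(tab$drug_id, levels = drugs))
  lapply(sets, unique)
}

#' Write a drug-to-target map to TSV
#'
#' @param targetMap named list of protein-id vectors.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeTargetMap <- function(targetMap, path) {
  tab <- data.frame(
    drug_id = rep(names(targetMap), lengths(targetMap)),
    protein_id = unlist(targetMap, use.names = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' Thin wrapper over [Biostrings::readAAStringSet()]; sequences are
#' upper-cased and validated to the single-letter amino-acid alphabet
#' (unknown residues only as `X`).
#'
#' @param path FASTA file path.
#' @return a [Biostrings::AAStringSet] named by protein id.
#' @export
readSequenceDB <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  up <- toupper(as.character(seqs))
  if (any(!nzchar(up))) stop("empty sequence(s) in ", path)
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", up)
  if (any(bad))
    stop("non-IUPAC residue in sequence(s): ",
         paste(names(seqs)[bad], collapse = ", "))
  Biostrings::AAStringSet(stats::setNames(up, names(seqs)))
}

#' Read drug structures as SMILES from TSV
#'
#' Two tab-separated columns: `drug_id`, `smiles`.
#'
#' @param path file path.
#' @return named character vector of SMILES strings.
#' @export
readSmiles <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  if (!all(c("drug_id", "smiles") %in% names(tab)))
    stop("SMILES file must have columns drug_id and smiles")
  if (anyDuplicated(tab$drug_id))
    stop("duplicate drug_id in SMILES file")
  stats::setNames(as.character(tab$smiles), as.character(tab$drug_id))
}
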