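#' Create an alignment scoring scheme
#'
#' Builds the [AlignmentScoring-class] behind the Smith-Waterman kernel of
#' target-based drug similarity.  Defaults follow the EMBOSS water protein
#' defaults: BLOSUM62, gap-open 10, gap-extend 0.5.  Alternatively a uniform
#' match/mismatch scheme over the amino-acid alphabet can be requested, or an
#' arbitrary substitution matrix supplied.
#'
#' @param substitution name of a substitution matrix shipped with Biostrings
#'   (e.g. `"BLOSUM62"`, `"BLOSUM50"`, `"PAM250"`), or a numeric matrix with
#'   residue dimnames.
#' @param gapOpen,gapExtend positive affine gap penalties; a gap of length L
#'   costs `gapOpen + (L - 1) * gapExtend`.
#' @param match,mismatch if both given, override `substitution` with a
#'   uniform matrix (`match` on the diagonal, `mismatch` off it) over the
#'   20 standard residues plus `X`.
#' @return an [AlignmentScoring-class].
#' @examples
#' sc <- alignmentScoring(match = 1, mismatch = -1, gapOpen = 1, gapExtend = 1)
#' smithWaterman("AAA", "AAA", sc)  # 3
#' @export
alignmentScoring <- function(substitution = "BLOSUM62", gapOpen = 10,
                             gapExtend = 0.5, match = NULL, mismatch = NULL) {
  if (!is.null(match) || !is.null(mismatch)) {
    if (is.null(match) || is.null(mismatch))
      stop("supply both match and mismatch, or neither")
    alpha <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], "X")
    m <- matrix(mismatch, length(alpha), length(alpha),
                dimnames = list(alpha, alpha))
    diag(m) <- match
    name <- sprintf("match/mismatch (%g/%g)", match, mismatch)
  } else if (is.character(substitution)) {
    name <- substitution
    env <- new.env()
    utils::data(list = substitution, package = "Biostrings", envir = env)
    m <- get(substitution, envir = env)
  } else {
    m <- as.matrix(substitution)
    name <- "custom"
  }
  new("AlignmentScoring", substitution = m, gapOpen = as.numeric(gapOpen),
      gapExtend = as.numeric(gapExtend), name = name)
}

# Map a residue string to 0-based indices into the substitution matrix,
# erroring on residues the matrix does not define.
encodeResidues <- function(seq, alphabet) {
  chars <- strsplit(toupper(seq), "")[[1L]]
  idx <- match(chars, alphabet)
  if (anyNA(idx))
    stop("residue(s) outside the scoring alphabet: ",
         paste(unique(chars[is.na(idx)]), collapse = ", "))
  idx - 1L
}

#' Smith-Waterman local alignment score
#'
#' Optimal local-alignment score under affine gap penalties, computed by the
#' Gotoh dynamic program (compiled).  Symmetric in its arguments; never
#' negative (the empty alignment scores 0).
#'
#' @param seq1,seq2 non-empty residue strings (or `AAString`s).
#' @param scoring an [AlignmentScoring-class]; defaults to BLOSUM62 with
#'   gap-open 10 and gap-extend 0.5.
#' @return a single non-negative numeric score.
#' @examples
#' smithWaterman("HEAGAWGHEE", "PAWHEAE", alignmentScoring())
#' @export
smithWaterman <- function(seq1, seq2, scoring = alignmentScoring()) {
  stopifnot(is(scoring, "AlignmentScoring"))
  seq1 <- as.character(seq1); seq2 <- as.character(seq2)
  if (!nzchar(seq1) || !nzchar(seq2)) stop("sequences must be non-empty")
  alpha <- rownames(scoring@substitution)
  sw_score_cpp(encodeResidues(seq1, alpha), encodeResidues(seq2, alpha),
               scoring@substitution, scoring@gapOpen, scoring@gapExtend)
}

#' Normalized target-set similarity between two drugs
#'
#' The target-based similarity of two drugs is the mean, over all pairs of
#' their target proteins, of the Smith-Waterman score normalized by the
#' geometric mean of the two self-alignment scores:
#' \deqn{S = \frac{1}{|P^a||P^b|} \sum_i \sum_j
#'   \frac{SW(p_i, q_j)}{\sqrt{SW(p_i, p_i)\,SW(q_j, q_j)}}}
#' so a drug is always similarity 1 to itself.  The product-normalization
#' variant (`normalization = "product"`, dividing by
#' \eqn{SW(p_i,p_i) SW(q_j,q_j)}) is selectable.  Scores are clipped to
#' \[0, 1\].
#'
#' @param pa,pb non-empty character vectors of protein ids.
#' @param db named character vector or `AAStringSet` of protein sequences;
#'   every id in `pa`/`pb` must resolve.
#' @param scoring an [AlignmentScoring-class].
#' @param normalization `"geometric"` (default) or `"product"`.
#' @param cache optional environment memoizing SW scores across calls
#'   (used by [buildTargetDSN()]).
#' @return similarity in \[0, 1\].
#' @export
targetSimilarity <- function(pa, pb, db, scoring = alignmentScoring(),
                             normalization = c("geometric", "product"),
                             cache = NULL) {
  normalization <- match.arg(normalization)
  db <- sequenceVector(db)
  if (!length(pa) || !length(pb)) stop("target sets must be non-empty")
  missing <- setdiff(unique(c(pa, pb)), names(db))
  if (length(missing))
    stop("unresolvable protein id(s): ", paste(missing, collapse = ", "))
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  total <- 0
  for (p in pa) {
    sp <- cachedSW(p, p, db, scoring, cache)
    for (q in pb) {
      sq <- cachedSW(q, q, db, scoring, cache)
      cross <- cachedSW(p, q, db, scoring, cache)
      denom <- if (normalization == "geometric") sqrt(sp * sq) else sp * sq
      if (denom <= 0) stop("non-positive self-alignment score for ", p, "/", q)
      total <- total + cross / denom
    }
  }
  min(max(total / (length(pa) * length(pb)), 0), 1)
}

sequenceVector <- function(db) {
  if (methods::is(db, "XStringSet")) db <- as.character(db)
  if (is.null(names(db))) stop("sequence database must be named by protein id")
  db
}

cachedSW <- function(p, q, db, scoring, cache) {
  key <- if (p <= q) paste(p, q, sep = "\r") else paste(q, p, sep = "\r")
  hit <- get0(key, envir = cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  val <- smithWaterman(db[[p]], db[[q]], scoring)
  assign(key, val, envir = cache)
  val
}

#' Build the target-based drug similarity network
#'
#' Pairwise [targetSimilarity()] over all drugs of a target map, with every
#' Smith-Waterman score (self- and cross-alignments) computed once and
#' cached.  The diagonal is forced to exactly 1.
#'
#' @param targetMap named list of non-empty protein-id vectors (one per drug,
#'   in network order).
#' @param db protein sequences (named character vector or `AAStringSet`).
#' @param scoring an [AlignmentScoring-class].
#' @param normalization see [targetSimilarity()].
#' @return a unit-scale [DrugSimMatrix-class].
#' @export
buildTargetDSN <- function(targetMap, db, scoring = alignmentScoring(),
                           normalization = c("geometric", "product")) {
  normalization <- match.arg(normalization)
  drugs <- names(targetMap)
  if (is.null(drugs) || anyDuplicated(drugs))
    stop("target map must be named by unique drug ids")
  if (length(drugs) < 2L) stop("need at least two drugs")
  if (any(lengths(targetMap) == 0L))
    stop("every drug entering target similarity needs at least one target")
  db <- sequenceVector(db)
  cache <- new.env(parent = emptyenv())
  n <- length(drugs)
  v <- diag(1, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      v[i, j] <- v[j, i] <- targetSimilarity(
        targetMap[[i]], targetMap[[j]], db, scoring,
        normalization = normalization, cache = cache)
    }
  }
  dimnames(v) <- list(drugs, drugs)
  DrugSimMatrix(v, scale = "unit")
}
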