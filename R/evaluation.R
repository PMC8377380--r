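# Partition and ranking quality statistics: NMI, ATC/superclass overlap
# rates, Rogers-Tanimoto agreement, and the sliding-bin overlap curve.

#' Normalized mutual information of two labelings
#'
#' \eqn{MI(X, Y) / \sqrt{H(X) H(Y)}} with base-2 logarithms, computed from
#' the joint contingency table of two equal-length label vectors.  Returns 0
#' when either marginal entropy is 0 (single-label degenerate case, where
#' the quotient is undefined).
#'
#' @param labels_x,labels_y equal-length label vectors (any atomic type) over
#'   the same drugs, or [ClusterAssignment-class] objects on the same drug
#'   set.
#' @return numeric in \[0, 1\].
#' @examples
#' nmi(c(0, 0, 1, 1), c(0, 1, 0, 1))  # independent -> 0
#' nmi(c(0, 0, 1, 1), c(1, 1, 0, 0))  # relabeling  -> 1
#' @export
nmi <- function(labels_x, labels_y) {
  if (is(labels_x, "ClusterAssignment") && is(labels_y, "ClusterAssignment")) {
    if (!setequal(drugIds(labels_x), drugIds(labels_y)))
      stop("assignments cover different drug sets")
    ids <- drugIds(labels_x)
    labels_y <- clusterLabels(labels_y)[ids]
    labels_x <- clusterLabels(labels_x)
  }
  if (length(labels_x) != length(labels_y))
    stop("label vectors differ in length")
  joint <- table(labels_x, labels_y)
  p <- joint / sum(joint)
  px <- rowSums(p); py <- colSums(p)
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hy <- -sum(py[py > 0] * log2(py[py > 0]))
  if (hx == 0 || hy == 0) return(0)
  expected <- outer(px, py)
  nz <- p > 0
  mi <- sum(p[nz] * log2(p[nz] / expected[nz]))
  min(max(mi / sqrt(hx * hy), 0), 1)
}

overlapRate <- function(pairs, labelSets, predicate, what) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (!nrow(pairs)) stop("empty pair set")
  a <- as.character(pairs[[1L]]); b <- as.character(pairs[[2L]])
  known <- names(labelSets)[lengths(labelSets) > 0 &
                              !vapply(labelSets, function(x) all(is.na(x)), TRUE)]
  usable <- a %in% known & b %in% known
  dropped <- sum(!usable)
  if (dropped)
    message(dropped, " pair(s) excluded from ", what,
            " (missing annotation on at least one drug)")
  if (!any(usable))
    stop("no pair has ", what, " annotation on both drugs")
  hits <- mapply(function(x, y) predicate(labelSets[[x]], labelSets[[y]]),
                 a[usable], b[usable])
  structure(mean(hits), n_used = sum(usable), n_excluded = dropped)
}

#' ATC overlap rate of a set of drug pairs
#'
#' Fraction of pairs whose first-level ATC code sets intersect.  Pairs in
#' which either drug lacks ATC annotation are excluded (and counted in a
#' message) rather than scored as non-overlap.
#'
#' @param pairs two-column data.frame/matrix of drug ids (extra columns
#'   ignored).
#' @param registry a [DrugRegistry-class].
#' @return rate in \[0, 1\], with attributes `n_used` and `n_excluded`.
#' @export
aor <- function(pairs, registry) {
  overlapRate(pairs, atcFirstLevels(registry),
              function(x, y) length(intersect(x, y)) > 0, "AOR")
}

#' Superclass overlap rate of a set of drug pairs
#'
#' As [aor()], but a pair counts when the two superclass labels are equal.
#'
#' @inheritParams aor
#' @return rate in \[0, 1\], with attributes `n_used` and `n_excluded`.
#' @export
sor <- function(pairs, registry) {
  sc <- superclasses(registry)
  sets <- lapply(sc, function(x) if (is.na(x)) character() else x)
  overlapRate(pairs, sets, function(x, y) identical(x, y), "SOR")
}

#' Rogers-Tanimoto agreement between two partitions
#'
#' Pair-counting agreement over all unordered drug pairs:
#' \eqn{(n_{11} + n_{00}) / (n_{11} + n_{00} + 2 (n_{10} + n_{01}))},
#' where \eqn{n_{11}} counts pairs co-clustered in both partitions,
#' \eqn{n_{00}} pairs separated in both, and \eqn{n_{10}}, \eqn{n_{01}}
#' the disagreements.  Invariant to cluster relabeling.
#'
#' @param p1,p2 [ClusterAssignment-class] objects (or label vectors named by
#'   drug) over the same drug set.
#' @return numeric in \[0, 1\].
#' @export
rogersTanimoto <- function(p1, p2) {
  l1 <- if (is(p1, "ClusterAssignment")) clusterLabels(p1) else p1
  l2 <- if (is(p2, "ClusterAssignment")) clusterLabels(p2) else p2
  if (is.null(names(l1)) || is.null(names(l2)))
    stop("partitions must be named by drug id")
  if (!setequal(names(l1), names(l2)))
    stop("partitions cover different drug sets; difference: ",
         paste(c(setdiff(names(l1), names(l2)),
                 setdiff(names(l2), names(l1))), collapse = ", "))
  l2 <- l2[names(l1)]
  n <- length(l1)
  total <- choose(n, 2)
  ct <- table(l1, l2)
  n11 <- sum(choose(ct, 2))
  same1 <- sum(choose(rowSums(ct), 2))
  same2 <- sum(choose(colSums(ct), 2))
  n10 <- same1 - n11
  n01 <- same2 - n11
  n00 <- total - n11 - n10 - n01
  (n11 + n00) / (n11 + n00 + 2 * (n10 + n01))
}

#' Sliding-bin ATC overlap curve over a ranked pair list
#'
#' Slides a window of `binSize` consecutive pairs down a similarity-ranked
#' pair list in steps of `step` and reports the ATC overlap rate of each
#' window.  The published analysis used bins of 3000 pairs with step 100;
#' both are configurable so the curve can be computed at desk scale.
#'
#' @param ranked data.frame with columns `drug_a`, `drug_b`, `score`, sorted
#'   by descending score (as produced by [topPairs()]).
#' @param registry a [DrugRegistry-class].
#' @param binSize window size in pairs.
#' @param step stride in pairs.
#' @param nBins number of windows; default as many as fit.
#' @return data.frame with columns `start_rank` and `aor`.
#' @export
aorCurve <- function(ranked, registry, binSize = 3000L, step = 100L,
                     nBins = NULL) {
  ranked <- as.data.frame(ranked, stringsAsFactors = FALSE)
  if (!all(c("drug_a", "drug_b", "score") %in% names(ranked)))
    stop("ranked list needs columns drug_a, drug_b, score")
  if (is.unsorted(rev(ranked$score)))
    stop("ranked list must be sorted by descending score")
  n <- nrow(ranked)
  binSize <- as.integer(binSize); step <- as.integer(step)
  maxBins <- (n - binSize) %/% step + 1L
  if (is.null(nBins)) nBins <- maxBins
  if (nBins < 1L || n < binSize + (nBins - 1L) * step)
    stop("ranked list too short: need at least ",
         binSize + (max(nBins, 1L) - 1L) * step, " pairs")
  starts <- seq(1L, by = step, length.out = nBins)
  vals <- vapply(starts, function(s) {
    win <- ranked[s:(s + binSize - 1L), c("drug_a", "drug_b")]
    as.numeric(suppressMessages(aor(win, registry)))
  }, numeric(1L))
  data.frame(start_rank = starts, aor = vals)
}
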