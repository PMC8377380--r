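# Interpretation of the fused network: per-edge data-type attribution,
# repositioning candidate extraction, the ATC repositioning graph,
# hypergeometric cluster enrichment, and property deviation.

#' Attribute one edge to its contributing data types
#'
#' Ranks the per-view similarity scores of a drug pair as
#' \eqn{S_i \ge S_j \ge S_k \ge \dots} and cuts at the first gap of at least
#' `margin` (relative by default: \eqn{S_i \ge (1 + margin) S_j}); the
#' contributors are every view above the cut, or all views when no gap
#' reaches the margin.  For three views this yields the familiar rule: a
#' single view when it is at least 10% higher than the runner-up, the top
#' two views when the runner-up in turn is at least 10% higher than the
#' last, otherwise all three.  The relative reading is scale-free; an
#' absolute-gap variant (`relative = FALSE`, cut at \eqn{S_i \ge S_j +
#' margin}) is selectable.
#'
#' @param scores named non-negative numeric vector of per-view scores for
#'   one pair (2 or more views).
#' @param margin positive margin, default 0.10.
#' @param relative interpret `margin` as a ratio (default) or an absolute
#'   gap.
#' @return character vector of contributing view names (a subset of
#'   `names(scores)`).
#' @examples
#' attributeEdge(c(chem = 0.9, target = 0.5, side = 0.4))   # "chem"
#' attributeEdge(c(chem = 0.5, target = 0.5, side = 0.5))   # all three
#' @export
attributeEdge <- function(scores, margin = 0.10, relative = TRUE) {
  if (is.null(names(scores)) || length(scores) < 2L)
    stop("scores must be a named vector over at least two views")
  if (any(scores < 0)) stop("scores must be non-negative")
  if (margin <= 0) stop("margin must be positive")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  for (i in seq_len(length(s) - 1L)) {
    gap <- if (relative) s[i] >= (1 + margin) * s[i + 1L]
           else s[i] >= s[i + 1L] + margin
    if (gap) return(names(s)[seq_len(i)])
  }
  names(scores)
}

#' Summarize data-type contributions over the network's edges
#'
#' Attributes every retained edge of the fused network to its contributing
#' views and reports, per scope, the fraction of edges falling in each
#' contributor category (7 categories for three views: three single, three
#' pairs, one all-three).  Scopes are: all retained edges, within-cluster
#' edges, between-cluster edges, and each cluster separately.  By default
#' only the top 5% of fused edges by score are retained; set
#' `topFrac = 1` for all edges.
#'
#' @param views named list of aligned unit-scale [DrugSimMatrix-class]
#'   objects (the single-property networks).
#' @param fused the fused [DrugSimMatrix-class] (or [FusionResult-class])
#'   whose edge scores define retention.
#' @param assignment a [ClusterAssignment-class] over the same drugs.
#' @param margin,relative see [attributeEdge()].
#' @param topFrac fraction of highest-scoring edges to retain, in (0, 1].
#' @return list with `edges` (one row per retained edge: pair, per-view
#'   scores, contributor category, within-cluster flag) and `summary`
#'   (data.frame of scope, category, n, fraction; fractions sum to 1 within
#'   each scope).
#' @export
contributionSummary <- function(views, fused, assignment, margin = 0.10,
                                relative = TRUE, topFrac = 0.05) {
  if (is(fused, "FusionResult")) fused <- fusedMatrix(fused)
  checkAlignedViews(c(views, list(fused)))
  if (topFrac <= 0 || topFrac > 1) stop("topFrac must lie in (0, 1]")
  viewNames <- names(views)
  if (is.null(viewNames)) stop("views must be named")
  edges <- enumeratePairs(fused)
  keep <- max(1L, ceiling(topFrac * nrow(edges)))
  ord <- order(-edges$score, edges$drug_a, edges$drug_b)
  edges <- edges[ord[seq_len(keep)], , drop = FALSE]
  lab <- clusterLabels(assignment)
  scoreMat <- vapply(views, function(v)
    simValues(v)[cbind(edges$drug_a, edges$drug_b)], numeric(nrow(edges)))
  scoreMat <- matrix(scoreMat, nrow = nrow(edges),
                     dimnames = list(NULL, viewNames))
  cats <- vapply(seq_len(nrow(edges)), function(i) {
    contrib <- attributeEdge(scoreMat[i, ], margin = margin, relative = relative)
    paste(sort(contrib), collapse = "+")
  }, character(1L))
  within <- lab[edges$drug_a] == lab[edges$drug_b]
  edges <- cbind(edges, as.data.frame(scoreMat), category = cats,
                 within_cluster = unname(within))
  allCats <- categoryUniverse(viewNames)
  scopes <- list(all = rep(TRUE, nrow(edges)),
                 within_cluster = within,
                 between_cluster = !within)
  for (k in sort(unique(lab[edges$drug_a][within])))
    scopes[[paste0("cluster_", k)]] <- within & lab[edges$drug_a] == k
  summ <- do.call(rbind, lapply(names(scopes), function(sc) {
    sel <- scopes[[sc]]
    counts <- table(factor(cats[sel], levels = allCats))
    total <- sum(counts)
    data.frame(scope = sc, category = allCats, n = as.integer(counts),
               fraction = if (total > 0) as.numeric(counts) / total
                          else rep(NA_real_, length(allCats)))
  }))
  rownames(summ) <- NULL
  list(edges = edges, summary = summ)
}

categoryUniverse <- function(viewNames) {
  v <- sort(viewNames)
  subsets <- unlist(lapply(seq_along(v), function(size)
    utils::combn(v, size, paste, collapse = "+", simplify = FALSE)),
    recursive = FALSE)
  unlist(subsets)
}

#' Enrichment score of a label in a cluster
#'
#' Fold over-representation \eqn{(k/n) / (m/N)}: the frequency of the label
#' inside the cluster over its frequency in the whole drug universe.
#'
#' @param k drugs carrying the label inside the cluster.
#' @param n cluster size.
#' @param m drugs carrying the label in the universe.
#' @param N universe size.
#' @return non-negative numeric.
#' @examples
#' enrichmentScore(5, 10, 20, 100)  # 2.5
#' @export
enrichmentScore <- function(k, n, m, N) {
  checkCounts(k, n, m, N)
  if (n == 0 || m == 0) stop("n and m must be positive")
  (k / n) / (m / N)
}

#' Hypergeometric enrichment p-value
#'
#' Upper-tail probability \eqn{P(X \ge k)} of drawing at least `k` labeled
#' drugs when `n` drugs are drawn without replacement from a universe of `N`
#' drugs of which `m` carry the label:
#' \deqn{P(X \ge k) = \sum_{x = k}^{\min(m, n)}
#'   \binom{m}{x} \binom{N - m}{n - x} \Big/ \binom{N}{n}.}
#'
#' @inheritParams enrichmentScore
#' @return probability in \[0, 1\].
#' @examples
#' hypergeomP(2, 2, 2, 4)  # 1/6
#' @export
hypergeomP <- function(k, n, m, N) {
  checkCounts(k, n, m, N)
  if (k > min(m, n)) return(0)
  if (k <= 0) return(1)
  stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
}

checkCounts <- function(k, n, m, N) {
  vals <- c(k = k, n = n, m = m, N = N)
  if (any(vals < 0) || any(vals != floor(vals)))
    stop("counts must be non-negative integers")
  if (m > N || n > N)
    stop("impossible counts: m and n cannot exceed N")
  invisible(TRUE)
}

#' Hypergeometric enrichment of labels across clusters
#'
#' Tests every (cluster, term) combination of a drug-to-term vocabulary for
#' over-representation: enrichment score [enrichmentScore()], raw
#' hypergeometric p [hypergeomP()], and Benjamini-Hochberg q across all
#' tests.  Multi-label drugs count once per distinct term.  Significance is
#' flagged at `alpha` on the raw p by default (`significanceColumn = "q"`
#' switches to the adjusted value; q is reported regardless).
#'
#' @param assignment a [ClusterAssignment-class]; its drugs are the universe
#'   (`N`).
#' @param vocabulary named list mapping drug id to a character vector of
#'   terms (e.g. [atcVocabulary()], [superclassVocabulary()], or any
#'   user-supplied mapping such as ADMET labels).  Drugs without an entry
#'   simply carry no term.
#' @param alpha significance level.
#' @param significanceColumn `"p"` (default) or `"q"`.
#' @return data.frame with columns `cluster`, `term`, `k`, `n`, `m`, `N`,
#'   `es`, `p`, `q`, `significant`.
#' @export
annotateClusters <- function(assignment, vocabulary, alpha = 0.05,
                             significanceColumn = c("p", "q")) {
  significanceColumn <- match.arg(significanceColumn)
  stopifnot(is(assignment, "ClusterAssignment"))
  lab <- clusterLabels(assignment)
  N <- length(lab)
  drugs <- names(lab)
  terms <- sort(unique(unlist(vocabulary[intersect(names(vocabulary), drugs)])))
  if (!length(terms)) stop("vocabulary assigns no terms to the assigned drugs")
  has <- vapply(terms, function(tm)
    vapply(drugs, function(d) tm %in% vocabulary[[d]], logical(1L)),
    logical(length(drugs)))
  has <- matrix(has, nrow = length(drugs), dimnames = list(drugs, terms))
  ks <- sort(unique(lab))
  rows <- do.call(rbind, lapply(ks, function(cl) {
    members <- lab == cl
    n <- sum(members)
    do.call(rbind, lapply(terms, function(tm) {
      k <- sum(has[members, tm])
      m <- sum(has[, tm])
      data.frame(cluster = cl, term = tm, k = k, n = n, m = m, N = N,
                 es = enrichmentScore(k, n, m, N),
                 p = hypergeomP(k, n, m, N))
    }))
  }))
  rows$q <- stats::p.adjust(rows$p, method = "BH")
  rows$significant <- rows[[significanceColumn]] < alpha & rows$k > 0
  rownames(rows) <- NULL
  rows
}

#' ATC first-level and superclass vocabularies of a registry
#'
#' Convenience builders of the drug-to-term maps consumed by
#' [annotateClusters()].
#'
#' @param registry a [DrugRegistry-class].
#' @return named list of character term vectors.
#' @export
atcVocabulary <- function(registry) atcFirstLevels(registry)

#' @rdname atcVocabulary
#' @export
superclassVocabulary <- function(registry) {
  lapply(superclasses(registry), function(x)
    if (is.na(x)) character() else x)
}

#' Flag unexpected drugs within enriched clusters
#'
#' In every cluster with at least one significantly enriched ATC term, drugs
#' whose own first-level ATC set misses the cluster's enriched term set are
#' repositioning candidates: the enriched terms are the proposed novel
#' therapeutic property.  Drugs with no ATC annotation are not flagged
#' (there is no label to contradict).
#'
#' @param assignment a [ClusterAssignment-class].
#' @param enrichment output of [annotateClusters()] on an ATC vocabulary.
#' @param registry a [DrugRegistry-class].
#' @return data.frame with columns `drug_id`, `cluster`, `own_codes`
#'   (semicolon-joined first-level codes) and `proposed` (semicolon-joined
#'   enriched terms of the cluster).
#' @export
findUnexpectedDrugs <- function(assignment, enrichment, registry) {
  lab <- clusterLabels(assignment)
  levels <- atcFirstLevels(registry)
  sig <- enrichment[enrichment$significant, , drop = FALSE]
  out <- list()
  for (cl in sort(unique(sig$cluster))) {
    terms <- sort(unique(sig$term[sig$cluster == cl]))
    members <- names(lab)[lab == cl]
    for (d in members) {
      own <- levels[[d]]
      if (is.null(own) || !length(own)) next
      if (!length(intersect(own, terms)))
        out[[length(out) + 1L]] <- data.frame(
          drug_id = d, cluster = cl,
          own_codes = paste(sort(own), collapse = ";"),
          proposed = paste(terms, collapse = ";"))
    }
  }
  if (!length(out))
    return(data.frame(drug_id = character(), cluster = integer(),
                      own_codes = character(), proposed = character()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Highest-similarity drug pairs with ATC concordance flags
#'
#' Ranks all unordered drug pairs of a network by descending score (ties
#' broken by canonical pair order, i.e. by the two drug ids) and flags pairs
#' whose first-level ATC sets do not intersect — the discordant
#' high-similarity pairs are repositioning candidates.
#'
#' @param matrix a [DrugSimMatrix-class] (unit or affinity scale).
#' @param registry optional [DrugRegistry-class]; when given, adds the
#'   `atc_overlap` flag (`NA` when either drug lacks ATC annotation).
#' @param nTop number of pairs to return (default all).
#' @return data.frame with columns `rank`, `drug_a`, `drug_b`, `score` and,
#'   with a registry, `atc_overlap`.
#' @export
topPairs <- function(matrix, registry = NULL, nTop = NULL) {
  pairs <- enumeratePairs(matrix)
  ord <- order(-pairs$score, pairs$drug_a, pairs$drug_b)
  pairs <- pairs[ord, , drop = FALSE]
  if (!is.null(nTop)) {
    if (nTop > nrow(pairs)) stop("nTop exceeds the number of pairs")
    pairs <- pairs[seq_len(nTop), , drop = FALSE]
  }
  pairs$rank <- seq_len(nrow(pairs))
  if (!is.null(registry)) {
    levels <- atcFirstLevels(registry)
    pairs$atc_overlap <- mapply(function(x, y) {
      lx <- levels[[x]]; ly <- levels[[y]]
      if (is.null(lx) || is.null(ly) || !length(lx) || !length(ly))
        NA
      else length(intersect(lx, ly)) > 0
    }, pairs$drug_a, pairs$drug_b)
  }
  rownames(pairs) <- NULL
  pairs[c("rank", "drug_a", "drug_b", "score",
          intersect("atc_overlap", names(pairs)))]
}

#' Repositioning graph over ATC first-level codes
#'
#' Restricts the network to its top fraction of pairs by score, assigns each
#' drug to every one of its first-level ATC codes, and weights each pair of
#' codes by the mean similarity of the drug pairs spanning the two code
#' groups — an index of repositioning potential between therapeutic classes.
#'
#' @param matrix a [DrugSimMatrix-class].
#' @param registry a [DrugRegistry-class].
#' @param topFrac fraction of top pairs to keep, in (0, 1] (default 0.05).
#' @return data.frame with columns `code_a`, `code_b` (`code_a <= code_b`),
#'   `weight` (mean score) and `n_pairs`.
#' @export
atcRepositioningGraph <- function(matrix, registry, topFrac = 0.05) {
  if (topFrac <= 0 || topFrac > 1) stop("topFrac must lie in (0, 1]")
  pairs <- topPairs(matrix, registry = NULL)
  keep <- max(1L, ceiling(topFrac * nrow(pairs)))
  pairs <- pairs[seq_len(keep), , drop = FALSE]
  levels <- atcFirstLevels(registry)
  acc <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(pairs))) {
    la <- levels[[pairs$drug_a[i]]]
    lb <- levels[[pairs$drug_b[i]]]
    if (is.null(la) || is.null(lb) || !length(la) || !length(lb)) next
    for (ca in la) for (cb in lb) {
      key <- if (ca <= cb) paste(ca, cb) else paste(cb, ca)
      prev <- get0(key, envir = acc, inherits = FALSE)
      if (is.null(prev)) prev <- c(0, 0)
      assign(key, prev + c(pairs$score[i], 1), envir = acc)
    }
  }
  keys <- sort(ls(acc))
  if (!length(keys))
    return(data.frame(code_a = character(), code_b = character(),
                      weight = numeric(), n_pairs = integer()))
  parts <- do.call(rbind, strsplit(keys, " ", fixed = TRUE))
  sums <- t(vapply(keys, function(k) get(k, envir = acc), numeric(2L)))
  data.frame(code_a = parts[, 1L], code_b = parts[, 2L],
             weight = sums[, 1L] / sums[, 2L],
             n_pairs = as.integer(sums[, 2L]), row.names = NULL)
}

#' Deviation of a cluster's property mean from a reference
#'
#' Relative deviation \eqn{D = (C - A) / A} of the cluster mean `C` from the
#' reference mean `A`, with a Welch two-sample t-test of the difference.
#'
#' @param clusterValues numeric property values of the cluster's drugs
#'   (length >= 2 for the test).
#' @param referenceValues numeric property values of the reference drug set;
#'   the reference mean must be non-zero.
#' @return list with elements `D` (relative deviation) and `p` (two-sided
#'   Welch t-test probability; `NA` when either group has fewer than two
#'   values).
#' @export
propertyDeviation <- function(clusterValues, referenceValues) {
  A <- mean(referenceValues)
  if (!is.finite(A) || A == 0) stop("reference mean must be non-zero")
  C <- mean(clusterValues)
  p <- if (length(clusterValues) >= 2L && length(referenceValues) >= 2L)
    tryCatch(stats::t.test(clusterValues, referenceValues)$p.value,
             error = function(e) NA_real_)   # e.g. constant data
  else NA_real_
  list(D = (C - A) / A, p = p)
}
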