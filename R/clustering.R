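# Spectral clustering of the fused network and validity-index based
# selection of the number of clusters.

#' Convert unit-scale similarities to distances
#'
#' `d = 1 - s`, zero diagonal.  The result is symmetric but need not satisfy
#' the triangle inequality; the Dunn, silhouette and connectivity indices do
#' not require it.
#'
#' @param matrix a unit-scale [DrugSimMatrix-class].
#' @return symmetric numeric distance matrix with zero diagonal.
#' @export
similarityToDistance <- function(matrix) {
  stopifnot(is(matrix, "DrugSimMatrix"))
  if (simScale(matrix) != "unit")
    stop("distance conversion needs a unit-scale matrix; see unitRescale()")
  d <- 1 - simValues(matrix)
  diag(d) <- 0
  d[d < 0] <- 0
  d
}

# Deterministic kmeans++-style seeding from the distinct rows of the
# embedding, then stats::kmeans.  Duplicate embedding rows (exact block
# structure) would otherwise make random center sampling fail.
seededKmeans <- function(u, k, seed, attempts = 20L) {
  distinct <- !duplicated(round(u, 12L))
  pool <- which(distinct)
  if (length(pool) < k)
    stop("cannot form ", k, " non-empty clusters: only ", length(pool),
         " distinct embedding points")
  for (attempt in seq_len(attempts)) {
    centers <- withSeed(seed + attempt - 1L, {
      ctr <- pool[sample.int(length(pool), 1L)]
      while (length(ctr) < k) {
        d2 <- apply(u[, , drop = FALSE], 1L, function(row)
          min(colSums((t(u[ctr, , drop = FALSE]) - row)^2)))
        d2[-pool] <- 0            # only distinct rows may become centers
        d2[ctr] <- 0
        if (sum(d2) <= 0) {
          cand <- setdiff(pool, ctr)
          ctr <- c(ctr, cand[seq_len(k - length(ctr))])
        } else {
          ctr <- c(ctr, sample.int(nrow(u), 1L, prob = d2))
        }
      }
      ctr
    })
    fit <- withSeed(seed + attempt - 1L, tryCatch(
      stats::kmeans(u, centers = u[centers, , drop = FALSE], iter.max = 100L),
      error = function(e) NULL))
    if (!is.null(fit) && all(tabulate(fit$cluster, k) > 0L))
      return(fit$cluster)
  }
  stop("kmeans failed to produce ", k, " non-empty clusters")
}

#' Spectral clustering of a similarity network
#'
#' Normalized-cut spectral clustering: the top-`k` eigenvectors of the
#' symmetric-normalized affinity \eqn{D^{-1/2} W D^{-1/2}} are row-normalized
#' and partitioned by k-means (seeded deterministically).  Cluster labels are
#' relabeled to first-appearance order, so results are reproducible
#' bit-for-bit for a given seed.
#'
#' @param matrix a [DrugSimMatrix-class] (unit or affinity scale).
#' @param k number of clusters, `2 <= k < n`.
#' @param seed integer seed controlling the k-means initialization.
#' @return a [ClusterAssignment-class].
#' @export
spectralCluster <- function(matrix, k, seed = 1L) {
  stopifnot(is(matrix, "DrugSimMatrix"))
  w <- simValues(matrix)
  n <- nrow(w)
  k <- as.integer(k)
  if (k < 2L || k >= n) stop("k must satisfy 2 <= k < n")
  g <- igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected",
                                           diag = FALSE)
  ncomp <- igraph::components(g)$no
  if (ncomp > k)
    stop("graph has ", ncomp, " connected components but k = ", k,
         "; increase k or densify the network")
  d <- rowSums(w)
  d[d <= 0] <- .Machine$double.eps
  dm12 <- 1 / sqrt(d)
  a <- dm12 * t(dm12 * w)      # D^{-1/2} W D^{-1/2}, kept exactly symmetric
  eig <- eigen(symmetrize(a), symmetric = TRUE)
  u <- eig$vectors[, seq_len(k), drop = FALSE]
  norms <- sqrt(rowSums(u^2))
  norms[norms == 0] <- 1
  u <- u / norms
  cl <- seededKmeans(u, k, seed = as.integer(seed))
  cl <- as.integer(factor(cl, levels = unique(cl)))   # first-appearance order
  ClusterAssignment(cl, drugs = drugIds(matrix), k = k)
}

alignLabels <- function(distances, assignment) {
  lab <- clusterLabels(assignment)
  ids <- rownames(distances)
  if (!is.null(ids)) {
    if (!all(ids %in% names(lab)))
      stop("assignment is missing drugs present in the distance matrix")
    lab <- lab[ids]
  } else if (length(lab) != nrow(distances)) {
    stop("assignment and distance matrix differ in size")
  }
  unname(lab)
}

#' Dunn index of a partition
#'
#' Ratio of the smallest between-cluster pair distance to the largest
#' within-cluster diameter; higher is better.  Requires at least two clusters
#' and at least one cluster with two members.
#'
#' @param distances symmetric distance matrix (rows named by drug when the
#'   assignment should be matched by id).
#' @param assignment a [ClusterAssignment-class].
#' @return non-negative numeric (possibly `Inf` when all diameters are 0).
#' @export
dunnIndex <- function(distances, assignment) {
  lab <- alignLabels(distances, assignment)
  if (length(unique(lab)) < 2L) stop("Dunn index needs at least two clusters")
  if (max(tabulate(lab)) < 2L)
    stop("Dunn index undefined: all clusters are singletons")
  same <- outer(lab, lab, `==`)
  ut <- upper.tri(distances)
  minInter <- min(distances[ut & !same])
  maxIntra <- max(distances[ut & same])
  if (maxIntra == 0) return(Inf)
  minInter / maxIntra
}

#' Mean silhouette width of a partition
#'
#' For each sample, \eqn{s_i = (b_i - a_i) / \max(a_i, b_i)} with \eqn{a_i}
#' the mean distance to its own cluster and \eqn{b_i} the smallest mean
#' distance to another cluster; singleton-cluster samples (and samples with
#' \eqn{a_i = b_i = 0}) contribute 0.  Higher is better.
#'
#' @inheritParams dunnIndex
#' @return numeric in \[-1, 1\].
#' @export
silhouetteMean <- function(distances, assignment) {
  lab <- alignLabels(distances, assignment)
  ks <- sort(unique(lab))
  if (length(ks) < 2L) stop("silhouette needs at least two clusters")
  n <- length(lab)
  sizes <- tabulate(lab, max(ks))
  # mean distance from each point to each cluster
  member <- vapply(ks, function(k) as.numeric(lab == k), numeric(n))
  sums <- distances %*% member
  s <- numeric(n)
  for (i in seq_len(n)) {
    ci <- lab[i]
    if (sizes[ci] == 1L) { s[i] <- 0; next }
    a <- sums[i, match(ci, ks)] / (sizes[ci] - 1L)
    others <- ks[ks != ci]
    b <- min(sums[i, match(others, ks)] / sizes[others])
    m <- max(a, b)
    s[i] <- if (m == 0) 0 else (b - a) / m
  }
  mean(s)
}

#' Connectivity of a partition
#'
#' Sums, over every sample and its `L` nearest neighbors, a penalty of
#' `1/j` whenever the j-th nearest neighbor lies in a different cluster;
#' 0 means every neighborhood is cluster-pure.  Lower is better.  Neighbor
#' ties are broken by sample order.
#'
#' @inheritParams dunnIndex
#' @param L neighbor count, `L < n`.
#' @return non-negative numeric.
#' @export
clusterConnectivity <- function(distances, assignment, L = 10L) {
  lab <- alignLabels(distances, assignment)
  n <- length(lab)
  L <- as.integer(L)
  if (L >= n) stop("L must be smaller than the number of samples")
  total <- 0
  for (i in seq_len(n)) {
    d <- distances[i, ]
    d[i] <- Inf
    nb <- order(d)[seq_len(L)]
    penal <- which(lab[nb] != lab[i])
    if (length(penal)) total <- total + sum(1 / penal)
  }
  total
}

#' Scan cluster counts and select one by validity indices
#'
#' Clusters the network at every `k` in `kRange` and computes the validity
#' profile (Dunn index, mean silhouette, connectivity) on the unit-rescaled
#' distance transform.  The selected `k` maximizes silhouette, with ties
#' broken by larger Dunn index, then by smaller `k`.  Values of `k` at which
#' the spectral step cannot produce `k` non-empty clusters (possible on
#' exactly block-structured data with duplicated embedding rows) get `NA`
#' entries and are excluded from selection, with a warning.
#'
#' @param matrix a [DrugSimMatrix-class].
#' @param kRange integer vector of candidate cluster counts within
#'   `[2, n - 1]`.
#' @param seed integer seed passed to [spectralCluster()].
#' @param L connectivity neighbor count.
#' @return list with elements `k` (the selection), `profile` (data.frame
#'   with columns `k`, `dunn`, `silhouette`, `connectivity`),
#'   `assignments` (list of [ClusterAssignment-class] per scanned `k`) and
#'   `rule` (a string describing the selection rule).
#' @export
selectK <- function(matrix, kRange = 2:10, seed = 1L, L = 10L) {
  stopifnot(is(matrix, "DrugSimMatrix"))
  kRange <- sort(unique(as.integer(kRange)))
  n <- length(drugIds(matrix))
  if (!length(kRange)) stop("empty k range")
  if (min(kRange) < 2L || max(kRange) > n - 1L)
    stop("k range must lie within [2, n - 1]")
  unit <- if (simScale(matrix) == "unit") matrix else unitRescale(matrix)
  d <- similarityToDistance(unit)
  profile <- data.frame(k = kRange, dunn = NA_real_, silhouette = NA_real_,
                        connectivity = NA_real_)
  assignments <- stats::setNames(vector("list", length(kRange)),
                                 as.character(kRange))
  for (i in seq_along(kRange)) {
    k <- kRange[i]
    asg <- tryCatch(spectralCluster(matrix, k, seed = seed),
                    error = function(e) e)
    if (inherits(asg, "error")) {
      warning("k = ", k, " skipped: ", conditionMessage(asg))
      next
    }
    assignments[[i]] <- asg
    profile$silhouette[i] <- silhouetteMean(d, asg)
    profile$dunn[i] <- tryCatch(dunnIndex(d, asg), error = function(e) NA_real_)
    profile$connectivity[i] <- clusterConnectivity(d, asg, L = L)
  }
  ok <- which(!is.na(profile$silhouette))
  if (!length(ok)) stop("no scanned k produced a valid clustering")
  dunnKey <- profile$dunn[ok]
  dunnKey[is.na(dunnKey)] <- -Inf
  pick <- ok[order(-profile$silhouette[ok], -dunnKey, profile$k[ok])][1L]
  list(k = profile$k[pick], profile = profile, assignments = assignments,
       rule = "max silhouette, ties by max Dunn, then smallest k")
}
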