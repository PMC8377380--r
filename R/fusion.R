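# Network fusion: similarity network fusion (cross-diffusion) plus the three
# linear comparison integrators (elementwise maximum, weighted average,
# probability disjunction).

# Full kernel: off-diagonal mass 1/2 split proportionally, diagonal 1/2.
snfNormalize <- function(w) {
  d <- rowSums(w) - diag(w)
  d[d <= 0] <- .Machine$double.eps
  p <- w / (2 * d)
  diag(p) <- 0.5
  p
}

# Sparse kernel: keep each row's K nearest neighbors (self excluded, ties
# broken by drug order), then row-normalize.
snfKnnKernel <- function(w, K) {
  n <- nrow(w)
  s <- matrix(0, n, n, dimnames = dimnames(w))
  for (i in seq_len(n)) {
    wi <- w[i, ]
    wi[i] <- -Inf
    nb <- order(wi, decreasing = TRUE)[seq_len(K)]   # order() is stable
    mass <- sum(w[i, nb])
    s[i, nb] <- if (mass > 0) w[i, nb] / mass else 1 / K
  }
  s
}

#' Fuse similarity networks by cross-diffusion (SNF)
#'
#' Integrates two or more unit-scale drug similarity networks into one
#' affinity network by similarity network fusion: each view's full transition
#' kernel is iteratively diffused through the average of the other views'
#' kernels, restricted by its own K-nearest-neighbor kernel,
#' \deqn{P_v \leftarrow S_v \, \bar{P}_{-v} \, S_v^\top,}
#' with re-normalization and re-symmetrization each round; after `T` rounds
#' the fused network is the mean of the per-view kernels, symmetrized.  The
#' procedure is deterministic.
#'
#' The networks produced by the similarity module are consumed directly as
#' affinities (the default).  When raw feature matrices are to be
#' kernelized with a scaled exponential kernel instead, `eta` is the kernel
#' bandwidth hyperparameter; it is carried in the result for provenance
#' either way.
#'
#' @param views named list of aligned [DrugSimMatrix-class] objects (same
#'   drugs, same order); at least two.
#' @param eta positive bandwidth hyperparameter (recorded; used only by the
#'   kernelization path).
#' @param K neighbor count of the sparse kernel; must be `< n` drugs.
#' @param T number of diffusion iterations (`>= 1`).
#' @return a [FusionResult-class] with an affinity-scale fused matrix.
#' @examples
#' v <- matrix(c(1, .8, .8, 1), 2, dimnames = list(c("a","b"), c("a","b")))
#' m <- DrugSimMatrix(v)
#' f <- snfFuse(list(x = m, y = m), K = 1, T = 2)
#' fusedMatrix(f)
#' @export
snfFuse <- function(views, eta = 0.5, K = 20L, T = 20L) {
  drugs <- checkAlignedViews(views)
  n <- length(drugs)
  K <- as.integer(K); T <- as.integer(T)
  if (K >= n) stop("K (", K, ") must be smaller than the number of drugs (", n, ")")
  if (K < 1L || T < 1L) stop("K and T must be positive")
  if (eta <= 0) stop("eta must be positive")
  m <- length(views)
  P <- lapply(views, function(v) symmetrize(snfNormalize(simValues(v))))
  S <- lapply(P, snfKnnKernel, K = K)
  for (iter in seq_len(T)) {
    Pnext <- vector("list", m)
    for (v in seq_len(m)) {
      other <- Reduce(`+`, P[-v]) / (m - 1)
      Pnext[[v]] <- S[[v]] %*% other %*% t(S[[v]])
    }
    P <- lapply(Pnext, function(p) symmetrize(snfNormalize(symmetrize(p))))
  }
  fused <- symmetrize(Reduce(`+`, P) / m)
  fused[fused < 0] <- 0
  dimnames(fused) <- list(drugs, drugs)
  viewNames <- if (is.null(names(views))) paste0("view", seq_len(m)) else names(views)
  new("FusionResult",
      fused = DrugSimMatrix(fused, scale = "affinity"),
      method = "snf", params = list(eta = eta, K = K, T = T),
      views = viewNames)
}

#' Rescale an affinity network to unit scale
#'
#' Divides off-diagonal entries by the maximum off-diagonal entry and sets
#' the diagonal to 1; a monotone transform, so pair rankings are unchanged.
#' Needed so fused networks can feed the distance-based validity indices.
#'
#' @param affinity a [DrugSimMatrix-class] (any scale).
#' @return a unit-scale [DrugSimMatrix-class].
#' @export
unitRescale <- function(affinity) {
  stopifnot(is(affinity, "DrugSimMatrix"))
  v <- simValues(affinity)
  off <- v[upper.tri(v)]
  mx <- if (length(off)) max(off) else 0
  if (mx <= 0) stop("cannot rescale: all off-diagonal entries are zero")
  v <- v / mx
  diag(v) <- 1
  v[v > 1] <- 1
  DrugSimMatrix(v, scale = "unit")
}

linearFusionResult <- function(values, views, method, params, scale = "unit") {
  drugs <- rownames(values)
  viewNames <- if (is.null(names(views))) paste0("view", seq_along(views)) else names(views)
  new("FusionResult", fused = DrugSimMatrix(values, scale = scale),
      method = method, params = params, views = viewNames)
}

#' Elementwise-maximum integration
#'
#' @param views named list of aligned [DrugSimMatrix-class] objects.
#' @return a [FusionResult-class] (`method = "max"`).
#' @export
maxIntegrate <- function(views) {
  checkAlignedViews(views)
  vals <- Reduce(pmax, lapply(views, simValues))
  linearFusionResult(vals, views, "max", list())
}

#' Weighted-average integration and the weight grid
#'
#' `weightedAverageIntegrate()` computes \eqn{\sum_v w_v S_v / \sum_v w_v}.
#' `weightGrid()` enumerates every weight vector on the step-`0.1` simplex
#' (weights summing to 1, all-zero excluded) used to traverse the weighted
#' average baseline.
#'
#' @param views named list of aligned [DrugSimMatrix-class] objects.
#' @param weights non-negative weights, one per view, not all zero.
#' @return a [FusionResult-class] (`method = "wavg"`).
#' @export
weightedAverageIntegrate <- function(views, weights) {
  checkAlignedViews(views)
  if (length(weights) != length(views))
    stop("need one weight per view")
  if (any(weights < 0) || sum(weights) <= 0)
    stop("weights must be non-negative with positive sum")
  w <- weights / sum(weights)
  vals <- Reduce(`+`, Map(function(v, wi) wi * simValues(v), views, w))
  linearFusionResult(vals, views, "wavg", list(weights = w))
}

#' @rdname weightedAverageIntegrate
#' @param nViews number of views.
#' @param step grid step (default 0.1).
#' @return `weightGrid`: a matrix with one normalized weight vector per row.
#' @export
weightGrid <- function(nViews, step = 0.1) {
  units <- as.integer(round(1 / step))
  combos <- expand.grid(rep(list(0:units), nViews))
  combos <- combos[rowSums(combos) == units, , drop = FALSE]
  grid <- as.matrix(combos) * step
  dimnames(grid) <- NULL
  grid[nrow(grid):1, , drop = FALSE]
}

#' Probability-disjunction integration
#'
#' Elementwise noisy-OR over unit-scale views:
#' \eqn{S = 1 - \prod_v (1 - S_v)}.
#'
#' @param views named list of aligned unit-scale [DrugSimMatrix-class]
#'   objects.
#' @return a [FusionResult-class] (`method = "disjunction"`).
#' @export
probabilityDisjunction <- function(views) {
  checkAlignedViews(views)
  mats <- lapply(views, simValues)
  for (m in mats)
    if (any(m < 0) || any(m > 1 + 1e-12))
      stop("probability disjunction needs entries in [0, 1]")
  vals <- 1 - Reduce(`*`, lapply(mats, function(m) 1 - pmin(m, 1)))
  linearFusionResult(vals, views, "disjunction", list())
}
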