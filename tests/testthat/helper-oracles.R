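# Independent brute-force oracles used to validate the package's
# implementations on small instances.  These are written against the
# definitions directly (full tables, explicit loops) and share no code with
# the implementation paths they check.

# Smith-Waterman with affine gaps: naive full-table dynamic program keeping
# all three state matrices.  Gap of length L costs open + (L - 1) * ext.
swOracle <- function(s1, s2, subs, open, ext) {
  a <- strsplit(s1, "")[[1L]]
  b <- strsplit(s2, "")[[1L]]
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(-Inf, n + 1L, m + 1L)
  F <- matrix(-Inf, n + 1L, m + 1L)
  best <- 0
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      E[i, j] <- max(H[i, j - 1L] - open, E[i, j - 1L] - ext)
      F[i, j] <- max(H[i - 1L, j] - open, F[i - 1L, j] - ext)
      H[i, j] <- max(0, H[i - 1L, j - 1L] + subs[a[i - 1L], b[j - 1L]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# Tanimoto through explicit binary incidence vectors.
tanimotoBitOracle <- function(a, b) {
  univ <- union(a, b)
  if (!length(univ)) return(0)
  va <- as.integer(univ %in% a)
  vb <- as.integer(univ %in% b)
  shared <- sum(va * vb)
  shared / (sum(va) + sum(vb) - shared)
}

# NMI from explicit joint/marginal probabilities, base-2 logs.
nmiOracle <- function(x, y) {
  n <- length(x)
  ux <- unique(x); uy <- unique(y)
  pj <- outer(ux, uy, Vectorize(function(a, b) sum(x == a & y == b) / n))
  px <- rowSums(pj); py <- colSums(pj)
  mi <- 0
  for (i in seq_along(ux)) for (j in seq_along(uy)) {
    if (pj[i, j] > 0)
      mi <- mi + pj[i, j] * log2(pj[i, j] / (px[i] * py[j]))
  }
  hx <- -sum(ifelse(px > 0, px * log2(px), 0))
  hy <- -sum(ifelse(py > 0, py * log2(py), 0))
  if (hx == 0 || hy == 0) return(0)
  mi / sqrt(hx * hy)
}

# Dunn index by enumerating every pair of samples.
dunnOracle <- function(d, lab) {
  n <- length(lab)
  minInter <- Inf; maxIntra <- 0
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    if (lab[i] == lab[j]) maxIntra <- max(maxIntra, d[i, j])
    else minInter <- min(minInter, d[i, j])
  }
  minInter / maxIntra
}

# Mean silhouette by per-sample loops over clusters.
silhouetteOracle <- function(d, lab) {
  n <- length(lab)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(lab == lab[i] & seq_len(n) != i)
    if (!length(own)) { vals[i] <- 0; next }
    a <- mean(d[i, own])
    b <- Inf
    for (cl in setdiff(unique(lab), lab[i]))
      b <- min(b, mean(d[i, lab == cl]))
    vals[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(vals)
}

# Rogers-Tanimoto by enumerating all unordered pairs.
rtOracle <- function(l1, l2) {
  n <- length(l1)
  n11 <- n10 <- n01 <- n00 <- 0
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    s1 <- l1[i] == l1[j]; s2 <- l2[i] == l2[j]
    if (s1 && s2) n11 <- n11 + 1
    else if (s1) n10 <- n10 + 1
    else if (s2) n01 <- n01 + 1
    else n00 <- n00 + 1
  }
  (n11 + n00) / (n11 + n00 + 2 * (n10 + n01))
}

# Hypergeometric upper tail by exhaustive enumeration of all C(N, n) draws.
hyperOracle <- function(k, n, m, N) {
  draws <- utils::combn(N, n)
  labeled <- seq_len(m)   # drugs 1..m carry the label
  hits <- apply(draws, 2L, function(col) sum(col %in% labeled) >= k)
  mean(hits)
}

# Target similarity by direct double loop over protein pairs.
targetSimOracle <- function(pa, pb, db, scoring) {
  tot <- 0
  for (p in pa) for (q in pb) {
    tot <- tot + smithWaterman(db[[p]], db[[q]], scoring) /
      sqrt(smithWaterman(db[[p]], db[[p]], scoring) *
           smithWaterman(db[[q]], db[[q]], scoring))
  }
  tot / (length(pa) * length(pb))
}

randomAASeq <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], len,
               replace = TRUE), collapse = "")
}

randomBlockMatrix <- function(n, k, within = 0.9, between = 0.1) {
  blk <- sort(rep_len(seq_len(k), n))
  v <- outer(blk, blk, function(a, b) ifelse(a == b, within, between))
  diag(v) <- 1
  ids <- sprintf("d%03d", seq_len(n))
  dimnames(v) <- list(ids, ids)
  list(matrix = DrugSimMatrix(v), labels = stats::setNames(blk, ids))
}

smallRegistry <- function() {
  DrugRegistry(c("d1", "d2", "d3", "d4", "d5", "d6"),
               atc_codes = list(c("N02", "A01"), "A03", "C01", c("N05"),
                                character(), "M01"),
               superclass = c("x", "x", "y", "y", NA, "z"))
}
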