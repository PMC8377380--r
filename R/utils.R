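# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards so library code never perturbs user RNG.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

symmetrize <- function(m) (m + t(m)) / 2

# Shared-drug-order check for multi-view operations; errors list the
# symmetric difference when the drug sets disagree.
checkAlignedViews <- function(views) {
  if (length(views) < 2L) stop("at least two views are required")
  ids <- lapply(views, drugIds)
  ref <- ids[[1L]]
  for (i in seq_along(ids)[-1L]) {
    if (!identical(ids[[i]], ref)) {
      d1 <- setdiff(ref, ids[[i]])
      d2 <- setdiff(ids[[i]], ref)
      if (length(d1) || length(d2))
        stop("views disagree on the drug set; symmetric difference: ",
             paste(c(d1, d2), collapse = ", "))
      stop("views list the same drugs in different orders")
    }
  }
  invisible(ref)
}

# Canonical (a < b) unordered pair of drug ids.
canonicalPairs <- function(a, b) {
  swap <- a > b
  pa <- ifelse(swap, b, a)
  pb <- ifelse(swap, a, b)
  data.frame(drug_a = pa, drug_b = pb, stringsAsFactors = FALSE)
}

# Upper-triangle pair enumeration of a DrugSimMatrix, in canonical row order.
enumeratePairs <- function(mat) {
  v <- simValues(mat)
  ids <- drugIds(mat)
  idx <- which(upper.tri(v), arr.ind = TRUE)
  data.frame(drug_a = ids[idx[, 1L]], drug_b = ids[idx[, 2L]],
             score = v[idx], stringsAsFactors = FALSE)
}
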