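#' Run configuration
#'
#' Bundles every tunable of the pipeline with its default: the fusion
#' parameters (`eta = 0.5`, `K = 20`, `T = 20` — the recommended operating
#' point of the fusion algorithm), the cluster-scan range, the relative
#' attribution margin (0.10, i.e. "at least 10% higher"), the sliding-bin
#' parameters of the ATC-overlap curve (bin of 3000 pairs, step 100), the
#' enrichment significance level (0.05 on raw p), the connectivity neighbor
#' count (`L = 10`) and the random seed.
#'
#' @param eta positive kernel bandwidth hyperparameter; used only by the
#'   optional distance-kernelization path of [snfFuse()].
#' @param K number of nearest neighbors in the sparse fusion kernel.
#' @param T number of cross-diffusion iterations.
#' @param kRange integer vector of cluster counts to scan in [selectK()].
#' @param margin relative attribution margin of [attributeEdge()].
#' @param binSize,step sliding-window parameters of [aorCurve()].
#' @param alpha significance level of [annotateClusters()].
#' @param L neighbor count of [clusterConnectivity()].
#' @param seed integer random seed.
#' @return a named list of class `dsnfuse_config`.
#' @examples
#' cfg <- runConfig(K = 10)
#' cfg$K
#' @export
runConfig <- function(eta = 0.5, K = 20L, T = 20L, kRange = 2:10,
                      margin = 0.10, binSize = 3000L, step = 100L,
                      alpha = 0.05, L = 10L, seed = 1L) {
  stopifnot(eta > 0, K >= 1, T >= 1, margin > 0, binSize >= 1, step >= 1,
            alpha > 0, alpha < 1, L >= 1)
  structure(list(eta = eta, K = as.integer(K), T = as.integer(T),
                 kRange = as.integer(kRange), margin = margin,
                 binSize = as.integer(binSize), step = as.integer(step),
                 alpha = alpha, L = as.integer(L), seed = as.integer(seed)),
            class = "dsnfuse_config")
}

#' Read a run configuration from JSON
#'
#' Unknown keys are rejected; missing keys fall back to [runConfig()]
#' defaults.
#'
#' @param path path to a JSON file.
#' @return a `dsnfuse_config` list.
#' @export
readRunConfig <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- names(formals(runConfig))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  do.call(runConfig, raw)
}
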