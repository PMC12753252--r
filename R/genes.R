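#' Generate a synthetic regional gene-expression matrix
#'
#' Emulates a regions x genes expression matrix (the shape of an Allen-atlas
#' projection, e.g. 238 x 15,633) with a planted spatially covarying
#' component: a designated subset of "signal" genes equals
#' `signal_weight * signal_map` plus Gaussian noise, all remaining genes are
#' pure noise. The identities of the signal genes are recorded in the
#' `"signal_genes"` attribute so transcriptomic-association stages can be
#' scored against ground truth.
#'
#' @param n_regions Number of regions (rows).
#' @param n_genes Number of genes (columns).
#' @param signal_map Region-length vector carried by the signal genes; `NULL`
#'   (with `signal_weight = 0`) gives a pure-noise matrix.
#' @param n_signal_genes How many genes carry the signal.
#' @param signal_weight Loading of `signal_map` in the signal genes.
#' @param noise_sd SD of the additive Gaussian noise.
#' @param seed Integer seed.
#' @return A numeric `n_regions` x `n_genes` matrix with column names
#'   `g00001, ...`, row names `region_1, ...` and attribute `signal_genes`
#'   (integer column indices, possibly empty).
#' @examples
#' g <- generate_gene_expression(30, 100, signal_map = sin(1:30),
#'                               n_signal_genes = 10, signal_weight = 1,
#'                               noise_sd = 0.5, seed = 2)
#' attr(g, "signal_genes")
#' @export
generate_gene_expression <- function(n_regions, n_genes,
                                     signal_map = NULL,
                                     n_signal_genes = 0,
                                     signal_weight = 1,
                                     noise_sd = 1,
                                     seed = 1L) {
  stopifnot(n_regions > 0, n_genes > 0, n_signal_genes <= n_genes,
            n_signal_genes >= 0, noise_sd >= 0)
  if (n_signal_genes > 0 && signal_weight != 0) {
    if (is.null(signal_map)) stopf("signal_map is required when planting signal genes")
    if (length(signal_map) != n_regions) {
      stopf("signal_map length (%d) must equal n_regions (%d)",
            length(signal_map), n_regions)
    }
    if (sd(signal_map) == 0) {
      warnf("signal_map has zero variance; correlation with signal genes is undefined")
    }
  }
  set.seed(substream_seed(seed, 424243L))
  x <- matrix(rnorm(n_regions * n_genes, 0, noise_sd), n_regions, n_genes)
  signal_genes <- integer(0)
  if (n_signal_genes > 0 && signal_weight != 0) {
    signal_genes <- sort(sample.int(n_genes, n_signal_genes))
    x[, signal_genes] <- x[, signal_genes] + signal_weight * signal_map
  }
  dimnames(x) <- list(paste0("region_", seq_len(n_regions)),
                      sprintf("g%05d", seq_len(n_genes)))
  attr(x, "signal_genes") <- signal_genes
  x
}
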