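# standardise columns; constant columns become all-zero (they carry no
# signal and receive zero weight)
standardise_cols <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  x <- sweep(x, 2, mu)
  ok <- sdv > 0
  x[, ok] <- sweep(x[, ok, drop = FALSE], 2, sdv[ok], "/")
  x
}

# one NIPALS component for a univariate response; returns weight vector w
# (unit norm), scores t, gene loadings p, response loading q
pls_component <- function(X, y) {
  w <- crossprod(X, y)
  nw <- sqrt(sum(w^2))
  if (nw == 0) stopf("response is orthogonal to every gene; no component")
  w <- w / nw
  scores <- as.numeric(X %*% w)
  tt <- sum(scores^2)
  list(w = as.numeric(w), scores = scores,
       p = as.numeric(crossprod(X, scores)) / tt,
       q = sum(y * scores) / tt, tt = tt)
}

#' Partial least squares between a regional map and gene expression
#'
#' Links a region-length statistic map (e.g. the combined z map of an
#' AD-vs-HC centrality contrast) to a regions x genes expression matrix by
#' PLS regression (NIPALS, univariate response). Gene columns and the
#' response are standardised; for each component the explained-variance
#' share is reported both in the gene block and in the response, since
#' either can serve as the headline quantity. Component orientation is fixed
#' so that the correlation between component-1 scores and the response is
#' nonnegative, with weights flipped coherently.
#'
#' @param response Region-length numeric vector (must not be constant).
#' @param genes Regions x genes numeric matrix, rows aligned with
#'   `response`. Regions without expression data are dropped via
#'   `region_mask`.
#' @param ncomp Number of components (default 10, capped by the data).
#' @param region_mask Optional logical/integer mask selecting the regions of
#'   `response` with expression coverage (e.g. 238 of 246).
#' @return Object of class `pls_result`: list with `scores` (regions x
#'   ncomp), `weights` and `loadings` (genes x ncomp),
#'   `expl_gene`, `expl_response` (per-component shares), `cor1`
#'   (correlation of component-1 scores with the response), `genes`
#'   (column names), `n_regions`.
#' @export
pls_fit <- function(response, genes, ncomp = 10, region_mask = NULL) {
  genes <- as.matrix(genes)
  if (!is.null(region_mask)) {
    response <- response[region_mask]
    genes <- genes[region_mask, , drop = FALSE]
  }
  n <- length(response)
  if (n != nrow(genes)) {
    stopf("response length (%d) must match gene-matrix rows (%d)", n, nrow(genes))
  }
  if (n < 10) stopf("need at least 10 regions, got %d", n)
  if (sd(response) == 0) stopf("response map is constant")
  y0 <- as.numeric(scale(response))
  X0 <- standardise_cols(genes)
  ss_x <- sum(X0^2)
  ss_y <- sum(y0^2)
  ncomp <- min(ncomp, n - 1, ncol(genes))

  X <- X0
  y <- y0
  W <- P <- matrix(0, ncol(genes), ncomp)
  Tm <- matrix(0, n, ncomp)
  qv <- expl_gene <- expl_response <- numeric(ncomp)
  for (k in seq_len(ncomp)) {
    cmp <- pls_component(X, y)
    flip <- if (cor(cmp$scores, y0) < 0) -1 else 1
    W[, k] <- flip * cmp$w
    Tm[, k] <- flip * cmp$scores
    P[, k] <- flip * cmp$p
    qv[k] <- flip * cmp$q
    expl_gene[k] <- cmp$tt * sum(cmp$p^2) / ss_x
    expl_response[k] <- cmp$q^2 * cmp$tt / ss_y
    X <- X - cmp$scores %*% t(cmp$p)
    y <- y - cmp$scores * cmp$q
  }
  gene_names <- colnames(genes)
  if (is.null(gene_names)) gene_names <- sprintf("g%05d", seq_len(ncol(genes)))
  dimnames(W) <- dimnames(P) <- list(gene_names, paste0("comp", seq_len(ncomp)))
  structure(list(
    scores = Tm, weights = W, loadings = P, q = qv,
    expl_gene = expl_gene, expl_response = expl_response,
    cor1 = cor(Tm[, 1], y0), genes = gene_names, n_regions = n,
    ncomp = ncomp
  ), class = "pls_result")
}

#' @export
print.pls_result <- function(x, ...) {
  cat(sprintf("<pls_result> %d regions, %d genes, %d components\n",
              x$n_regions, length(x$genes), x$ncomp))
  cat(sprintf("  component 1: %.1f%% of gene-block variance, %.1f%% of response variance (score-response r = %.3f)\n",
              100 * x$expl_gene[1], 100 * x$expl_response[1], x$cor1))
  invisible(x)
}

# component-1 gene-block explained share for a given response; the
# permutation statistic (cheap: no deflation needed)
pls1_gene_share <- function(X0, y, ss_x) {
  cmp <- pls_component(X0, as.numeric(scale(y)))
  cmp$tt * sum(cmp$p^2) / ss_x
}

#' Permutation test for the first PLS component
#'
#' The region labels of the response are permuted `B` times; the statistic is
#' the component-1 explained-variance share in the gene block (the same
#' quantity as the headline result), and
#' \eqn{p = (1 + \#\{perm \ge obs\}) / (B + 1)}. With `exact = TRUE` all
#' permutations of the regions are enumerated instead (feasible for very
#' small region counts) and the p-value is the exact tail fraction,
#' identity permutation included.
#'
#' @param response Region-length map.
#' @param genes Regions x genes matrix.
#' @param B Number of permutations (default 5000).
#' @param region_mask Optional region alignment mask (see [pls_fit()]).
#' @param exact Enumerate all permutations (requires <= 8 regions).
#' @param seed Integer seed.
#' @return List with `p_value`, `observed` (component-1 gene-block share)
#'   and `null` (permutation statistics).
#' @export
pls_permutation <- function(response, genes, B = 5000, region_mask = NULL,
                            exact = FALSE, seed = 1L) {
  genes <- as.matrix(genes)
  if (!is.null(region_mask)) {
    response <- response[region_mask]
    genes <- genes[region_mask, , drop = FALSE]
  }
  n <- length(response)
  stopifnot(n == nrow(genes), B >= 1)
  X0 <- standardise_cols(genes)
  ss_x <- sum(X0^2)
  obs <- pls1_gene_share(X0, response, ss_x)
  if (exact) {
    if (n > 8) stopf("exact enumeration supported for <= 8 regions, got %d", n)
    perms <- all_permutations(n)
    null <- vapply(seq_len(nrow(perms)), function(i) {
      pls1_gene_share(X0, response[perms[i, ]], ss_x)
    }, numeric(1))
    p <- mean(null >= obs - 1e-12)
  } else {
    set.seed(substream_seed(seed, 77001L))
    null <- vapply(seq_len(B), function(b) {
      pls1_gene_share(X0, response[sample.int(n)], ss_x)
    }, numeric(1))
    p <- (1 + sum(null >= obs - 1e-12)) / (B + 1)
  }
  list(p_value = p, observed = obs, null = null)
}

# all permutations of 1..n as a matrix (n! rows); recursive construction
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Bootstrap stability of PLS gene weights
#'
#' Regions are resampled with replacement `B` times and the component-1
#' weight vector refitted; each resample's component is sign-aligned to the
#' full-model component before accumulating. The stability Z of a gene is
#' its full-model weight divided by its bootstrap standard error. Degenerate
#' resamples (a single unique region) are redrawn and counted.
#'
#' @param response Region-length map.
#' @param genes Regions x genes matrix.
#' @param B Number of bootstrap resamples (default 5000).
#' @param region_mask Optional region alignment mask.
#' @param seed Integer seed.
#' @return Tibble with columns `gene`, `weight` (full model), `boot_mean`,
#'   `boot_se`, `z`; attribute `n_redrawn` counts degenerate resamples.
#' @export
pls_bootstrap <- function(response, genes, B = 5000, region_mask = NULL,
                          seed = 1L) {
  stopifnot(B >= 2)
  genes <- as.matrix(genes)
  if (!is.null(region_mask)) {
    response <- response[region_mask]
    genes <- genes[region_mask, , drop = FALSE]
  }
  n <- length(response)
  stopifnot(n == nrow(genes))
  full <- pls_fit(response, genes, ncomp = 1)
  w_full <- full$weights[, 1]
  set.seed(substream_seed(seed, 88002L))
  acc <- matrix(0, ncol(genes), B)
  n_redrawn <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(idx)) > 1 && sd(response[idx]) > 0) break
      n_redrawn <- n_redrawn + 1L
    }
    Xb <- standardise_cols(genes[idx, , drop = FALSE])
    cmp <- pls_component(Xb, as.numeric(scale(response[idx])))
    wb <- cmp$w
    if (sum(wb * w_full) < 0) wb <- -wb
    acc[, b] <- wb
  }
  se <- apply(acc, 1, sd)
  out <- tibble(
    gene = full$genes,
    weight = as.numeric(w_full),
    boot_mean = rowMeans(acc),
    boot_se = se,
    z = as.numeric(w_full) / se
  )
  attr(out, "n_redrawn") <- n_redrawn
  out
}

#' Rank genes by absolute full-model PLS weight
#'
#' Component-1 weights from the full model, sorted by absolute value in
#' descending order; ties broken by gene identifier.
#'
#' @param result A [pls_fit()] result.
#' @param k Number of genes to return (default 500).
#' @return Tibble with columns `rank`, `gene`, `weight`.
#' @export
rank_top_genes <- function(result, k = 500) {
  stopifnot(inherits(result, "pls_result"))
  w <- result$weights[, 1]
  if (k > length(w)) {
    stopf("k = %d exceeds the number of genes (%d)", k, length(w))
  }
  ord <- order(-abs(w), result$genes)
  top <- ord[seq_len(k)]
  tibble(rank = seq_len(k), gene = result$genes[top],
         weight = as.numeric(w[top]))
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test of the overlap between a ranked gene list
#' and each gene set (sets are intersected with the background), with
#' Benjamini-Hochberg correction across sets. Equivalent to a one-sided
#' Fisher exact test on the corresponding 2 x 2 table.
#'
#' @param gene_list Character vector of selected genes (must be a subset of
#'   `background`).
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param background Character vector: the gene universe.
#' @param q FDR level.
#' @return Tibble with columns `set`, `set_size`, `overlap`, `p`, `p_adj`,
#'   `significant`, sorted by `p`.
#' @export
hypergeom_enrich <- function(gene_list, gene_sets, background, q = 0.05) {
  if (length(background) == 0) stopf("background gene universe is empty")
  background <- unique(background)
  gene_list <- unique(gene_list)
  if (!all(gene_list %in% background)) {
    stopf("gene_list contains %d gene(s) outside the background",
          sum(!gene_list %in% background))
  }
  N <- length(background)
  k <- length(gene_list)
  rows <- purrr::imap(gene_sets, function(set, name) {
    set <- intersect(unique(set), background)
    m <- length(set)
    ov <- length(intersect(set, gene_list))
    p <- if (m == 0) 1 else phyper(ov - 1, m, N - m, k, lower.tail = FALSE)
    tibble(set = name, set_size = m, overlap = ov, p = p)
  })
  out <- dplyr::bind_rows(rows)
  adj <- fdr_bh(out$p, q)
  out$p_adj <- adj$p_adj
  out$significant <- adj$reject
  dplyr::arrange(out, .data$p, .data$set)
}
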