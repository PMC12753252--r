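#' Covariate-adjusted group test at a single site
#'
#' Per region, fits the linear model `value ~ group + age + sex` and reports
#' the t statistic and two-sided p-value of the group coefficient. With
#' shared covariate slopes this is equivalent to a two-sample t-test on
#' age/sex-residualised values, which is how each site enters the
#' mega-analysis.
#'
#' @param values Subjects x regions numeric matrix.
#' @param groups Two-level factor/character vector (the second level of
#'   `contrast` is the reference; positive t means higher values in the
#'   first level).
#' @param covariates Optional data frame of numeric covariates (e.g. `age`,
#'   `sex`); factors are expanded to indicators.
#' @param contrast Length-2 character: `c(test_group, reference_group)`,
#'   default `c("AD", "HC")`.
#' @param site Optional site label carried on the result.
#' @return An object of class `site_test`: tibble with columns `region`,
#'   `t`, `p`, plus attributes `site`, `n` (subjects used) and `contrast`.
#' @export
site_group_test <- function(values, groups, covariates = NULL,
                            contrast = c("AD", "HC"), site = NA_character_) {
  values <- as.matrix(values)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(values))
  keep <- groups %in% contrast
  values <- values[keep, , drop = FALSE]
  groups <- groups[keep]
  if (!is.null(covariates)) covariates <- covariates[keep, , drop = FALSE]
  n_test <- sum(groups == contrast[1])
  n_ref <- sum(groups == contrast[2])
  if (n_test < 3 || n_ref < 3) {
    stopf("site %s: both groups need >= 3 subjects (have %d %s, %d %s)",
          site, n_test, contrast[1], n_ref, contrast[2])
  }
  X <- cbind(`(Intercept)` = 1, group = as.numeric(groups == contrast[1]))
  if (!is.null(covariates)) {
    cov_mm <- stats::model.matrix(~ ., data = as.data.frame(covariates))[, -1, drop = FALSE]
    X <- cbind(X, cov_mm)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stopf("site %s: collinear design; offending column(s): %s",
          site, paste(bad, collapse = ", "))
  }
  n <- nrow(X)
  df <- n - ncol(X)
  coefs <- qr.coef(qrX, values)
  resid <- qr.resid(qrX, values)
  sigma2 <- colSums(resid^2) / df
  xtx_inv_gg <- solve(crossprod(X))[2, 2]
  tval <- coefs["group", ] / sqrt(sigma2 * xtx_inv_gg)
  pval <- 2 * pt(-abs(tval), df)
  out <- tibble(region = seq_len(ncol(values)), t = as.numeric(tval),
                p = as.numeric(pval))
  attr(out, "site") <- site
  attr(out, "n") <- n
  attr(out, "contrast") <- contrast
  class(out) <- c("site_test", class(out))
  out
}

#' Weighted Liptak-Stouffer combination of site tests
#'
#' Each site's two-sided p-value is transformed to a z-score,
#' \eqn{z_i = \mathrm{sign}(t_i)\,\Phi^{-1}(1 - p_i/2)}, attaching the sign
#' of the site t statistic so increases and decreases combine directionally.
#' Sites are combined per region with square-root-of-sample-size weights,
#' \deqn{z = \frac{\sum_i w_i z_i}{\sqrt{\sum_i w_i^2}}, \quad w_i = \sqrt{n_i},}
#' which is standard normal under the null; the combined two-sided p-value
#' is then corrected across regions with Benjamini-Hochberg.
#'
#' @param site_results List of [site_group_test()] results covering an
#'   identical region set.
#' @param q FDR level for the significance flag (default 0.05).
#' @return An object of class `mega_result`: tibble with columns `region`,
#'   `z` (combined), `p`, `p_adj`, `significant`, plus attributes
#'   `site_z` (regions x sites matrix), `weights`, `sites`, `k` and
#'   `contrast`.
#' @export
stouffer_combine <- function(site_results, q = 0.05) {
  stopifnot(length(site_results) >= 1)
  regions <- site_results[[1]]$region
  for (sr in site_results) {
    if (!identical(sr$region, regions)) {
      stopf("all sites must cover the identical region set")
    }
  }
  k <- length(site_results)
  site_z <- vapply(site_results, function(sr) {
    p <- sr$p
    if (any(p <= 0)) {
      warnf("p-value(s) of 0 clipped to the smallest positive double")
      p <- pmax(p, .Machine$double.xmin)
    }
    # upper-tail form of qnorm(1 - p/2): stays finite and accurate for tiny p
    sign(sr$t) * qnorm(p / 2, lower.tail = FALSE)
  }, numeric(length(regions)))
  site_z <- matrix(site_z, nrow = length(regions))
  w <- vapply(site_results, function(sr) sqrt(attr(sr, "n")), numeric(1))
  z <- as.numeric(site_z %*% w) / sqrt(sum(w^2))
  p <- pmax(2 * pnorm(-abs(z)), .Machine$double.xmin) # huge |z| underflows
  adj <- fdr_bh(p, q)
  sites <- vapply(site_results, function(sr) as.character(attr(sr, "site")),
                  character(1))
  out <- tibble(region = regions, z = z, p = p,
                p_adj = adj$p_adj, significant = adj$reject)
  attr(out, "site_z") <- site_z
  attr(out, "weights") <- w
  attr(out, "sites") <- sites
  attr(out, "k") <- k
  attr(out, "contrast") <- attr(site_results[[1]], "contrast")
  attr(out, "q") <- q
  class(out) <- c("mega_result", class(out))
  out
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Standard BH step-up: monotone adjusted p-values via
#' [stats::p.adjust()][stats::p.adjust] and the rejection mask at level `q`.
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @param q FDR level (default 0.05).
#' @return Tibble with columns `p`, `p_adj`, `reject`.
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  if (length(pvals) == 0) {
    return(tibble(p = numeric(0), p_adj = numeric(0), reject = logical(0)))
  }
  stopifnot(all(pvals > 0 & pvals <= 1))
  p_adj <- p.adjust(pvals, method = "BH")
  tibble(p = pvals, p_adj = p_adj, reject = p_adj <= q)
}

#' Multi-site mega-analysis of a centrality table
#'
#' Convenience wrapper: splits subjects by site, runs the covariate-adjusted
#' group test at every site with enough subjects in both groups, and combines
#' the sites with [stouffer_combine()].
#'
#' @param values Subjects x regions matrix (rows aligned with `subjects`).
#' @param subjects Tibble with columns `site`, `diagnosis`, `age`, `sex`.
#' @param contrast Length-2 character, e.g. `c("AD", "HC")`.
#' @param q FDR level.
#' @param min_per_group Minimum subjects per group for a site to enter.
#' @return A `mega_result` (see [stouffer_combine()]).
#' @export
mega_analysis <- function(values, subjects, contrast = c("AD", "HC"),
                          q = 0.05, min_per_group = 3) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == nrow(subjects))
  site_results <- list()
  for (s in unique(subjects$site)) {
    at <- subjects$site == s
    n_by_group <- table(factor(subjects$diagnosis[at], levels = contrast))
    if (any(n_by_group < min_per_group)) next
    site_results[[s]] <- site_group_test(
      values[at, , drop = FALSE],
      groups = subjects$diagnosis[at],
      covariates = data.frame(age = subjects$age[at],
                              sex = as.numeric(subjects$sex[at] == "M")),
      contrast = contrast, site = s
    )
  }
  if (!length(site_results)) stopf("no site has enough subjects in both groups")
  stouffer_combine(site_results, q = q)
}
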