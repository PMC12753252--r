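#' Tidy a mega-analysis result
#'
#' @param x A `mega_result`.
#' @param ... Unused.
#' @return Tibble with one row per region: `region`, `z`, `p`, `p_adj`,
#'   `significant`, `direction`.
#' @export
tidy.mega_result <- function(x, ...) {
  tibble(region = x$region, z = x$z, p = x$p, p_adj = x$p_adj,
         significant = x$significant,
         direction = ifelse(x$z >= 0, "increase", "decrease"))
}

#' One-row summary of a mega-analysis result
#'
#' @param x A `mega_result`.
#' @param ... Unused.
#' @return Tibble with `contrast`, `k_sites`, `n_regions`,
#'   `n_significant`, `n_increase`, `n_decrease`, `q`.
#' @export
glance.mega_result <- function(x, ...) {
  sig <- x$significant
  tibble(
    contrast = paste(attr(x, "contrast"), collapse = " vs "),
    k_sites = attr(x, "k"),
    n_regions = length(x$region),
    n_significant = sum(sig),
    n_increase = sum(sig & x$z > 0),
    n_decrease = sum(sig & x$z < 0),
    q = attr(x, "q")
  )
}

#' Plot a mega-analysis z map
#'
#' Combined z per region with FDR-significant regions highlighted.
#'
#' @param object A `mega_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mega_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$region, y = .data$z,
                                  colour = .data$significant)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey70",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "region", y = "combined z",
                  colour = "FDR significant",
                  title = paste(attr(object, "contrast"), collapse = " vs "))
}

#' Tidy per-site classification metrics
#'
#' @param x A `loso_classification`.
#' @param ... Unused.
#' @return The per-site metric tibble.
#' @export
tidy.loso_classification <- function(x, ...) x$per_site

#' One-row summary of leave-one-site-out classification
#'
#' @param x A `loso_classification`.
#' @param ... Unused.
#' @return Tibble with mean `acc`, `sen`, `spe`, `auc` and `n_folds`.
#' @export
glance.loso_classification <- function(x, ...) {
  dplyr::bind_cols(x$mean, tibble(n_folds = nrow(x$per_site)))
}

#' Plot per-site classification performance
#'
#' @param object A `loso_classification`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.loso_classification <- function(object, ...) {
  d <- tidyr::pivot_longer(object$per_site, c("acc", "sen", "spe", "auc"),
                           names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$site, y = .data$value,
                                  fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "grey50") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "held-out site", y = "metric value")
}

#' Tidy per-site regression correlations
#'
#' @param x A `loso_regression`.
#' @param ... Unused.
#' @return The per-site tibble.
#' @export
tidy.loso_regression <- function(x, ...) x$per_site

#' One-row summary of leave-one-site-out score regression
#'
#' @param x A `loso_regression`.
#' @param ... Unused.
#' @return Tibble with `r_mean`, `r_pooled`, `rmse`, `r_squared`.
#' @export
glance.loso_regression <- function(x, ...) {
  tibble(r_mean = x$r_mean, r_pooled = x$r_pooled, rmse = x$rmse,
         r_squared = x$r_squared)
}

#' Tidy PLS gene weights
#'
#' @param x A `pls_result`.
#' @param ... Unused.
#' @return Tibble with `gene` and one weight column per component.
#' @export
tidy.pls_result <- function(x, ...) {
  dplyr::bind_cols(tibble(gene = x$genes), as_tibble(x$weights))
}

#' One-row summary of a PLS fit
#'
#' @param x A `pls_result`.
#' @param ... Unused.
#' @return Tibble with `ncomp`, component-1 explained shares and
#'   score-response correlation.
#' @export
glance.pls_result <- function(x, ...) {
  tibble(ncomp = x$ncomp,
         pls1_gene_share = x$expl_gene[1],
         pls1_response_share = x$expl_response[1],
         pls1_score_response_r = x$cor1)
}

#' Plot per-component PLS explained-variance shares
#'
#' @param object A `pls_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pls_result <- function(object, ...) {
  d <- tibble(
    component = rep(seq_len(object$ncomp), 2),
    share = c(object$expl_gene, object$expl_response),
    block = rep(c("gene expression", "response map"), each = object$ncomp)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$component),
                                  y = .data$share, fill = .data$block)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "PLS component", y = "explained variance share")
}

#' Plot an LCC attack curve
#'
#' @param object An `lcc_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lcc_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fraction_removed,
                                       y = .data$lcc_fraction)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "fraction of regions removed",
                  y = "largest component fraction",
                  title = attr(object, "metric"))
}

#' Plot group-average attack curves
#'
#' @param curves Output of [group_attack_curves()].
#' @return A ggplot object.
#' @export
plot_group_robustness <- function(curves) {
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$fraction_removed,
                                       y = .data$lcc_fraction,
                                       colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "fraction of regions removed",
                  y = "largest component fraction", colour = "group")
}
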