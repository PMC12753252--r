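#' Configure an end-to-end pipeline run
#'
#' Bundles every stage's options: cohort source (a [cohort_config()] for
#' synthetic runs, or a directory written by [write_cohort()]), network
#' density and optional sweep list, centrality metrics, group contrasts, FDR
#' level, prediction/PLS toggles, and the seed from which all randomness is
#' derived.
#'
#' @param cohort A `cohort_config`, a `synthetic_cohort`, or a directory
#'   path containing `subjects.tsv` and `timeseries/`.
#' @param density Network density (default 0.04).
#' @param densities Optional density list for the sensitivity sweep.
#' @param metrics Centrality metrics for the mega-analysis stage.
#' @param contrasts List of length-2 character contrasts.
#' @param q FDR level.
#' @param sigma Either `"template"` (select sigma once on the mean HC
#'   network; default) or `"per_subject"`.
#' @param run_prediction,run_pls Stage toggles.
#' @param gene_matrix Optional regions x genes matrix for the PLS stage; if
#'   `NULL` and the cohort is synthetic with planted effects, a gene matrix
#'   with a component covarying with the planted-effect map is generated.
#' @param n_genes,n_signal_genes,gene_noise_sd Synthetic gene-matrix
#'   parameters.
#' @param pls_permutations,pls_bootstraps Iteration counts for PLS
#'   inference.
#' @param seed Integer master seed.
#' @param output_dir Optional directory for per-stage artifacts.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort,
                            density = 0.04,
                            densities = NULL,
                            metrics = "domirank",
                            contrasts = list(c("AD", "HC")),
                            q = 0.05,
                            sigma = c("template", "per_subject"),
                            run_prediction = TRUE,
                            run_pls = TRUE,
                            gene_matrix = NULL,
                            n_genes = 2000,
                            n_signal_genes = 200,
                            gene_noise_sd = 1,
                            pls_permutations = 1000,
                            pls_bootstraps = 200,
                            seed = 1L) {
  sigma <- match.arg(sigma)
  stopifnot(density > 0, density <= 1)
  if (!is.null(densities)) stopifnot(all(densities > 0 & densities <= 1))
  structure(list(
    cohort = cohort, density = density, densities = densities,
    metrics = metrics, contrasts = contrasts, q = q, sigma = sigma,
    run_prediction = run_prediction, run_pls = run_pls,
    gene_matrix = gene_matrix, n_genes = n_genes,
    n_signal_genes = n_signal_genes, gene_noise_sd = gene_noise_sd,
    pls_permutations = pls_permutations, pls_bootstraps = pls_bootstraps,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

resolve_cohort <- function(cohort) {
  if (inherits(cohort, "synthetic_cohort")) return(cohort)
  if (inherits(cohort, "cohort_config")) return(generate_cohort(cohort))
  if (is.character(cohort) && dir.exists(cohort)) {
    subjects <- read_subject_table(file.path(cohort, "subjects.tsv"))
    series <- lapply(subjects$id, function(id) {
      read_matrix(file.path(cohort, "timeseries", paste0(id, ".tsv")))
    })
    names(series) <- subjects$id
    return(structure(list(subjects = subjects, time_series = series,
                          truth = NULL, config = NULL),
                     class = "synthetic_cohort"))
  }
  stopf("cohort must be a cohort_config, a synthetic_cohort, or a directory")
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order on a synthetic or loaded cohort: network
#' construction (Fisher-z + spanning-tree-constrained proportional
#' threshold), sigma selection, DomiRank and requested classical
#' centralities, multi-site mega-analysis per contrast, group-level
#' attack-robustness curves, leave-one-site-out classification and MMSE
#' prediction, region-wise cognition association, and the PLS
#' transcriptomic stage. Fully seeded: the same config and seed reproduce
#' the identical report.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `pipeline_report`: list with per-stage results
#'   (`cohort`, `networks`, `sigma`, `centrality`, `mega`, `robustness`,
#'   `prediction`, `pls`, `sweep`) and a flat numeric `summary` list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- resolve_cohort(config$cohort)
  subjects <- cohort$subjects

  nets <- purrr::imap(cohort$time_series, function(ts, id) {
    threshold_mst(compute_fc(ts, subject_id = id), density = config$density)
  })

  sigma_sel <- NULL
  if (config$sigma == "template") {
    hc_ids <- subjects$id[subjects$diagnosis == "HC"]
    if (!length(hc_ids)) hc_ids <- subjects$id
    zbar <- Reduce(`+`, lapply(cohort$time_series[hc_ids],
                               function(ts) compute_fc(ts)$z)) / length(hc_ids)
    template <- threshold_mst(zbar, density = config$density)
    # shared sigma must be feasible for every subject's network, so the scan
    # is capped just below the smallest per-subject bound
    uppers <- vapply(nets, function(nt) {
      sigma_feasible_interval(nt)$upper_bound
    }, numeric(1))
    sigma_sel <- select_sigma(template, sigma_max = 0.95 * min(uppers))
    sigma_use <- sigma_sel$sigma
  } else {
    sigma_use <- "per_subject"
  }

  centrality <- cohort_centrality(nets, sigma = sigma_use,
                                  metrics = config$metrics)
  dom <- centrality_matrix(centrality, metric = config$metrics[1])
  dom <- dom[subjects$id, , drop = FALSE]

  mega <- lapply(config$contrasts, function(ct) {
    mega_analysis(dom, subjects, contrast = ct, q = config$q)
  })
  names(mega) <- vapply(config$contrasts, paste, character(1), collapse = "_vs_")

  curves <- purrr::imap(nets, function(net, id) {
    targeted_attack_curve(net, dom[id, ], metric = config$metrics[1])
  })
  robustness <- group_attack_curves(curves, subjects$diagnosis)
  areas <- dplyr::summarise(
    dplyr::group_by(robustness, .data$group),
    area = trapezoid_area(.data$fraction_removed, .data$lcc_fraction),
    .groups = "drop"
  )

  prediction <- NULL
  if (config$run_prediction) {
    cls <- loso_classify(dom, subjects$diagnosis, subjects$site,
                         levels = c("AD", "HC"), seed = config$seed)
    patient <- subjects$diagnosis %in% c("AD", "MCI")
    reg <- if ("mmse" %in% names(subjects)) {
      loso_regress_scores(dom, subjects$mmse, subjects$site)
    } else {
      NULL
    }
    assoc <- if ("mmse" %in% names(subjects) && sum(patient) > 20) {
      cognition_association(dom[patient, , drop = FALSE],
                            subjects$mmse[patient], subjects$age[patient],
                            subjects$sex[patient], subjects$site[patient],
                            q = config$q)
    } else {
      NULL
    }
    prob_cor <- NA_real_
    if ("mmse" %in% names(subjects)) {
      mm <- subjects$mmse[cls$predictions$row]
      if (sd(mm) > 0) prob_cor <- cor(cls$predictions$prob_positive, mm)
    }
    prediction <- list(classification = cls, regression = reg,
                       association = assoc, prob_mmse_cor = prob_cor)
  }

  pls <- NULL
  if (config$run_pls) {
    zmap <- mega[[1]]$z
    genes <- config$gene_matrix
    if (is.null(genes)) {
      signal_map <- zmap # spatial profile the planted signal genes follow
      genes <- generate_gene_expression(
        n_regions = length(zmap), n_genes = config$n_genes,
        signal_map = signal_map, n_signal_genes = config$n_signal_genes,
        signal_weight = 0.8 * sd(zmap), noise_sd = config$gene_noise_sd,
        seed = substream_seed(config$seed, 99003L)
      )
    }
    fit <- pls_fit(zmap, genes, ncomp = min(10, nrow(genes) - 1))
    perm <- pls_permutation(zmap, genes, B = config$pls_permutations,
                            seed = config$seed)
    boot <- pls_bootstrap(zmap, genes, B = config$pls_bootstraps,
                          seed = config$seed)
    top <- rank_top_genes(fit, k = min(500, ncol(genes)))
    pls <- list(fit = fit, permutation = perm, bootstrap = boot, top = top,
                map_score_cor = fit$cor1)
  }

  sweep <- NULL
  if (!is.null(config$densities)) {
    sweep <- density_sweep(cohort, config, sigma_use)
  }

  report <- structure(list(
    cohort = cohort, networks = nets, sigma = sigma_sel,
    centrality = centrality, mega = mega,
    robustness = list(curves = robustness, areas = areas),
    prediction = prediction, pls = pls, sweep = sweep,
    config = config
  ), class = "pipeline_report")
  report$summary <- summarise_report(report)
  report
}

summarise_report <- function(report) {
  out <- list(
    n_subjects = nrow(report$cohort$subjects),
    n_regions = nrow(report$networks[[1]]$A),
    n_edges = report$networks[[1]]$n_edges,
    sigma = if (!is.null(report$sigma)) report$sigma$sigma else NA_real_
  )
  for (nm in names(report$mega)) {
    out[[paste0("n_significant_", nm)]] <- sum(report$mega[[nm]]$significant)
  }
  truth_regions <- report$cohort$truth$effect_regions
  if (length(truth_regions)) {
    hit <- report$mega[[1]]$significant[truth_regions]
    out$planted_regions <- length(truth_regions)
    out$planted_recovered <- sum(hit)
  }
  if (!is.null(report$prediction)) {
    out <- c(out, list(
      loso_auc = report$prediction$classification$mean$auc,
      loso_acc = report$prediction$classification$mean$acc,
      loso_sen = report$prediction$classification$mean$sen,
      loso_spe = report$prediction$classification$mean$spe
    ))
    if (!is.null(report$prediction$regression)) {
      out$mmse_r <- report$prediction$regression$r_mean
      out$mmse_rmse <- report$prediction$regression$rmse
      out$mmse_r2 <- report$prediction$regression$r_squared
    }
    out$prob_mmse_cor <- report$prediction$prob_mmse_cor
  }
  if (!is.null(report$pls)) {
    out$pls1_gene_share <- report$pls$fit$expl_gene[1]
    out$pls1_response_share <- report$pls$fit$expl_response[1]
    out$pls1_perm_p <- report$pls$permutation$p_value
    out$pls1_map_cor <- report$pls$map_score_cor
  }
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  s <- x$summary
  for (nm in names(s)) {
    v <- s[[nm]]
    cat(sprintf("  %-24s %s\n", nm,
                if (is.numeric(v)) format(signif(v, 4)) else as.character(v)))
  }
  invisible(x)
}

#' Density sensitivity sweep
#'
#' Recomputes the first-contrast mega-analysis z map at each density and
#' returns the pairwise Pearson similarity matrix between the maps --
#' the check that group-difference topography is stable across network
#' sparsity choices.
#'
#' @param cohort A `synthetic_cohort` (or anything [run_pipeline()] accepts
#'   as a cohort).
#' @param config A `pipeline_config` with a non-`NULL` `densities` list.
#' @param sigma Sigma passed to [cohort_centrality()] (value or
#'   `"per_subject"`).
#' @return List with `z_maps` (regions x densities matrix) and `similarity`
#'   (densities x densities correlation matrix).
#' @export
density_sweep <- function(cohort, config, sigma) {
  cohort <- resolve_cohort(cohort)
  subjects <- cohort$subjects
  densities <- config$densities
  fcs <- lapply(cohort$time_series, compute_fc)
  z_maps <- vapply(densities, function(d) {
    nets <- lapply(fcs, threshold_mst, density = d)
    names(nets) <- names(fcs)
    cent <- cohort_centrality(nets, sigma = sigma, metrics = config$metrics[1])
    vals <- centrality_matrix(cent, config$metrics[1])[subjects$id, , drop = FALSE]
    mega_analysis(vals, subjects, contrast = config$contrasts[[1]],
                  q = config$q)$z
  }, numeric(cohort$config$n_regions %||% nrow(fcs[[1]]$z)))
  colnames(z_maps) <- paste0("d", densities)
  sim <- cor(z_maps)
  list(z_maps = z_maps, similarity = sim)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a pipeline report's artifacts
#'
#' Tab-separated per-stage tables plus the flat summary as JSON; rerunning
#' the pipeline with the same config and seed regenerates the files
#' byte-identically.
#'
#' @param report A `pipeline_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  for (nm in names(report$mega)) {
    w(as.data.frame(report$mega[[nm]]), paste0("mega_", nm, ".tsv"))
  }
  w(as.data.frame(report$robustness$curves), "robustness_curves.tsv")
  if (!is.null(report$prediction)) {
    w(as.data.frame(report$prediction$classification$per_site),
      "loso_classification.tsv")
    if (!is.null(report$prediction$regression)) {
      w(as.data.frame(report$prediction$regression$predictions),
        "mmse_predictions.tsv")
    }
  }
  if (!is.null(report$pls)) {
    w(as.data.frame(report$pls$top), "pls_top_genes.tsv")
  }
  jsonlite::write_json(report$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
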