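#' Configure a synthetic multi-site cohort
#'
#' Describes a multi-site case-control resting-state cohort with known planted
#' structure: a block ("community") baseline correlation pattern shared by all
#' subjects, group-specific connectivity shifts expressed in Fisher-z units on
#' designated edges, per-site global connectivity offsets, linear age/sex
#' effects, and cognition scores (MMSE/MoCA) whose decline tracks each
#' patient's planted effect magnitude. Every downstream stage of the pipeline
#' can therefore be checked against the configuration's ground truth.
#'
#' Planted effects are applied in Fisher-z space and back-transformed to
#' correlations before factorisation, so an edge configured with `dz = 0.5`
#' shifts the population Fisher-z of that edge by exactly 0.5 in the affected
#' group -- the same units in which the pipeline measures group differences.
#'
#' @param per_site_group_sizes List with one integer vector `c(HC, MCI, AD)`
#'   per site.
#' @param n_regions Number of brain regions (default 246, Brainnetome-style).
#' @param n_timepoints Length of each regional time series (default 170).
#' @param n_blocks Number of communities in the baseline correlation pattern.
#' @param within_r,between_r Baseline Pearson correlation within / between
#'   communities.
#' @param effect_edges Data frame with columns `i`, `j`, `dz_mci`, `dz_ad`:
#'   Fisher-z shifts planted on edge (i, j) in the MCI and AD groups (HC is
#'   the reference). `NULL` for a null cohort.
#' @param effect_regions Optional integer vector of regions whose within-block
#'   edges are attenuated in patients; expanded into `effect_edges` via
#'   [hub_attenuation_edges()] when `effect_edges` is `NULL`.
#' @param effect_dz Fisher-z attenuation used with `effect_regions`
#'   (applied as `-effect_dz` in AD and `-effect_dz/2` in MCI).
#' @param site_offset_sd SD of the per-site Fisher-z offset, applied to all
#'   within-community edges (site/scanner effects modulate measured network
#'   coupling; weak between-community correlations are left at baseline so
#'   offsets cannot push the matrix outside positive definiteness).
#' @param age_beta,sex_beta Linear Fisher-z effect per year of age (centred at
#'   68) and for male sex, applied to within-community edges like the site
#'   offset.
#' @param age_mean,age_sd Per-site age distribution.
#' @param cognition MMSE/MoCA group means and SDs plus `loading`, the score
#'   penalty per unit of excess planted-effect severity.
#' @param severity_sd SD of the per-patient severity multiplier (mean 1)
#'   scaling that patient's planted edge shifts.
#' @param seed Integer seed; expanded into per-subject substreams so that
#'   changing the subject count does not perturb earlier subjects' draws.
#'
#' @return An object of class `cohort_config`.
#' @seealso [generate_cohort()], [seven_site_config()]
#' @export
cohort_config <- function(per_site_group_sizes = list(c(20, 20, 20)),
                          n_regions = 246,
                          n_timepoints = 170,
                          n_blocks = 20,
                          within_r = 0.45,
                          between_r = 0.08,
                          effect_edges = NULL,
                          effect_regions = NULL,
                          effect_dz = 0.5,
                          site_offset_sd = 0.05,
                          age_beta = -0.002,
                          sex_beta = 0.01,
                          age_mean = 68,
                          age_sd = 7,
                          cognition = list(
                            mmse_mean = c(HC = 28.5, MCI = 25, AD = 16),
                            mmse_sd = c(HC = 2, MCI = 3, AD = 6),
                            moca_mean = c(HC = 26, MCI = 22, AD = 13),
                            moca_sd = c(HC = 2, MCI = 3, AD = 6),
                            loading = 4
                          ),
                          severity_sd = 0.25,
                          seed = 1L) {
  stopifnot(length(per_site_group_sizes) >= 1, n_regions > 0, n_timepoints > 0,
            n_blocks > 0)
  sizes <- lapply(per_site_group_sizes, function(x) {
    x <- as.integer(x)
    if (length(x) != 3 || any(x < 0)) {
      stopf("each site needs nonnegative sizes c(HC, MCI, AD)")
    }
    x
  })
  cfg <- structure(list(
    per_site_group_sizes = sizes,
    n_sites = length(sizes),
    n_regions = as.integer(n_regions),
    n_timepoints = as.integer(n_timepoints),
    n_blocks = as.integer(n_blocks),
    within_r = within_r,
    between_r = between_r,
    effect_edges = effect_edges,
    effect_regions = effect_regions,
    effect_dz = effect_dz,
    site_offset_sd = site_offset_sd,
    age_beta = age_beta,
    sex_beta = sex_beta,
    age_mean = age_mean,
    age_sd = age_sd,
    cognition = cognition,
    severity_sd = severity_sd,
    seed = as.integer(seed)
  ), class = "cohort_config")
  if (is.null(cfg$effect_edges) && !is.null(effect_regions)) {
    cfg$effect_edges <- hub_attenuation_edges(cfg, effect_regions, effect_dz)
  }
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  ee <- cfg$effect_edges
  if (!is.null(ee)) {
    stopifnot(all(c("i", "j", "dz_mci", "dz_ad") %in% names(ee)))
    if (any(ee$i < 1 | ee$i > cfg$n_regions | ee$j < 1 | ee$j > cfg$n_regions)) {
      stopf("effect edge indices must lie in 1..n_regions")
    }
    if (any(ee$i == ee$j)) stopf("effect edges must join distinct regions")
    if (any(!is.finite(ee$dz_mci)) || any(!is.finite(ee$dz_ad))) {
      stopf("planted effect sizes must be finite")
    }
  }
  invisible(cfg)
}

#' Build hub-attenuation effect edges for designated regions
#'
#' For each designated region, plants negative Fisher-z shifts on its edges
#' to every other member of its community block, emulating the loss of hub
#' dominance seen in patients: the full shift in AD, half of it in MCI.
#' Uniform attenuation of the whole block neighbourhood keeps the shifted
#' correlation matrix positive definite; attenuating only part of a tightly
#' correlated block is geometrically infeasible for shifts of this size.
#'
#' @param config A `cohort_config` (block assignment is read from it).
#' @param regions Integer vector of affected regions.
#' @param dz Magnitude of the Fisher-z attenuation in AD.
#' @return Data frame with columns `i`, `j`, `dz_mci`, `dz_ad`.
#' @export
hub_attenuation_edges <- function(config, regions, dz = 0.5) {
  blocks <- region_blocks(config$n_regions, config$n_blocks)
  out <- lapply(regions, function(r) {
    mates <- setdiff(which(blocks == blocks[r]), r)
    data.frame(i = pmin(r, mates), j = pmax(r, mates),
               dz_mci = -dz / 2, dz_ad = -dz)
  })
  out <- do.call(rbind, out)
  out[!duplicated(out[, c("i", "j")]), , drop = FALSE]
}

# contiguous community assignment of regions to blocks
region_blocks <- function(n_regions, n_blocks) {
  sort(rep_len(seq_len(n_blocks), n_regions))
}

# baseline Fisher-z matrix implied by the block pattern (zero diagonal)
base_z_matrix <- function(cfg) {
  blocks <- region_blocks(cfg$n_regions, cfg$n_blocks)
  same <- outer(blocks, blocks, "==")
  r <- ifelse(same, cfg$within_r, cfg$between_r)
  z <- atanh(r)
  diag(z) <- 0
  z
}

#' Generate a synthetic multi-site cohort
#'
#' Draws per-subject regional time series from a multivariate normal model
#' whose population correlation matrix is the back-transform of the configured
#' baseline Fisher-z pattern plus group-specific planted shifts, per-site
#' offsets, and linear age/sex effects. Cognition scores are drawn from
#' group-specific normals and decline with each patient's planted-effect
#' severity, so predicted disease probability and cognition are negatively
#' coupled by construction.
#'
#' The global seed is expanded into per-subject substreams: adding subjects or
#' sites never changes the draws of earlier subjects.
#'
#' @param config A [cohort_config()].
#' @return An object of class `synthetic_cohort`: a list with `subjects`
#'   (tibble: id, site, diagnosis, age, sex, mmse, moca, severity),
#'   `time_series` (named list of regions x timepoints matrices), `truth`
#'   (the planted effect specification) and `config`.
#' @examples
#' cfg <- cohort_config(per_site_group_sizes = list(c(5, 0, 5)),
#'                      n_regions = 20, n_timepoints = 40, n_blocks = 4,
#'                      seed = 7)
#' coh <- generate_cohort(cfg)
#' coh$subjects
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  z0 <- base_z_matrix(config)
  blocks <- region_blocks(config$n_regions, config$n_blocks)
  within_mask <- outer(blocks, blocks, "==")
  diag(within_mask) <- FALSE
  groups <- c("HC", "MCI", "AD")

  # per-site global offsets drawn from a site-level substream
  site_offsets <- vapply(seq_len(config$n_sites), function(s) {
    set.seed(substream_seed(config$seed, 1000000L + s))
    rnorm(1, 0, config$site_offset_sd)
  }, numeric(1))

  subj_rows <- list()
  series <- list()
  idx <- 0L
  for (s in seq_len(config$n_sites)) {
    sizes <- config$per_site_group_sizes[[s]]
    for (g in 1:3) {
      for (k in seq_len(sizes[g])) {
        idx <- idx + 1L
        subj <- draw_subject(config, z0, within_mask, site = s,
                             group = groups[g],
                             site_offset = site_offsets[s], index = idx)
        subj_rows[[idx]] <- subj$row
        series[[idx]] <- subj$ts
      }
    }
  }
  subjects <- dplyr::bind_rows(subj_rows)
  names(series) <- subjects$id
  structure(list(
    subjects = subjects,
    time_series = series,
    truth = list(effect_edges = config$effect_edges,
                 effect_regions = effect_regions_of(config),
                 site_offsets = site_offsets),
    config = config
  ), class = "synthetic_cohort")
}

# designated effect regions for recovery checks: the configured hubs when
# given, otherwise every region touched by a planted edge
effect_regions_of <- function(config) {
  if (!is.null(config$effect_regions)) {
    return(sort(unique(as.integer(config$effect_regions))))
  }
  ee <- config$effect_edges
  if (is.null(ee)) return(integer(0))
  sort(unique(c(ee$i[ee$dz_ad != 0 | ee$dz_mci != 0],
                ee$j[ee$dz_ad != 0 | ee$dz_mci != 0])))
}

draw_subject <- function(config, z0, within_mask, site, group, site_offset,
                         index) {
  set.seed(substream_seed(config$seed, index))
  age <- rnorm(1, config$age_mean, config$age_sd)
  sex <- rbinom(1, 1, 0.5)
  # severity multiplier scaling the planted shifts; clipped so extreme draws
  # cannot push the shifted correlation matrix outside positive definiteness
  severity <- if (group == "HC") 0 else min(abs(rnorm(1, 1, config$severity_sd)), 1.4)

  z <- z0
  z[within_mask] <- z[within_mask] + site_offset +
    config$age_beta * (age - config$age_mean) +
    config$sex_beta * sex
  ee <- config$effect_edges
  if (!is.null(ee) && group != "HC") {
    dz <- if (group == "AD") ee$dz_ad else ee$dz_mci
    ij <- cbind(ee$i, ee$j)
    z[ij] <- z[ij] + severity * dz
    z[ij[, 2:1, drop = FALSE]] <- z[ij]
  }
  r <- tanh(z)
  diag(r) <- 1
  L <- tryCatch(chol(r), error = function(e) {
    minor <- regmatches(conditionMessage(e),
                        regexpr("[0-9]+", conditionMessage(e)))
    stopf("requested covariance is not positive definite (leading minor of order %s violated) for subject %d",
          if (length(minor)) minor else "?", index)
  })
  e <- matrix(rnorm(config$n_timepoints * config$n_regions),
              config$n_timepoints, config$n_regions)
  ts <- t(e %*% L) # regions x timepoints, population correlation = r

  cg <- config$cognition
  pen <- cg$loading * (severity - 1) * (group != "HC")
  mmse <- min(30, max(0, rnorm(1, cg$mmse_mean[[group]] - pen, cg$mmse_sd[[group]])))
  moca <- min(30, max(0, rnorm(1, cg$moca_mean[[group]] - pen, cg$moca_sd[[group]])))

  list(row = tibble(
    id = sprintf("sub-%04d", index),
    site = sprintf("S%02d", site),
    diagnosis = group,
    age = age,
    sex = c("F", "M")[sex + 1L],
    mmse = mmse,
    moca = moca,
    severity = severity
  ), ts = ts)
}

#' Preset cohort emulating a seven-site memory-clinic study
#'
#' Seven sites with per-site HC/MCI/AD group sizes 41/34/44, 21/23/24,
#' 24/33/37, 42/16/66, 64/93/39, 21/18/33 and 42/37/41 (793 subjects in
#' total), 246 regions, and -- unless overridden -- ten attenuated hub regions
#' planted with a Fisher-z reduction of 0.5 in AD (0.25 in MCI).
#'
#' @param effect_regions Regions whose hub connectivity is attenuated;
#'   defaults to ten regions spread across communities.
#' @param effect_dz Planted Fisher-z attenuation in AD.
#' @param ... Further arguments passed to [cohort_config()]
#'   (e.g. `n_timepoints`, `seed`).
#' @return A `cohort_config`.
#' @export
seven_site_config <- function(effect_regions = seq(10, 240, length.out = 10),
                              effect_dz = 0.5, ...) {
  cohort_config(
    per_site_group_sizes = list(
      c(41, 34, 44), c(21, 23, 24), c(24, 33, 37), c(42, 16, 66),
      c(64, 93, 39), c(21, 18, 33), c(42, 37, 41)
    ),
    n_regions = 246,
    effect_regions = as.integer(round(effect_regions)),
    effect_dz = effect_dz,
    ...
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  tab <- table(x$subjects$site, x$subjects$diagnosis)
  cat(sprintf("<synthetic_cohort> %d subjects, %d sites, %d regions x %d timepoints\n",
              nrow(x$subjects), length(unique(x$subjects$site)),
              x$config$n_regions, x$config$n_timepoints))
  print(tab)
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Subject table as tab-separated values, one delimited text matrix per
#' subject (regions in rows), and the planted-truth specification as JSON.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(cohort$subjects, file.path(dir, "subjects.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dir.create(file.path(dir, "timeseries"), showWarnings = FALSE)
  for (id in names(cohort$time_series)) {
    write_matrix(cohort$time_series[[id]],
                 file.path(dir, "timeseries", paste0(id, ".tsv")))
  }
  truth <- cohort$truth
  truth$effect_edges <- as.data.frame(truth$effect_edges)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
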