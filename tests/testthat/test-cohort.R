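test_that("cohorts are bit-identical given seed and stable under extension", {
  cfg <- cohort_config(per_site_group_sizes = list(c(4, 3, 4), c(5, 4, 3)),
                       n_regions = 16, n_timepoints = 30, n_blocks = 4,
                       seed = 12)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$time_series, b$time_series)

  # appending a site leaves earlier subjects' draws untouched (substreams)
  cfg2 <- cohort_config(per_site_group_sizes = list(c(4, 3, 4), c(5, 4, 3),
                                                    c(6, 6, 6)),
                        n_regions = 16, n_timepoints = 30, n_blocks = 4,
                        seed = 12)
  c3 <- generate_cohort(cfg2)
  expect_identical(a$time_series[[1]], c3$time_series[[1]])
  expect_identical(a$time_series[[23]], c3$time_series[[23]])
})

test_that("group labels, sizes and cognition scores follow the configuration", {
  cfg <- cohort_config(per_site_group_sizes = list(c(6, 5, 7)),
                       n_regions = 12, n_timepoints = 25, n_blocks = 3,
                       seed = 4)
  coh <- generate_cohort(cfg)
  tab <- table(coh$subjects$diagnosis)
  expect_equal(as.integer(tab[c("HC", "MCI", "AD")]), c(6, 5, 7))
  expect_true(all(vapply(coh$time_series, function(m) all(is.finite(m)),
                         logical(1))))
  expect_true(all(coh$subjects$mmse >= 0 & coh$subjects$mmse <= 30))
  # HC severity identically zero; patients positive
  expect_true(all(coh$subjects$severity[coh$subjects$diagnosis == "HC"] == 0))
  expect_true(all(coh$subjects$severity[coh$subjects$diagnosis != "HC"] > 0))
  # truth echoes the configuration
  expect_identical(coh$truth$effect_edges, cfg$effect_edges)
})

test_that("planted Fisher-z shifts are recovered empirically on effect edges", {
  # 20 designated edges with dz = 0.5 in AD; Monte-Carlo oracle of the mean
  # empirical z difference across replicates
  edges <- data.frame(i = 1:20, j = 21:40, dz_mci = 0, dz_ad = 0.5)
  diffs <- vapply(1:10, function(rep) {
    cfg <- cohort_config(per_site_group_sizes = list(c(40, 0, 40)),
                         n_regions = 40, n_timepoints = 120, n_blocks = 40,
                         effect_edges = edges, site_offset_sd = 0,
                         age_beta = 0, sex_beta = 0, severity_sd = 0,
                         seed = 600 + rep)
    coh <- generate_cohort(cfg)
    zs <- vapply(coh$time_series, function(ts) {
      z <- compute_fc(ts)$z
      mean(z[cbind(edges$i, edges$j)])
    }, numeric(1))
    ad <- coh$subjects$diagnosis == "AD"
    mean(zs[ad]) - mean(zs[!ad])
  }, numeric(1))
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - 0.5), 3 * se + 0.02)
})

test_that("the seven-site preset matches the published group sizes", {
  cfg <- seven_site_config(seed = 1, n_timepoints = 10)
  expect_equal(cfg$n_sites, 7)
  expect_equal(cfg$n_regions, 246L)
  sizes <- do.call(rbind, cfg$per_site_group_sizes)
  expect_equal(sizes[, 1], c(41, 21, 24, 42, 64, 21, 42)) # HC
  expect_equal(sizes[, 2], c(34, 23, 33, 16, 93, 18, 37)) # MCI
  expect_equal(sizes[, 3], c(44, 24, 37, 66, 39, 33, 41)) # AD
  expect_equal(sum(sizes), 793)
  expect_length(cfg$effect_regions, 10)
})

test_that("invalid configurations fail fast", {
  expect_error(
    cohort_config(per_site_group_sizes = list(c(3, -1, 2))),
    "nonnegative"
  )
  expect_error(
    cohort_config(per_site_group_sizes = list(c(3, 3, 3)), n_regions = 10,
                  effect_edges = data.frame(i = 5, j = 50, dz_mci = 0,
                                            dz_ad = 0.2)),
    "1..n_regions"
  )
  expect_error(
    cohort_config(per_site_group_sizes = list(c(3, 3, 3)), n_regions = 10,
                  effect_edges = data.frame(i = 1, j = 2, dz_mci = Inf,
                                            dz_ad = 0)),
    "finite"
  )
  # infeasible covariance: named leading minor
  cfg_bad <- cohort_config(
    per_site_group_sizes = list(c(2, 0, 2)), n_regions = 8,
    n_timepoints = 20, n_blocks = 1, within_r = 0.3,
    effect_edges = data.frame(i = 1, j = 2:5, dz_mci = 0, dz_ad = -3),
    severity_sd = 0, seed = 5
  )
  expect_error(generate_cohort(cfg_bad), "leading minor")
})

test_that("gene-expression generator plants a recoverable spatial component", {
  map <- sin(seq_len(40))
  # no noise: signal genes equal the map exactly (correlation 1)
  g0 <- generate_gene_expression(40, 50, signal_map = map,
                                 n_signal_genes = 5, signal_weight = 1,
                                 noise_sd = 0, seed = 3)
  sg <- attr(g0, "signal_genes")
  expect_length(sg, 5)
  for (j in sg) expect_equal(cor(map, g0[, j]), 1, tolerance = 1e-12)

  # pure noise: mean |correlation| near the closed-form null level
  g1 <- generate_gene_expression(40, 400, signal_weight = 0, seed = 3)
  expect_length(attr(g1, "signal_genes"), 0)
  null_level <- sqrt(2 / pi) / sqrt(40 - 1) # E|r| for null correlation
  mean_abs <- mean(abs(cor(map, g1)))
  expect_lt(abs(mean_abs - null_level), 3 * null_level / sqrt(400))

  # requested shape is honoured exactly
  g2 <- generate_gene_expression(238, 15633, signal_weight = 0, seed = 1)
  expect_equal(dim(g2), c(238, 15633))

  expect_warning(
    generate_gene_expression(10, 5, signal_map = rep(1, 10),
                             n_signal_genes = 2, signal_weight = 1,
                             noise_sd = 1, seed = 1),
    "zero variance"
  )
  expect_error(
    generate_gene_expression(10, 5, signal_map = rep(1, 3),
                             n_signal_genes = 2, signal_weight = 1),
    "length"
  )
})

test_that("cohorts round-trip through disk", {
  coh <- generate_cohort(cohort_config(
    per_site_group_sizes = list(c(3, 0, 3)), n_regions = 8,
    n_timepoints = 15, n_blocks = 2, seed = 21
  ))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  subjects <- read_subject_table(file.path(dir, "subjects.tsv"))
  expect_equal(subjects$id, coh$subjects$id)
  expect_equal(subjects$mmse, coh$subjects$mmse, tolerance = 1e-10)
  ts1 <- read_matrix(file.path(dir, "timeseries",
                               paste0(coh$subjects$id[1], ".tsv")),
                     n_regions = 8)
  expect_equal(ts1, unname(coh$time_series[[1]]), tolerance = 1e-10)
})
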