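test_that("a response equal to one gene's profile is captured perfectly", {
  set.seed(20)
  n <- 30
  response <- rnorm(n)
  # other genes exactly orthogonal to the response, so the first weight
  # vector loads on the matching gene alone
  raw <- matrix(rnorm(n * 24), n)
  ortho <- apply(raw, 2, function(g) stats::residuals(stats::lm(g ~ response)))
  genes <- cbind(ortho[, 1:6], response, ortho[, 7:24])
  fit <- pls_fit(response, genes, ncomp = 3)
  expect_equal(abs(cor(fit$scores[, 1], response)), 1, tolerance = 1e-8)
  # orientation convention: score-response correlation nonnegative
  expect_gte(fit$cor1, 0)
})

test_that("first component dominates and shares are valid over random instances", {
  set.seed(21)
  for (i in 1:50) {
    y <- rnorm(25)
    X <- matrix(rnorm(25 * 40), 25)
    fit <- pls_fit(y, X, ncomp = 5)
    expect_true(all(fit$expl_gene >= 0 & fit$expl_gene <= 1))
    expect_true(all(fit$expl_response >= 0 & fit$expl_response <= 1))
    expect_lte(sum(fit$expl_response), 1 + 1e-10)
    # component 1 carries the largest response share; later components may
    # fluctuate but only within a small fraction of it
    expect_equal(max(fit$expl_response), fit$expl_response[1])
    expect_true(all(diff(fit$expl_response) <= 0.03 * fit$expl_response[1]))
  }
})

test_that("PLS1 agrees with an independent implementation on random data", {
  set.seed(22)
  y <- rnorm(30)
  X <- matrix(rnorm(30 * 20), 30)
  fit <- pls_fit(y, X, ncomp = 2)
  ref <- mixOmics::pls(X, y, ncomp = 2, scale = TRUE, mode = "regression")
  w_ref <- ref$loadings$X[, 1]
  align <- sign(sum(w_ref * fit$weights[, 1]))
  expect_equal(abs(cor(fit$weights[, 1], align * w_ref)), 1, tolerance = 1e-6)
  expect_equal(abs(cor(fit$scores[, 1], ref$variates$X[, 1])), 1,
               tolerance = 1e-6)
})

test_that("planted gene-map association is detected against its permutation null", {
  set.seed(23)
  map <- rnorm(40)
  genes <- generate_gene_expression(40, 300, signal_map = map,
                                    n_signal_genes = 60, signal_weight = 0.8,
                                    noise_sd = 1, seed = 23)
  perm <- pls_permutation(map, genes, B = 199, seed = 23)
  expect_lt(perm$p_value, 0.05)
  expect_gt(perm$observed, stats::quantile(perm$null, 0.95))
})

test_that("exact permutation p equals exhaustive enumeration by an independent oracle", {
  set.seed(24)
  y <- rnorm(6)
  X <- matrix(rnorm(6 * 12), 6)
  got <- pls_permutation(y, X, exact = TRUE)
  perms <- oracle_permutations(6)
  expect_length(perms, 720)
  null <- vapply(perms, function(p) oracle_pls1_share(y[p], X), numeric(1))
  obs <- oracle_pls1_share(y, X)
  expect_equal(got$observed, obs, tolerance = 1e-10)
  expect_equal(got$p_value, mean(null >= obs - 1e-12), tolerance = 1e-10)
  expect_error(pls_permutation(rnorm(9), matrix(rnorm(90), 9), exact = TRUE),
               "<= 8")
})

test_that("a strong planted association attains the minimal permutation p", {
  set.seed(25)
  map <- rnorm(30)
  genes <- generate_gene_expression(30, 150, signal_map = map,
                                    n_signal_genes = 50, signal_weight = 3,
                                    noise_sd = 0.3, seed = 25)
  B <- 99
  perm <- pls_permutation(map, genes, B = B, seed = 25)
  expect_equal(perm$p_value, 1 / (B + 1))
})

test_that("bootstrap weight stability separates signal from noise genes", {
  set.seed(26)
  map <- rnorm(35)
  genes <- generate_gene_expression(35, 120, signal_map = map,
                                    n_signal_genes = 30, signal_weight = 1,
                                    noise_sd = 0.8, seed = 26)
  sg <- attr(genes, "signal_genes")
  boot <- pls_bootstrap(map, genes, B = 150, seed = 26)
  expect_true(all(boot$boot_se > 0))
  z_signal <- mean(abs(boot$z[sg]))
  z_noise <- mean(abs(boot$z[-sg]))
  expect_gt(z_signal, z_noise)
  # doubling B leaves SE estimates within Monte-Carlo error
  boot2 <- pls_bootstrap(map, genes, B = 300, seed = 27)
  rel <- abs(boot$boot_se - boot2$boot_se) / boot$boot_se
  expect_lt(stats::median(rel), 0.25)
})

test_that("gene ranking is ordered, tie-stable and column-order invariant", {
  set.seed(27)
  map <- rnorm(30)
  genes <- generate_gene_expression(30, 80, signal_map = map,
                                    n_signal_genes = 20, signal_weight = 1,
                                    noise_sd = 1, seed = 27)
  fit <- pls_fit(map, genes, ncomp = 1)
  top <- rank_top_genes(fit, k = 25)
  expect_equal(nrow(top), 25)
  expect_true(all(diff(abs(top$weight)) <= 1e-12))
  expect_error(rank_top_genes(fit, k = 100), "exceeds")
  # full ordering when k equals the gene count
  expect_equal(nrow(rank_top_genes(fit, k = 80)), 80)

  # shuffling gene columns must not change the ranked list
  set.seed(28)
  shuf <- sample(80)
  fit2 <- pls_fit(map, genes[, shuf], ncomp = 1)
  top2 <- rank_top_genes(fit2, k = 25)
  expect_equal(top$gene, top2$gene)
  expect_equal(fit$expl_gene[1], fit2$expl_gene[1], tolerance = 1e-10)
})

test_that("hypergeometric enrichment matches closed forms and Fisher's exact test", {
  bg <- paste0("g", 1:10)
  sets <- list(hit = bg[1:5], miss = bg[6:10])
  res <- hypergeom_enrich(bg[1:4], sets, bg)
  # overlap 4 of a 5-gene set drawn 4 from 10: C(5,4)C(5,0)/C(10,4) = 1/42
  expect_equal(res$p[res$set == "hit"], 1 / 42, tolerance = 1e-12)
  expect_equal(res$overlap[res$set == "miss"], 0)
  expect_equal(res$p[res$set == "miss"], 1)

  set.seed(29)
  big_bg <- paste0("g", 1:200)
  for (i in 1:20) {
    gene_list <- sample(big_bg, sample(10:50, 1))
    gene_set <- sample(big_bg, sample(10:60, 1))
    res_i <- hypergeom_enrich(gene_list, list(s = gene_set), big_bg)
    ov <- length(intersect(gene_list, gene_set))
    tab <- matrix(c(ov, length(gene_set) - ov,
                    length(gene_list) - ov,
                    200 - length(gene_set) - length(gene_list) + ov), 2)
    fish <- stats::fisher.test(tab, alternative = "greater")$p.value
    expect_equal(res_i$p, fish, tolerance = 1e-9)
  }

  expect_error(hypergeom_enrich("x1", sets, bg), "outside the background")
  expect_error(hypergeom_enrich(character(0), sets, character(0)), "empty")
})

test_that("constant responses and misaligned regions are rejected", {
  genes <- matrix(rnorm(300), 15)
  expect_error(pls_fit(rep(1, 15), genes), "constant")
  expect_error(pls_fit(rnorm(12), genes), "match")
  # region mask drops uncovered regions from both blocks identically
  map <- rnorm(20)
  mask <- c(rep(TRUE, 15), rep(FALSE, 5))
  fit <- pls_fit(map[mask], genes, ncomp = 1)
  fit2 <- pls_fit(map, rbind(genes, matrix(0, 5, 20)), region_mask = mask,
                  ncomp = 1)
  expect_equal(fit$weights, fit2$weights, tolerance = 1e-12)
})
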