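test_that("closed-form DomiRank matches analytic values on symmetric graphs", {
  # K4 at sigma 0.2: gamma (1 + 3 sigma) = 3 sigma -> 0.6 / 1.6 = 0.375
  expect_equal(domirank(complete_adj(4), sigma = 0.2), rep(0.375, 4),
               tolerance = 1e-12)
  # star with 4 leaves at sigma 0.4: hub 8/3, leaves -2/3 (2-variable reduction)
  got <- domirank(star_adj(4), sigma = 0.4)
  expect_equal(got, c(8 / 3, rep(-2 / 3, 4)), tolerance = 1e-12)
  # edgeless graph: (I)Gamma = 0
  expect_equal(domirank(matrix(0, 3, 3), sigma = 0.5, check_sigma = FALSE),
               rep(0, 3))
})

test_that("closed form agrees with forward-integrated dynamics on random graphs", {
  for (seed in 1:6) {
    n <- sample(10:50, 1)
    net <- random_net(n, 0.25, seed = seed)
    feas <- sigma_feasible_interval(net)
    for (frac in c(0.2, 0.6, 0.9)) {
      sg <- frac * feas$upper_bound
      expect_equal(domirank(net, sg), domirank_dynamics(net$A, sg),
                   tolerance = 1e-6)
    }
  }
})

test_that("sigma feasibility interval matches known spectra", {
  # complete graph: lambda_N = -1, interval (0, 1)
  f5 <- sigma_feasible_interval(complete_adj(6))
  expect_equal(f5$lambda_N, -1, tolerance = 1e-10)
  expect_equal(f5$upper_bound, 1, tolerance = 1e-10)
  # star K_{1,4}: spectrum +/- sqrt(4), interval (0, 0.5)
  fs <- sigma_feasible_interval(star_adj(4))
  expect_equal(fs$lambda_N, -2, tolerance = 1e-10)
  expect_equal(fs$upper_bound, 0.5, tolerance = 1e-10)
  # 100 candidates strictly inside the interval
  expect_length(fs$candidates, 100)
  expect_true(all(fs$candidates > 0 & fs$candidates < fs$upper_bound))
  expect_equal(fs$candidates[1], fs$upper_bound / 101, tolerance = 1e-12)
  # edgeless graph has no interval
  expect_error(sigma_feasible_interval(matrix(0, 4, 4)), "undefined")
})

test_that("sigma outside the interval and singular systems are rejected", {
  expect_error(domirank(star_adj(4), sigma = 0.6), "feasible interval")
  expect_error(domirank(star_adj(4), sigma = -0.1), "feasible interval")
  # exactly at the pole sigma = -1/lambda_N = 0.5 the system is singular
  expect_error(domirank(star_adj(4), sigma = 0.5, check_sigma = FALSE),
               "singular")
})

test_that("sigma to zero limit recovers degree", {
  for (seed in 1:5) {
    net <- random_net(25, 0.25, seed = 100 + seed)
    feas <- sigma_feasible_interval(net)
    sg <- 1e-4 * feas$upper_bound
    gamma <- domirank(net, sg)
    deg <- rowSums(net$A)
    # Gamma / (sigma theta) -> A 1 as sigma -> 0
    expect_equal(gamma / sg, deg, tolerance = 1e-3)
    # the Gamma ordering refines the degree ordering (ties split by Gamma)
    expect_true(all(diff(deg[order(-gamma)]) <= 0))
  }
})

test_that("DomiRank is equivariant under node relabelling", {
  net <- random_net(18, 0.3, seed = 8)
  sg <- 0.5 * sigma_feasible_interval(net)$upper_bound
  gamma <- domirank(net, sg)
  set.seed(9)
  perm <- sample(18)
  gamma_perm <- domirank(net$A[perm, perm], sg)
  expect_equal(gamma_perm, gamma[perm], tolerance = 1e-10)
})

test_that("sigma scan returns the candidate minimising the attack area", {
  net <- random_net(40, 0.15, seed = 21)
  sel <- select_sigma(net, n_candidates = 40)
  expect_true(sel$sigma > 0 &&
                sel$sigma < sel$feasibility$upper_bound)
  expect_equal(sel$sigma, sel$areas$sigma[which.min(sel$areas$area)])
  # independent recomputation of every candidate area via the public attack API
  areas2 <- vapply(sel$areas$sigma, function(sg) {
    lcc_area(targeted_attack_curve(net, domirank(net, sg)))
  }, numeric(1))
  expect_equal(sel$areas$area, areas2, tolerance = 1e-12)
  # single candidate: that candidate is returned
  one <- select_sigma(net, n_candidates = 1)
  expect_equal(one$sigma, sigma_feasible_interval(net, 1)$candidates[1])
  # determinism
  sel2 <- select_sigma(net, n_candidates = 40)
  expect_identical(sel$sigma, sel2$sigma)
  expect_identical(sel$areas, sel2$areas)
})

test_that("the linear system is solvable across the whole candidate scan", {
  net <- random_net(30, 0.2, seed = 31)
  for (sg in sigma_feasible_interval(net, 25)$candidates) {
    expect_length(domirank(net, sg, check_sigma = FALSE), 30)
  }
})

test_that("classical centralities match hand values on canonical graphs", {
  k5 <- classical_centralities(complete_adj(5))
  expect_equal(k5$degree, rep(4, 5))
  expect_equal(k5$betweenness, rep(0, 5))

  star <- classical_centralities(star_adj(4))
  expect_equal(star$betweenness, c(1, 0, 0, 0, 0)) # all 6 leaf pairs via hub
  expect_equal(star$degree, c(4, 1, 1, 1, 1))

  p3 <- classical_centralities(path_adj(3))
  expect_equal(p3$closeness, c(2 / 3, 1, 2 / 3)) # (n-1)/sum d
  expect_equal(p3$harmonic, c(0.75, 1, 0.75))

  # eigenvector: nonnegative with unit Euclidean norm
  net <- random_net(15, 0.3, seed = 4)
  cc <- classical_centralities(net)
  expect_true(all(cc$eigenvector >= 0))
  expect_equal(sum(cc$eigenvector^2), 1, tolerance = 1e-8)
  # strength sums retained Fisher-z weights
  expect_equal(cc$strength, rowSums(net$weights), tolerance = 1e-12)
})

test_that("cohort centrality tables are tidy and extractable as matrices", {
  nets <- list(s1 = random_net(12, 0.3, seed = 1),
               s2 = random_net(12, 0.3, seed = 2))
  long <- cohort_centrality(nets, sigma = 0.1, metrics = c("domirank", "degree"))
  expect_setequal(unique(long$metric), c("domirank", "degree"))
  expect_equal(nrow(long), 2 * 12 * 2)
  m <- centrality_matrix(long, "domirank")
  expect_equal(dim(m), c(2, 12))
  expect_equal(m["s1", ], setNames(domirank(nets$s1, 0.1), colnames(m)),
               tolerance = 1e-12)
})
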