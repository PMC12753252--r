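# graph fixtures used across tests, built in code

complete_adj <- function(n) 1 - diag(n)

star_adj <- function(n_leaves) {
  A <- matrix(0, n_leaves + 1, n_leaves + 1)
  A[1, -1] <- A[-1, 1] <- 1
  A
}

path_adj <- function(n) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1
  A
}

# hub-dominated fixture: cliques joined through a central hub
star_of_cliques_adj <- function(n_cliques = 4, clique_size = 4) {
  n <- 1 + n_cliques * clique_size
  A <- matrix(0, n, n)
  for (c in seq_len(n_cliques)) {
    members <- 1 + ((c - 1) * clique_size + 1):(c * clique_size)
    A[members, members] <- 1
    A[1, members[1]] <- A[members[1], 1] <- 1
  }
  diag(A) <- 0
  A
}

# random connected binary network via the package's own thresholding of a
# random symmetric matrix (connectivity guaranteed by the tree backbone)
random_net <- function(n, density = 0.2, seed = 1) {
  set.seed(seed)
  z <- matrix(rnorm(n * n, 0, 0.3), n, n)
  z <- (z + t(z)) / 2
  diag(z) <- 0
  threshold_mst(z, density = density)
}

# minimal site_test object for combination tests
fake_site_test <- function(t, p, n, site, regions = seq_along(t),
                           contrast = c("AD", "HC")) {
  x <- tibble::tibble(region = regions, t = t, p = p)
  attr(x, "site") <- site
  attr(x, "n") <- n
  attr(x, "contrast") <- contrast
  class(x) <- c("site_test", class(x))
  x
}

# small multi-site null cohort for calibration-style tests
null_cohort_config <- function(seed, n_sites = 7, n_per_group = 20,
                               n_regions = 40, n_timepoints = 60) {
  cohort_config(
    per_site_group_sizes = rep(list(c(n_per_group, 0, n_per_group)), n_sites),
    n_regions = n_regions, n_timepoints = n_timepoints, n_blocks = 8,
    seed = seed
  )
}

# regional strength (row sums of Fisher z): cheap subject-level feature for
# calibration tests that do not need the centrality stage
strength_values <- function(cohort) {
  t(vapply(cohort$time_series, function(ts) rowSums(compute_fc(ts)$z),
           numeric(nrow(cohort$time_series[[1]]))))
}

# independent forward integration of the competition-relaxation dynamics
# (beta = 1, alpha = sigma); oracle for the closed-form solve
domirank_dynamics <- function(A, sigma, theta = 1, tol = 1e-12,
                              max_iter = 5e5) {
  n <- nrow(A)
  gamma <- numeric(n)
  dt <- 0.5 / (1 + sigma * max(rowSums(A)))
  for (i in seq_len(max_iter)) {
    dgamma <- sigma * (A %*% (theta - gamma)) - gamma
    gamma_new <- gamma + dt * dgamma
    if (max(abs(gamma_new - gamma)) < tol) return(as.numeric(gamma_new))
    gamma <- gamma_new
  }
  as.numeric(gamma)
}

# brute-force LCC after removing the given nodes, by fresh component search
brute_lcc <- function(A, removed) {
  keep <- setdiff(seq_len(nrow(A)), removed)
  if (!length(keep)) return(0L)
  B <- A[keep, keep, drop = FALSE]
  comp <- rep(0L, nrow(B))
  cid <- 0L
  for (s in seq_len(nrow(B))) {
    if (comp[s] > 0) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(B[v, ] != 0 & comp == 0L)
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  max(tabulate(comp))
}

# exhaustive BH step-up oracle for small m: largest i with p_(i) <= i q / m,
# reject everything at or below that order statistic
brute_bh_reject <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  thr <- which(ps <= seq_len(m) * q / m)
  reject <- logical(m)
  if (length(thr)) reject[ord[seq_len(max(thr))]] <- TRUE
  reject
}

# independent PLS1 gene-block explained share: straight-line formulas, no
# shared code with the package's NIPALS implementation
oracle_pls1_share <- function(y, X) {
  y <- (y - mean(y)) / sd(y)
  Xs <- apply(X, 2, function(col) {
    s <- sd(col)
    if (s == 0) rep(0, length(col)) else (col - mean(col)) / s
  })
  w <- t(Xs) %*% y
  w <- w / sqrt(sum(w^2))
  scores <- Xs %*% w
  loadings <- t(Xs) %*% scores / sum(scores^2)
  sum(scores^2) * sum(loadings^2) / sum(Xs^2)
}

# all permutations of 1..n, independent recursive enumeration
oracle_permutations <- function(n) {
  if (n == 1) return(list(1L))
  res <- list()
  for (p in oracle_permutations(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      res[[length(res) + 1L]] <- append(p, n, after = pos)
    }
  }
  res
}
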