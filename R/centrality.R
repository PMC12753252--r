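#' DomiRank centrality by closed-form linear solve
#'
#' DomiRank scores nodes by the steady state of competition-relaxation
#' dynamics on the adjacency matrix A,
#' \deqn{\dot\Gamma = \alpha A (\theta 1 - \Gamma) - \beta \Gamma,}
#' whose fixed point has the closed form
#' \deqn{\Gamma = \theta\sigma (\sigma A + I)^{-1} A 1, \quad \sigma = \alpha/\beta.}
#' Rather than iterating the dynamics, the linear system
#' \eqn{(\sigma A + I)\Gamma = \sigma\theta A 1} is solved directly; the
#' residual is checked to be below 1e-8. Scores can be negative: dominated
#' nodes sit in the shadow of stronger neighbours.
#'
#' \eqn{\sigma} trades local against global influence and must satisfy
#' \eqn{0 < \sigma < -1/\lambda_N}, where \eqn{\lambda_N} is the most negative
#' adjacency eigenvalue (see [sigma_feasible_interval()]).
#'
#' @param net A [threshold_mst()] network, or a binary adjacency matrix.
#' @param sigma Positive trade-off parameter inside the feasibility interval.
#' @param theta Pure scale of the dynamics (default 1).
#' @param check_sigma Verify `sigma` against the feasibility interval
#'   (default `TRUE`; the σ scan disables it after checking once).
#' @return Numeric vector of DomiRank scores, one per region.
#' @examples
#' A <- 1 - diag(4) # complete graph K4
#' domirank(A, sigma = 0.2) # 0.375 for every node
#' @export
domirank <- function(net, sigma, theta = 1, check_sigma = TRUE) {
  A <- as_adjacency(net)
  n <- nrow(A)
  if (check_sigma) {
    feas <- sigma_feasible_interval(A)
    if (sigma <= 0 || sigma >= feas$upper_bound) {
      stopf("sigma = %g outside the feasible interval (0, %g)", sigma,
            feas$upper_bound)
    }
  } else if (sigma <= 0) {
    stopf("sigma must be positive")
  }
  M <- sigma * A
  diag(M) <- diag(M) + 1
  b <- sigma * theta * rowSums(A)
  gamma <- tryCatch(solve(M, b), error = function(e) {
    stopf("linear system (sigma*A + I) is singular at sigma = %g: %s",
          sigma, conditionMessage(e))
  })
  resid <- max(abs(M %*% gamma - b))
  if (resid > 1e-8) {
    stopf("DomiRank solve residual %.3g exceeds 1e-8", resid)
  }
  as.numeric(gamma)
}

as_adjacency <- function(net) {
  if (inherits(net, "binary_network")) {
    return(net$A * 1.0)
  }
  A <- as.matrix(net) * 1.0
  stopifnot(nrow(A) == ncol(A))
  A
}

#' Feasibility interval for the DomiRank trade-off parameter
#'
#' Computes the most negative adjacency eigenvalue \eqn{\lambda_N} and the
#' admissible interval \eqn{(0, -1/\lambda_N)}, together with a grid of
#' candidate \eqn{\sigma} values: `n_candidates` evenly spaced fractions
#' j / (n_candidates + 1) of the upper bound, endpoints excluded.
#'
#' @param net A `binary_network` or adjacency matrix.
#' @param n_candidates Number of scan candidates (default 100).
#' @return An object of class `sigma_feasibility`: list with `lambda_N`,
#'   `upper_bound` and `candidates`.
#' @examples
#' A <- 1 - diag(5)
#' sigma_feasible_interval(A)$upper_bound # complete graph: lambda_N = -1
#' @export
sigma_feasible_interval <- function(net, n_candidates = 100) {
  A <- as_adjacency(net)
  if (nrow(A) == 0) stopf("network is empty")
  lambda_N <- min(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
  if (lambda_N >= -1e-12) {
    stopf("most negative adjacency eigenvalue is %.3g >= 0; the sigma interval is undefined (edgeless or degenerate network)",
          lambda_N)
  }
  upper <- -1 / lambda_N
  structure(list(
    lambda_N = lambda_N,
    upper_bound = upper,
    candidates = upper * seq_len(n_candidates) / (n_candidates + 1)
  ), class = "sigma_feasibility")
}

#' @export
print.sigma_feasibility <- function(x, ...) {
  cat(sprintf("<sigma_feasibility> lambda_N = %.4f, interval (0, %.4f), %d candidates\n",
              x$lambda_N, x$upper_bound, length(x$candidates)))
  invisible(x)
}

#' Select the DomiRank trade-off parameter by attack-area minimisation
#'
#' Scans candidate \eqn{\sigma} values across the feasibility interval; for
#' each candidate, DomiRank is computed, nodes are removed in descending
#' DomiRank order (non-adaptive: the ranking is fixed from the intact
#' network), and the area under the largest-connected-component curve is
#' integrated. The candidate minimising that area -- i.e. the most damaging
#' targeted-attack ordering -- is returned. Ties go to the smallest
#' \eqn{\sigma}. The scan is deterministic.
#'
#' @param net A `binary_network` or binary adjacency matrix.
#' @param n_candidates Number of evenly spaced candidates (default 100).
#' @param adaptive Recompute the ranking after every removal (exploratory
#'   mode; the default `FALSE` matches the fixed-ranking attack used
#'   throughout the pipeline).
#' @param sigma_max Optional upper cap on the scanned candidates. When one
#'   sigma is shared across a cohort (template mode), the cap is set to the
#'   smallest per-subject feasibility bound so the selected value is valid
#'   for every subject's network.
#' @return An object of class `sigma_selection`: list with `sigma` (the
#'   selected value), `areas` (tibble: sigma, area), and `feasibility`.
#' @export
select_sigma <- function(net, n_candidates = 100, adaptive = FALSE,
                         sigma_max = NULL) {
  A <- as_adjacency(net)
  feas <- sigma_feasible_interval(A, n_candidates)
  if (!is.null(sigma_max)) {
    feas$candidates <- feas$candidates[feas$candidates <= sigma_max]
    if (!length(feas$candidates)) {
      stopf("no scan candidate lies below sigma_max = %g", sigma_max)
    }
  }
  adj <- adjacency_list(A)
  n <- nrow(A)
  areas <- vapply(feas$candidates, function(sg) {
    gamma <- domirank(A, sg, check_sigma = FALSE)
    curve <- if (adaptive) {
      attack_curve_adaptive(A, function(B) domirank(B, sg, check_sigma = FALSE))
    } else {
      lcc_curve_values(adj, n, attack_order(gamma))
    }
    trapezoid_area(seq(0, 1, length.out = n + 1), curve)
  }, numeric(1))
  best <- which.min(areas)
  structure(list(
    sigma = feas$candidates[best],
    areas = tibble(sigma = feas$candidates, area = areas),
    feasibility = feas
  ), class = "sigma_selection")
}

#' @export
print.sigma_selection <- function(x, ...) {
  cat(sprintf("<sigma_selection> sigma = %.5f (attack area %.4f over %d candidates)\n",
              x$sigma, min(x$areas$area), nrow(x$areas)))
  invisible(x)
}

#' Classical node centralities of a binary network
#'
#' The seven standard metrics reported alongside DomiRank: binary degree,
#' strength (sum of the retained Fisher-z edge weights), betweenness,
#' closeness and harmonic centrality on unweighted shortest paths (all
#' normalised), principal eigenvector centrality (nonnegative, unit
#' Euclidean norm) and PageRank with damping 0.85. Shortest-path and
#' spectral metrics are delegated to igraph.
#'
#' @param net A `binary_network` (connected; as produced by
#'   [threshold_mst()]).
#' @return Tibble with one row per region and columns `region`, `degree`,
#'   `strength`, `betweenness`, `closeness`, `harmonic`, `eigenvector`,
#'   `pagerank`.
#' @export
classical_centralities <- function(net) {
  A <- as_adjacency(net)
  W <- if (inherits(net, "binary_network")) net$weights else A
  g <- igraph::graph_from_adjacency_matrix(A != 0, mode = "undirected")
  eig <- igraph::eigen_centrality(g)$vector
  eig <- abs(eig) / sqrt(sum(eig^2))
  tibble(
    region = seq_len(nrow(A)),
    degree = as.numeric(rowSums(A != 0)),
    strength = as.numeric(rowSums(W)),
    betweenness = igraph::betweenness(g, normalized = TRUE),
    closeness = igraph::closeness(g, normalized = TRUE),
    harmonic = igraph::harmonic_centrality(g, normalized = TRUE),
    eigenvector = eig,
    pagerank = igraph::page_rank(g, damping = 0.85)$vector
  )
}

#' Centrality tables for a list of networks
#'
#' Computes DomiRank (at a shared or per-subject sigma) and, optionally, the
#' seven classical centralities for every subject's network, returning
#' subjects x regions tables in long tidy form.
#'
#' @param nets Named list of `binary_network` objects (names = subject ids).
#' @param sigma Either a single sigma shared by all subjects (e.g. selected
#'   once on a template network) or `"per_subject"` to run the scan on every
#'   network.
#' @param metrics Character vector of metrics to compute; `"domirank"` plus
#'   any of the classical names, or `"all"`.
#' @param n_candidates Candidates for per-subject sigma scans.
#' @return Tibble with columns `subject`, `region`, `metric`, `value`.
#' @export
cohort_centrality <- function(nets, sigma, metrics = "domirank",
                              n_candidates = 100) {
  classical_names <- c("degree", "strength", "betweenness", "closeness",
                       "harmonic", "eigenvector", "pagerank")
  if (identical(metrics, "all")) metrics <- c("domirank", classical_names)
  want_classical <- intersect(metrics, classical_names)
  out <- purrr::imap(nets, function(net, id) {
    res <- list()
    if ("domirank" %in% metrics) {
      sg <- if (identical(sigma, "per_subject")) {
        select_sigma(net, n_candidates)$sigma
      } else {
        sigma
      }
      res$domirank <- domirank(net, sg, check_sigma = !identical(sigma, "per_subject"))
    }
    if (length(want_classical)) {
      cc <- classical_centralities(net)
      for (m in want_classical) res[[m]] <- cc[[m]]
    }
    tidyr::pivot_longer(
      dplyr::mutate(as_tibble(res), subject = id,
                    region = seq_len(nrow(net$A)), .before = 1),
      cols = -c("subject", "region"),
      names_to = "metric", values_to = "value"
    )
  })
  dplyr::bind_rows(out)
}

#' Subjects x regions matrix for one centrality metric
#'
#' @param centrality_long Output of [cohort_centrality()].
#' @param metric Metric name to extract.
#' @return Numeric matrix, subjects in rows (named), regions in columns.
#' @export
centrality_matrix <- function(centrality_long, metric = "domirank") {
  sub <- centrality_long[centrality_long$metric == metric, , drop = FALSE]
  if (nrow(sub) == 0) stopf("metric '%s' not present", metric)
  wide <- tidyr::pivot_wider(sub[c("subject", "region", "value")],
                             names_from = "region", values_from = "value")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$subject
  m
}
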