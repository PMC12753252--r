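#' Functional connectivity from regional time series
#'
#' Pairwise Pearson correlation between regional time series, clipped to
#' +/- (1 - 1e-7) and Fisher z-transformed (atanh); the diagonal is zeroed.
#' Clipping keeps the transform finite when a pair is perfectly (anti-)
#' correlated, e.g. a region paired with its own negation.
#'
#' @param ts Regions x timepoints numeric matrix (regions in rows).
#' @param subject_id Optional subject identifier carried on the result.
#' @return An object of class `fc_matrix`: list with `z` (symmetric N x N
#'   Fisher-z matrix, zero diagonal) and `subject_id`.
#' @examples
#' ts <- rbind(sin(1:50), cos(1:50), sin(1:50 + 0.2))
#' fc <- compute_fc(ts)
#' round(fc$z, 2)
#' @export
compute_fc <- function(ts, subject_id = NULL) {
  ts <- as.matrix(ts)
  if (ncol(ts) < 3) stopf("need at least 3 timepoints, got %d", ncol(ts))
  sds <- apply(ts, 1, sd)
  if (any(sds == 0)) {
    stopf("region(s) %s have zero variance",
          paste(which(sds == 0), collapse = ", "))
  }
  r <- cor(t(ts))
  z <- atanh(clip_r(r))
  diag(z) <- 0
  structure(list(z = z, subject_id = subject_id), class = "fc_matrix")
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat(sprintf("<fc_matrix> %d regions%s\n", nrow(x$z),
              if (!is.null(x$subject_id)) paste0(", subject ", x$subject_id) else ""))
  invisible(x)
}

#' Threshold a connectivity matrix into a connected binary network
#'
#' Proportional thresholding with a spanning-tree backbone: the edge set is
#' the maximum-weight spanning tree on signed Fisher-z (guaranteeing a single
#' connected component with no isolated regions) plus the strongest remaining
#' edges, in descending signed z, until exactly
#' `round(density * N(N-1)/2)` edges are retained (round half away from
#' zero). In absolute mode a z cutoff replaces the density budget, with the
#' same tree backbone preserving connectivity.
#'
#' Ties between equal-weight edges are broken lexicographically on
#' (min region id, max region id), so results are deterministic.
#'
#' @param fc An [compute_fc()] result, or a symmetric Fisher-z matrix.
#' @param density Fraction of all possible edges to retain (default 0.04).
#' @param mode `"proportional"` (density budget) or `"absolute"` (z cutoff).
#' @param cutoff Fisher-z cutoff for `mode = "absolute"`.
#' @param rank_abs Rank edges by |z| instead of signed z (default `FALSE`:
#'   strongest positive correlations are retained first).
#' @return An object of class `binary_network`: list with `A` (binary
#'   adjacency, zero diagonal), `weights` (retained Fisher-z values, zero
#'   elsewhere), `region_ids`, `n_edges`, `density`, `subject_id`.
#' @examples
#' set.seed(1)
#' ts <- matrix(rnorm(10 * 60), 10, 60)
#' net <- threshold_mst(compute_fc(ts), density = 0.3)
#' net$n_edges
#' @export
threshold_mst <- function(fc, density = 0.04,
                          mode = c("proportional", "absolute"),
                          cutoff = NULL, rank_abs = FALSE) {
  mode <- match.arg(mode)
  z <- if (inherits(fc, "fc_matrix")) fc$z else as.matrix(fc)
  subject_id <- if (inherits(fc, "fc_matrix")) fc$subject_id else NULL
  n <- nrow(z)
  if (n < 2 || nrow(z) != ncol(z)) stopf("need a square matrix of at least 2 regions")
  if (max(abs(z - t(z))) > 1e-10) stopf("connectivity matrix must be symmetric")

  edges <- upper_edges(n)
  w <- z[edges$idx]
  m_all <- length(w)
  key <- if (rank_abs) -abs(w) else -w
  ord <- order(key, edges$i, edges$j)

  if (mode == "proportional") {
    if (density <= 0 || density > 1) stopf("density must lie in (0, 1]")
    budget <- as.integer(round_half_away(density * m_all))
    if (budget < n - 1) {
      stopf("density %.4f yields %d edges; %d are needed for connectivity (minimum feasible density %.4f)",
            density, budget, n - 1, (n - 1) / m_all)
    }
  } else {
    if (is.null(cutoff)) stopf("mode = 'absolute' requires a cutoff")
    budget <- NA_integer_
  }

  # single descending pass: Kruskal tree edges always kept, remaining budget
  # filled with the strongest non-tree edges in the same order
  parent <- seq_len(n)
  find_root <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  keep <- integer(if (is.na(budget)) m_all else budget)
  n_keep <- 0L
  n_tree <- 0L
  for (e in ord) {
    ri <- find_root(edges$i[e])
    rj <- find_root(edges$j[e])
    is_tree <- ri != rj
    if (is_tree) {
      parent[ri] <- rj
      n_tree <- n_tree + 1L
      n_keep <- n_keep + 1L
      keep[n_keep] <- e
    } else if (is.na(budget)) {
      ok <- if (rank_abs) abs(w[e]) >= cutoff else w[e] >= cutoff
      if (ok) {
        n_keep <- n_keep + 1L
        keep[n_keep] <- e
      }
    } else if (n_keep - n_tree < budget - (n - 1L)) {
      n_keep <- n_keep + 1L
      keep[n_keep] <- e
    }
    if (!is.na(budget) && n_tree == n - 1L && n_keep == budget) break
  }
  keep <- keep[seq_len(n_keep)]

  A <- matrix(0L, n, n)
  W <- matrix(0, n, n)
  ii <- edges$i[keep]
  jj <- edges$j[keep]
  A[cbind(ii, jj)] <- 1L
  A[cbind(jj, ii)] <- 1L
  W[cbind(ii, jj)] <- w[keep]
  W[cbind(jj, ii)] <- w[keep]

  structure(list(
    A = A, weights = W,
    region_ids = seq_len(n),
    n_edges = length(keep),
    density = length(keep) / m_all,
    mode = mode,
    subject_id = subject_id
  ), class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("<binary_network> %d regions, %d edges (density %.4f)%s\n",
              nrow(x$A), x$n_edges, x$density,
              if (!is.null(x$subject_id)) paste0(", subject ", x$subject_id) else ""))
  invisible(x)
}

#' Edge list of a binary network
#'
#' @param net A `binary_network`.
#' @return Tibble with columns `region_i`, `region_j`, `weight`
#'   (retained Fisher-z).
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  n <- nrow(net$A)
  e <- upper_edges(n)
  on <- net$A[e$idx] != 0
  tibble(region_i = e$i[on], region_j = e$j[on], weight = net$weights[e$idx][on])
}

# adjacency list representation used by the attack simulator
adjacency_list <- function(A) {
  lapply(seq_len(nrow(A)), function(v) which(A[v, ] != 0))
}

# number of connected components of a binary adjacency matrix (igraph-free,
# used as an internal check; tests use igraph independently)
n_components <- function(A) {
  n <- nrow(A)
  seen <- logical(n)
  comp <- 0L
  adj <- adjacency_list(A)
  for (s in seq_len(n)) {
    if (seen[s]) next
    comp <- comp + 1L
    stack <- s
    seen[s] <- TRUE
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      nb <- adj[[v]]
      new <- nb[!seen[nb]]
      seen[new] <- TRUE
      stack <- c(stack, new)
    }
  }
  comp
}
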