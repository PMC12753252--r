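# removal order for a centrality ranking: descending value, ties broken by
# ascending region id
attack_order <- function(ranking) {
  order(-ranking, seq_along(ranking))
}

# LCC sizes along a fixed removal order, computed by the reverse process:
# nodes are re-inserted in reverse order and components merged with
# union-find, which is exact and far cheaper than recomputing components
# after every deletion. Returns lcc fraction at 0, 1, ..., n removals.
lcc_curve_values <- function(adj, n, removal_order) {
  parent <- integer(n)
  csize <- integer(n)
  present <- logical(n)
  find_root <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  lcc_rev <- numeric(n + 1) # lcc_rev[k + 1] = LCC with k nodes present
  maxc <- 0L
  for (k in seq_len(n)) {
    v <- removal_order[n - k + 1L]
    present[v] <- TRUE
    parent[v] <- v
    csize[v] <- 1L
    rv <- v
    for (u in adj[[v]]) {
      if (present[u]) {
        ru <- find_root(u)
        if (ru != rv) {
          if (csize[ru] < csize[rv]) {
            parent[ru] <- rv
            csize[rv] <- csize[rv] + csize[ru]
          } else {
            parent[rv] <- ru
            csize[ru] <- csize[ru] + csize[rv]
            rv <- ru
          }
        }
      }
    }
    if (csize[rv] > maxc) maxc <- csize[rv]
    lcc_rev[k + 1L] <- maxc
  }
  rev(lcc_rev) / n
}

# adaptive variant used only for exploration: recompute the ranking on the
# surviving subgraph before every removal
attack_curve_adaptive <- function(A, rank_fun) {
  n <- nrow(A)
  alive <- seq_len(n)
  curve <- numeric(n + 1)
  curve[1] <- max_component_size(A) / n
  for (k in seq_len(n)) {
    B <- A[alive, alive, drop = FALSE]
    r <- rank_fun(B)
    drop <- alive[attack_order(r)[1]]
    alive <- setdiff(alive, drop)
    curve[k + 1] <- if (length(alive)) {
      max_component_size(A[alive, alive, drop = FALSE]) / n
    } else {
      0
    }
  }
  curve
}

max_component_size <- function(A) {
  n <- nrow(A)
  if (n == 0) return(0L)
  adj <- adjacency_list(A)
  curve <- lcc_curve_values(adj, n, seq_len(n))
  as.integer(round(curve[1] * n))
}

trapezoid_area <- function(x, y) {
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Largest-connected-component curve under a targeted attack
#'
#' Removes nodes one at a time in descending order of the supplied centrality
#' ranking (ties broken by ascending region id; the ranking is fixed from the
#' intact network) and records the size of the largest connected component,
#' normalised by the original region count, after each removal.
#'
#' @param net A `binary_network` or binary adjacency matrix.
#' @param ranking Region-length numeric vector; higher values are removed
#'   first.
#' @param metric Optional label carried on the curve (e.g. `"domirank"`).
#' @return An object of class `lcc_curve`: tibble with columns
#'   `fraction_removed` (0, 1/N, ..., 1) and `lcc_fraction`, plus a
#'   `metric` attribute. The curve starts at 1 for connected input and ends
#'   at 0.
#' @examples
#' star <- matrix(0, 5, 5); star[1, 2:5] <- star[2:5, 1] <- 1
#' targeted_attack_curve(star, ranking = c(10, 1, 1, 1, 1))
#' @export
targeted_attack_curve <- function(net, ranking, metric = NULL) {
  A <- as_adjacency(net)
  n <- nrow(A)
  if (length(ranking) != n) {
    stopf("ranking length (%d) must equal the number of regions (%d)",
          length(ranking), n)
  }
  curve <- lcc_curve_values(adjacency_list(A), n, attack_order(ranking))
  out <- tibble(
    fraction_removed = seq(0, 1, length.out = n + 1),
    lcc_fraction = curve
  )
  attr(out, "metric") <- metric
  class(out) <- c("lcc_curve", class(out))
  out
}

#' Area under an LCC attack curve
#'
#' Trapezoidal integral of the largest-connected-component fraction over the
#' removed-node fraction in `[0, 1]`. Smaller areas mean a more damaging
#' attack; this is the criterion minimised by the sigma scan in
#' [select_sigma()].
#'
#' @param curve An [targeted_attack_curve()] result, or any data frame with
#'   `fraction_removed` and `lcc_fraction` columns.
#' @return Scalar area.
#' @export
lcc_area <- function(curve) {
  stopifnot(all(c("fraction_removed", "lcc_fraction") %in% names(curve)))
  trapezoid_area(curve$fraction_removed, curve$lcc_fraction)
}

#' Group-average attack curves
#'
#' Per-subject LCC curves are averaged within groups to give group-level
#' robustness profiles, one curve per group and metric.
#'
#' @param curves List of `lcc_curve` objects (one per subject).
#' @param groups Vector of group labels, one per curve.
#' @return Tibble with columns `group`, `fraction_removed`, `lcc_fraction`
#'   (mean over the group's subjects) and `n_subjects`.
#' @export
group_attack_curves <- function(curves, groups) {
  stopifnot(length(curves) == length(groups))
  dplyr::bind_rows(purrr::map2(curves, as.character(groups), function(cv, g) {
    tibble(group = g, fraction_removed = cv$fraction_removed,
           lcc_fraction = cv$lcc_fraction)
  })) |>
    dplyr::group_by(.data$group, .data$fraction_removed) |>
    dplyr::summarise(lcc_fraction = mean(.data$lcc_fraction),
                     n_subjects = dplyr::n(), .groups = "drop")
}
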