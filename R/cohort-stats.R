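#' Pearson chi-square test of independence on a contingency table
#'
#' Plain Pearson chi-square, \eqn{\sum (O - E)^2 / E}, with no continuity
#' correction and df = (r-1)(c-1) -- the demographic-table test for sex
#' ratios across diagnostic groups.
#'
#' @param counts r x c matrix of nonnegative integer counts.
#' @return Tibble with columns `statistic`, `df`, `p_value`.
#' @examples
#' chisq_independence(rbind(c(19, 22), c(13, 21), c(20, 24)))
#' @export
chisq_independence <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || sum(counts) == 0) {
    stopf("counts must be nonnegative with a positive grand total")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stopf("contingency table has an all-zero row or column")
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p_value = ct$p.value)
}

#' One-way ANOVA from group summary statistics
#'
#' Reconstructs the F test from per-group (n, mean, sd): between-group sum of
#' squares from sizes and means, within-group from `(n - 1) sd^2`. Collapsing
#' raw data to summaries and applying this function reproduces the classical
#' one-way ANOVA exactly, which is how printed demographic tables
#' (age, MMSE) are checked without subject-level data.
#'
#' @param n Integer vector of group sizes (each >= 2).
#' @param mean Numeric vector of group means.
#' @param sd Numeric vector of group standard deviations.
#' @return Tibble with columns `f`, `df1`, `df2`, `p_value`.
#' @examples
#' anova_from_summary(n = c(41, 34, 44), mean = c(68.6, 69.5, 69.9),
#'                    sd = c(6.7, 8.8, 8.9))
#' @export
anova_from_summary <- function(n, mean, sd) {
  stopifnot(length(n) == length(mean), length(n) == length(sd),
            length(n) >= 2, all(n >= 2), all(sd >= 0))
  k <- length(n)
  grand <- sum(n * mean) / sum(n)
  ssb <- sum(n * (mean - grand)^2)
  ssw <- sum((n - 1) * sd^2)
  df1 <- k - 1
  df2 <- sum(n) - k
  msw <- ssw / df2
  if (msw == 0) {
    if (ssb == 0) {
      return(tibble(f = 0, df1 = df1, df2 = df2, p_value = 1))
    }
    return(tibble(f = Inf, df1 = df1, df2 = df2, p_value = 0))
  }
  f <- (ssb / df1) / msw
  tibble(f = f, df1 = df1, df2 = df2, p_value = pf(f, df1, df2, lower.tail = FALSE))
}

#' Demographic report for a subject table
#'
#' Per site: sex-count chi-square across diagnostic groups and one-way
#' ANOVAs for age and each cognition score, the statistics printed in a
#' study's demographics table.
#'
#' @param subjects Tibble with columns `site`, `diagnosis`, `sex`, `age` and
#'   optionally `mmse`, `moca`.
#' @param groups Diagnosis levels to compare (default HC/MCI/AD, reduced to
#'   the levels present).
#' @return Tibble with one row per site: `site`, `n`, `sex_p`, `age_p` and,
#'   when available, `mmse_p`, `moca_p`.
#' @export
cohort_demographics <- function(subjects, groups = c("HC", "MCI", "AD")) {
  groups <- intersect(groups, unique(subjects$diagnosis))
  summary_p <- function(df, var) {
    s <- dplyr::summarise(
      dplyr::group_by(df, .data$diagnosis),
      n = dplyr::n(), m = mean(.data[[var]]), s = sd(.data[[var]]),
      .groups = "drop"
    )
    if (nrow(s) < 2 || any(s$n < 2)) return(NA_real_)
    anova_from_summary(s$n, s$m, s$s)$p_value
  }
  purrr::map_dfr(split(subjects, subjects$site), function(df) {
    df <- df[df$diagnosis %in% groups, , drop = FALSE]
    counts <- table(factor(df$diagnosis, levels = groups), df$sex)
    sex_p <- if (all(rowSums(counts) > 0) && all(colSums(counts) > 0)) {
      chisq_independence(unclass(counts))$p_value
    } else {
      NA_real_
    }
    tibble(
      site = df$site[1],
      n = nrow(df),
      sex_p = sex_p,
      age_p = summary_p(df, "age"),
      mmse_p = if ("mmse" %in% names(df)) summary_p(df, "mmse") else NA_real_,
      moca_p = if ("moca" %in% names(df)) summary_p(df, "moca") else NA_real_
    )
  })
}
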