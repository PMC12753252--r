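#' Confusion-matrix classification metrics
#'
#' @param tp,fn,tn,fp Counts of true positives, false negatives, true
#'   negatives and false positives.
#' @return Tibble with columns `acc`, `sen`, `spe`.
#' @examples
#' confusion_metrics(tp = 7, fn = 3, tn = 8, fp = 2)
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  tibble(
    acc = (tp + tn) / (tp + fn + tn + fp),
    sen = tp / (tp + fn),
    spe = tn / (tn + fp)
  )
}

# z-score features using training-fold statistics only (no leakage);
# constant features are centred and left unscaled
fold_standardise <- function(train, test) {
  mu <- colMeans(train)
  sdv <- apply(train, 2, sd)
  sdv[sdv == 0] <- 1
  list(train = sweep(sweep(train, 2, mu), 2, sdv, "/"),
       test = sweep(sweep(test, 2, mu), 2, sdv, "/"))
}

#' Leave-one-site-out classification from centrality features
#'
#' Each acquisition site serves once as the held-out test set. Per fold,
#' features are z-scored with training statistics only, a linear-kernel
#' support vector machine (C = 1) with Platt-style probability calibration
#' is fitted on the training sites, and the held-out site is scored. The
#' positive class is the first element of `levels` (default `"AD"`).
#'
#' @param features Subjects x regions numeric matrix.
#' @param labels Two-class vector, aligned with rows of `features`.
#' @param sites Site label per subject.
#' @param levels Length-2 character `c(positive, negative)`; other labels
#'   are dropped.
#' @param cost SVM cost parameter (default 1).
#' @param seed Integer seed for the probability-calibration CV.
#' @return Object of class `loso_classification`: list with `per_site`
#'   (tibble: site, n, acc, sen, spe, auc), `mean` (tibble of means),
#'   `predictions` (tibble: subject row, site, label, prob_positive,
#'   predicted).
#' @export
loso_classify <- function(features, labels, sites, levels = c("AD", "HC"),
                          cost = 1, seed = 1L) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  sites <- as.character(sites)
  stopifnot(nrow(features) == length(labels), length(labels) == length(sites))
  keep <- labels %in% levels
  features <- features[keep, , drop = FALSE]
  labels <- labels[keep]
  sites <- sites[keep]
  site_ids <- sort(unique(sites))
  if (length(site_ids) < 2) stopf("need at least 2 sites for leave-one-site-out")

  preds <- vector("list", length(site_ids))
  per_site <- vector("list", length(site_ids))
  for (f in seq_along(site_ids)) {
    s <- site_ids[f]
    te <- sites == s
    y_tr <- factor(labels[!te], levels = levels)
    if (length(unique(y_tr)) < 2) {
      stopf("training fold for held-out site %s contains a single class", s)
    }
    std <- fold_standardise(features[!te, , drop = FALSE],
                            features[te, , drop = FALSE])
    set.seed(substream_seed(seed, f))
    fit <- e1071::svm(std$train, y_tr, kernel = "linear", cost = cost,
                      probability = TRUE, scale = FALSE)
    pr <- stats::predict(fit, std$test, probability = TRUE)
    prob_pos <- attr(pr, "probabilities")[, levels[1]]
    y_te <- labels[te]
    pred <- as.character(pr)
    tp <- sum(pred == levels[1] & y_te == levels[1])
    fn <- sum(pred == levels[2] & y_te == levels[1])
    tn <- sum(pred == levels[2] & y_te == levels[2])
    fp <- sum(pred == levels[1] & y_te == levels[2])
    auc <- if (length(unique(y_te)) == 2) {
      as.numeric(pROC::auc(pROC::roc(
        response = factor(y_te, levels = rev(levels)),
        predictor = prob_pos, quiet = TRUE, direction = "<"
      )))
    } else {
      NA_real_
    }
    per_site[[f]] <- dplyr::bind_cols(
      tibble(site = s, n = sum(te)),
      confusion_metrics(tp, fn, tn, fp),
      tibble(auc = auc)
    )
    preds[[f]] <- tibble(row = which(keep)[te], site = s, label = y_te,
                         prob_positive = as.numeric(prob_pos),
                         predicted = pred)
  }
  per_site <- dplyr::bind_rows(per_site)
  structure(list(
    per_site = per_site,
    mean = dplyr::summarise(per_site,
                            acc = mean(.data$acc), sen = mean(.data$sen),
                            spe = mean(.data$spe),
                            auc = mean(.data$auc, na.rm = TRUE)),
    predictions = dplyr::bind_rows(preds),
    levels = levels
  ), class = "loso_classification")
}

#' @export
print.loso_classification <- function(x, ...) {
  cat(sprintf("<loso_classification> %d folds; mean ACC %.3f, SEN %.3f, SPE %.3f, AUC %.3f\n",
              nrow(x$per_site), x$mean$acc, x$mean$sen, x$mean$spe, x$mean$auc))
  invisible(x)
}

#' Leave-one-site-out cognition-score regression
#'
#' Linear-kernel support vector regression per fold (features z-scored on the
#' training sites), pooled out-of-site predictions, and accuracy summaries:
#' Pearson r (both averaged over sites -- the default headline -- and
#' pooled), RMSE and R-squared of the pooled predictions.
#'
#' @param features Subjects x regions matrix.
#' @param scores Numeric cognition score (e.g. MMSE) per subject.
#' @param sites Site label per subject.
#' @param cost SVM cost parameter.
#' @return Object of class `loso_regression`: list with `per_site` (tibble:
#'   site, n, r), `r_mean` (mean of per-site correlations, sites with
#'   constant actual scores reported missing), `r_pooled`, `rmse`,
#'   `r_squared`, `predictions` (tibble: row, site, actual, predicted).
#' @export
loso_regress_scores <- function(features, scores, sites, cost = 1) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(scores), length(scores) == length(sites))
  sites <- as.character(sites)
  site_ids <- sort(unique(sites))
  if (length(site_ids) < 2) stopf("need at least 2 sites for leave-one-site-out")
  preds <- vector("list", length(site_ids))
  for (f in seq_along(site_ids)) {
    s <- site_ids[f]
    te <- sites == s
    std <- fold_standardise(features[!te, , drop = FALSE],
                            features[te, , drop = FALSE])
    fit <- e1071::svm(std$train, scores[!te], kernel = "linear", cost = cost,
                      scale = FALSE)
    preds[[f]] <- tibble(row = which(te), site = s, actual = scores[te],
                         predicted = as.numeric(stats::predict(fit, std$test)))
  }
  preds <- dplyr::bind_rows(preds)
  per_site <- dplyr::summarise(
    dplyr::group_by(preds, .data$site),
    n = dplyr::n(),
    r = if (sd(.data$actual) == 0 || sd(.data$predicted) == 0) NA_real_
        else cor(.data$actual, .data$predicted),
    .groups = "drop"
  )
  err <- preds$predicted - preds$actual
  structure(list(
    per_site = per_site,
    r_mean = mean(per_site$r, na.rm = TRUE),
    r_pooled = cor(preds$actual, preds$predicted),
    rmse = sqrt(mean(err^2)),
    r_squared = 1 - sum(err^2) / sum((preds$actual - mean(preds$actual))^2),
    predictions = preds
  ), class = "loso_regression")
}

#' @export
print.loso_regression <- function(x, ...) {
  cat(sprintf("<loso_regression> mean per-site r %.3f (pooled %.3f), RMSE %.3f, R^2 %.3f\n",
              x$r_mean, x$r_pooled, x$rmse, x$r_squared))
  invisible(x)
}

#' Region-wise cognition association map
#'
#' Per region, multiple linear regression of centrality on the cognition
#' score with age, sex and site (categorical indicators) as covariates; the
#' T statistic of the cognition coefficient is reported with
#' Benjamini-Hochberg correction across regions.
#'
#' @param centrality Subjects x regions matrix.
#' @param score Cognition score per subject (MMSE or MoCA).
#' @param age,sex,site Covariates per subject; `site` is treated as
#'   categorical.
#' @param q FDR level.
#' @return Tibble with columns `region`, `t`, `p`, `p_adj`, `significant`.
#' @export
cognition_association <- function(centrality, score, age, sex, site,
                                  q = 0.05) {
  centrality <- as.matrix(centrality)
  n <- nrow(centrality)
  stopifnot(length(score) == n, length(age) == n, length(sex) == n,
            length(site) == n)
  df <- data.frame(score = score, age = age,
                   sex = as.numeric(as.factor(sex)) - 1,
                   site = as.factor(site))
  X <- if (nlevels(df$site) > 1) {
    stats::model.matrix(~ score + age + sex + site, data = df)
  } else {
    stats::model.matrix(~ score + age + sex, data = df) # single-site cohort
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stopf("rank-deficient design (%d < %d columns)", qrX$rank, ncol(X))
  }
  dfree <- n - ncol(X)
  coefs <- qr.coef(qrX, centrality)
  resid <- qr.resid(qrX, centrality)
  sigma2 <- colSums(resid^2) / dfree
  xtx_inv <- solve(crossprod(X))["score", "score"]
  tval <- coefs["score", ] / sqrt(sigma2 * xtx_inv)
  pval <- 2 * pt(-abs(tval), dfree)
  adj <- fdr_bh(pval, q)
  tibble(region = seq_len(ncol(centrality)), t = as.numeric(tval),
         p = as.numeric(pval), p_adj = adj$p_adj, significant = adj$reject)
}
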