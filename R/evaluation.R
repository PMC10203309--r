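#' ROC curve and AUC
#'
#' Threshold-sweep ROC with tie handling; the trapezoid AUC equals the
#' Mann-Whitney statistic divided by `n_pos * n_neg` (ties count one half).
#' Higher scores are taken to indicate the positive (greater-decliner) class.
#'
#' @param scores numeric classifier scores.
#' @param labels per-sample labels; `positive` names the positive level.
#' @param positive the positive class label, default `"greater"`.
#' @return A list: `points` (data frame fpr/tpr/threshold), `auc`, and
#'   `degenerate` (TRUE when all scores tie).
#' @export
roc_auc <- function(scores, labels, positive = "greater") {
  labels <- as.character(labels)
  pos <- labels == positive
  if (!any(pos) || all(pos)) stop("both classes must be present")
  if (any(!is.finite(scores))) stop("scores must be finite")
  n_pos <- sum(pos); n_neg <- sum(!pos)

  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(c) sum(scores[pos] >= c) / n_pos, numeric(1))
  fpr <- vapply(thr, function(c) sum(scores[!pos] >= c) / n_neg, numeric(1))
  points <- data.frame(
    fpr = c(0, fpr, 1), tpr = c(0, tpr, 1), threshold = c(Inf, thr, -Inf)
  )
  auc <- sum(diff(points$fpr) * (points$tpr[-1] + points$tpr[-nrow(points)]) / 2)
  list(points = points, auc = auc, degenerate = length(thr) == 1L)
}

#' Hanley-McNeil standard error of an AUC
#'
#' Closed form from the Wilcoxon statistic:
#' `SE^2 = [A(1-A) + (n_pos-1)(Q1-A^2) + (n_neg-1)(Q2-A^2)] / (n_pos n_neg)`
#' with `Q1 = A/(2-A)` and `Q2 = 2A^2/(1+A)`.
#'
#' @param A the AUC, in \[0, 1\].
#' @param n_pos,n_neg class sizes (>= 1).
#' @return The standard error.
#' @export
hanley_mcneil_se <- function(A, n_pos, n_neg) {
  if (A < 0 || A > 1) stop("A must lie in [0, 1]")
  if (n_pos < 1 || n_neg < 1) stop("group sizes must be >= 1")
  q1 <- A / (2 - A)
  q2 <- 2 * A^2 / (1 + A)
  v <- (A * (1 - A) + (n_pos - 1) * (q1 - A^2) + (n_neg - 1) * (q2 - A^2)) /
    (n_pos * n_neg)
  sqrt(max(v, 0))
}

#' Compare two correlated AUCs (Hanley-McNeil)
#'
#' For two score vectors on the same labeled samples:
#' `z = (A1 - A2) / sqrt(se1^2 + se2^2 - 2 r se1 se2)` with a two-tailed
#' normal p. The between-curve correlation `r` is estimated as the mean of the
#' within-class Pearson correlations of the two score vectors.
#'
#' @param scores1,scores2 score vectors on identical samples.
#' @param labels class labels; `positive` as in [roc_auc()].
#' @param positive positive class label.
#' @return A list of class `roc_comparison`: `A1`, `A2`, `se1`, `se2`, `r`,
#'   `z`, `p`, `degenerate`.
#' @export
compare_auc_correlated <- function(scores1, scores2, labels,
                                   positive = "greater") {
  if (length(scores1) != length(scores2)) stop("score vectors must align")
  labels <- as.character(labels)
  pos <- labels == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  A1 <- roc_auc(scores1, labels, positive)$auc
  A2 <- roc_auc(scores2, labels, positive)$auc
  se1 <- hanley_mcneil_se(A1, n_pos, n_neg)
  se2 <- hanley_mcneil_se(A2, n_pos, n_neg)
  safe_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
    stats::cor(x, y)
  }
  r <- mean(c(safe_cor(scores1[pos], scores2[pos]),
              safe_cor(scores1[!pos], scores2[!pos])))
  v <- se1^2 + se2^2 - 2 * r * se1 * se2
  degenerate <- v <= 0
  if (degenerate) {
    z <- 0; p <- 1
  } else {
    z <- (A1 - A2) / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(A1 = A1, A2 = A2, se1 = se1, se2 = se2, r = r,
                 z = z, p = p, degenerate = degenerate),
            class = "roc_comparison")
}

#' Confusion-matrix metrics
#'
#' Sensitivity on the greater-decliner (positive) class, specificity on the
#' lesser class, their mean (balanced accuracy), and raw accuracy.
#'
#' @param predicted,truth label vectors (levels greater/lesser).
#' @return A list: `sensitivity`, `specificity`, `balanced_accuracy`,
#'   `accuracy`, all in \[0, 1\].
#' @export
confusion_metrics <- function(predicted, truth) {
  predicted <- check_binary_classes(predicted)
  truth <- check_binary_classes(truth)
  if (length(predicted) != length(truth)) stop("label vectors must align")
  if (!all(c("greater", "lesser") %in% truth)) {
    stop("both classes must appear in the truth labels")
  }
  pos <- truth == "greater"
  sens <- mean(predicted[pos] == "greater")
  spec <- mean(predicted[!pos] == "lesser")
  list(
    sensitivity = sens,
    specificity = spec,
    balanced_accuracy = (sens + spec) / 2,
    accuracy = mean(predicted == truth)
  )
}

#' Covariate-adjusted association of model scores with decline
#'
#' Ordinary least squares of annualized decline on a score vector plus
#' covariates (the adjustment set used for the score-vs-decline panels:
#' age, race, height, sex, baseline FEV1 percent predicted, smoking status,
#' pack-years, ICS use — or any covariate frame supplied).
#'
#' @param scores numeric scores (e.g. LV1 or PC1), one per participant.
#' @param decline annualized decline, mL/year.
#' @param covariates data frame of covariates (may be `NULL` for unadjusted).
#' @return A list: `coefficient` (score slope), `p` (t-based), `r_p`
#'   (unadjusted Pearson correlation of scores and decline), and the `fit`.
#' @export
adjusted_linear_association <- function(scores, decline, covariates = NULL) {
  if (length(scores) != length(decline)) stop("scores and decline must align")
  dat <- data.frame(.decline = decline, .score = scores)
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == length(scores))
    dat <- cbind(dat, covariates)
  }
  fit <- stats::lm(.decline ~ ., data = dat)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear terms: ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  list(
    coefficient = sm[".score", "Estimate"],
    p = sm[".score", "Pr(>|t|)"],
    r_p = stats::cor(scores, decline),
    fit = fit
  )
}
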