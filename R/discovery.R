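#' Balanced resample at the size of the smallest class
#'
#' Draws, from each class, a without-replacement subset of size equal to the
#' smallest class, so every resample has equal class counts (2 x n_min
#' samples). With the study's 14/31 split each resample keeps all 14 minority
#' samples and 14 of the 31 majority samples.
#'
#' @param classes per-sample labels (levels greater/lesser).
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return Integer sample indices (sorted).
#' @export
balanced_resample <- function(classes, seed = NULL) {
  classes <- check_binary_classes(classes)
  n_by <- table(classes)
  if (any(n_by < 2)) stop("each class needs n >= 2")
  n_min <- min(n_by)
  draw <- function() {
    idx <- unlist(lapply(levels(classes), function(l) {
      i <- which(classes == l)
      if (length(i) == n_min) i else sample(i, n_min)
    }))
    sort(idx)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Elastic-net selection-frequency ranking over balanced resamples
#'
#' Repeats, per iteration: balanced resample; elastic-net-penalized logistic
#' regression (mixing parameter `alpha_mix`) with the penalty strength chosen
#' by internal cross-validation at minimum deviance; record the analytes with
#' nonzero coefficients. Analytes are then ranked by selection frequency
#' (selections / `n_iterations`), with ties broken by higher mean absolute
#' coefficient across selecting iterations, then analyte id.
#'
#' @param X samples x analytes matrix or [proteomic_matrix] (preprocessed,
#'   log scale).
#' @param classes labels, levels greater/lesser.
#' @param n_iterations number of resamples (default 2000).
#' @param alpha_mix elastic-net mixing parameter in \[0, 1\], default 0.5.
#' @param seed master seed; per-iteration substreams are derived from it.
#' @param nfolds_inner folds for the internal penalty-choice CV, default 5.
#' @return A data frame of class `selection_ranking` (analyte, frequency,
#'   n_selected, mean_abs_coef), ordered by the ranking, with attributes
#'   `n_iterations` and `n_skipped`.
#' @export
enet_selection_frequencies <- function(X, classes, n_iterations = 2000,
                                       alpha_mix = 0.5, seed = 1L,
                                       nfolds_inner = 5) {
  if (inherits(X, "proteomic_matrix")) X <- X$values
  X <- as.matrix(X)
  classes <- check_binary_classes(classes)
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  y <- as.numeric(classes == "greater")
  p <- ncol(X)
  counts <- numeric(p)
  abs_coef <- numeric(p)
  skipped <- 0L
  seeds <- spawn_seeds(seed, n_iterations)
  for (i in seq_len(n_iterations)) {
    res <- with_seed(seeds[i], tryCatch({
      idx <- balanced_resample(classes)
      fit <- suppressWarnings(glmnet::cv.glmnet(
        X[idx, , drop = FALSE], y[idx],
        family = "binomial", alpha = alpha_mix,
        nfolds = nfolds_inner, type.measure = "deviance"
      ))
      as.numeric(stats::coef(fit, s = "lambda.min"))[-1]
    }, error = function(e) NULL))
    if (is.null(res)) {
      skipped <- skipped + 1L
      next
    }
    nz <- res != 0
    counts[nz] <- counts[nz] + 1
    abs_coef[nz] <- abs_coef[nz] + abs(res[nz])
  }
  if (skipped > 0.1 * n_iterations) {
    stop(sprintf("%d of %d elastic-net iterations failed", skipped,
                 n_iterations))
  }
  ranking <- data.frame(
    analyte = colnames(X),
    frequency = counts / n_iterations,
    n_selected = counts,
    mean_abs_coef = ifelse(counts > 0, abs_coef / counts, 0),
    stringsAsFactors = FALSE
  )
  ord <- order(-ranking$frequency, -ranking$mean_abs_coef, ranking$analyte)
  ranking <- ranking[ord, , drop = FALSE]
  rownames(ranking) <- NULL
  attr(ranking, "n_iterations") <- n_iterations
  attr(ranking, "n_skipped") <- skipped
  class(ranking) <- c("selection_ranking", "data.frame")
  ranking
}

# Stratified fold assignment; k = n gives leave-one-out.
assign_folds <- function(classes, k, seed) {
  n <- length(classes)
  if (k < 2 || k > n) stop("k must be in [2, n]")
  if (k == n) return(seq_len(n))
  if (min(table(classes)) < k) {
    stop("a class is too small to stratify into ", k,
         " folds; use a smaller k")
  }
  with_seed(seed, {
    folds <- integer(n)
    for (l in levels(classes)) {
      i <- sample(which(classes == l))
      folds[i] <- rep_len(seq_len(k), length(i))
    }
    folds
  })
}

#' k-fold cross-validated evaluation of a feature signature
#'
#' Stratified k-fold CV of a PLSDA model on a feature set: autoscaling and
#' fitting use training folds only; held-out predictions are pooled across
#' folds into cross-validated sensitivity, specificity, balanced accuracy and
#' ROC/AUC. Calibration metrics come from the full-data fit. `k = n` gives
#' leave-one-out.
#'
#' @param features analyte ids to use.
#' @param X samples x analytes matrix or [proteomic_matrix].
#' @param classes labels, levels greater/lesser.
#' @param k number of folds, default 6.
#' @param seed fold-assignment seed.
#' @param n_lv latent variables for the PLSDA fits, default 2.
#' @return A list of class `signature_evaluation`: `features`, `calibration`
#'   and `cv` metric lists (sensitivity, specificity, balanced_accuracy,
#'   accuracy, auc), `cv_roc` points, `cv_response` (pooled out-of-fold
#'   responses), `fold` assignment and per-fold raw accuracies
#'   `fold_accuracy`, and the full-data `model`.
#' @export
kfold_cv_evaluate <- function(features, X, classes, k = 6, seed = 1L,
                              n_lv = 2) {
  if (inherits(X, "proteomic_matrix")) X <- X$values
  X <- as.matrix(X)
  classes <- check_binary_classes(classes)
  missing <- setdiff(features, colnames(X))
  if (length(missing)) {
    stop("features absent from X: ", paste(missing, collapse = ", "))
  }
  Xf <- X[, features, drop = FALSE]
  n <- nrow(Xf)
  folds <- assign_folds(classes, k, seed)

  cv_response <- numeric(n)
  cv_class <- character(n)
  fold_accuracy <- numeric(k)
  for (fold in seq_len(k)) {
    test <- folds == fold
    fit <- suppressWarnings(
      fit_plsda(Xf[!test, , drop = FALSE], classes[!test], n_lv = n_lv)
    )
    pr <- predict(fit, Xf[test, , drop = FALSE])
    cv_response[test] <- pr$response
    cv_class[test] <- as.character(pr$class)
    fold_accuracy[fold] <- mean(pr$class == classes[test])
  }
  cv_class <- factor(cv_class, levels = c("greater", "lesser"))
  cv_conf <- confusion_metrics(cv_class, classes)
  cv_roc <- roc_auc(cv_response, classes)
  y <- as.numeric(classes == "greater")
  cv_rmse <- sqrt(mean((cv_response - y)^2))

  model <- suppressWarnings(fit_plsda(Xf, classes, n_lv = n_lv))
  cal_pred <- predict(model, Xf)
  cal_conf <- confusion_metrics(cal_pred$class, classes)
  cal_roc <- roc_auc(cal_pred$response, classes)

  structure(list(
    features = features,
    calibration = c(cal_conf, list(auc = cal_roc$auc)),
    cv = c(cv_conf, list(auc = cv_roc$auc, rmse = cv_rmse)),
    cv_roc = cv_roc$points,
    cv_response = cv_response,
    cv_class = cv_class,
    fold = folds,
    fold_accuracy = fold_accuracy,
    model = model
  ), class = "signature_evaluation")
}

#' @export
print.signature_evaluation <- function(x, ...) {
  cat(sprintf(
    paste0("signature_evaluation: %d features\n",
           "  calibration: bal.acc %.1f%%, sens %.1f%%, spec %.1f%%, AUC %.3f\n",
           "  CV:          bal.acc %.1f%%, sens %.1f%%, spec %.1f%%, AUC %.3f\n"),
    length(x$features),
    100 * x$calibration$balanced_accuracy, 100 * x$calibration$sensitivity,
    100 * x$calibration$specificity, x$calibration$auc,
    100 * x$cv$balanced_accuracy, 100 * x$cv$sensitivity,
    100 * x$cv$specificity, x$cv$auc
  ))
  invisible(x)
}

#' Step-forward PLSDA search over a selection ranking
#'
#' Starting from the most frequently selected analyte, grows the feature set
#' one analyte at a time in ranking order, evaluating each size by stratified
#' k-fold CV. The optimal signature is the size with the highest CV balanced
#' accuracy; accuracy ties (common once the curve saturates) are broken by
#' the lowest cross-validated response RMSE, then the smallest size. The same
#' fold assignment is used at every size so the curve is comparable across
#' steps.
#'
#' @param ranking a `selection_ranking` (or character vector of analytes in
#'   rank order).
#' @param X,classes data as in [kfold_cv_evaluate()].
#' @param k folds, default 6.
#' @param max_size largest signature size to evaluate (clipped to the number
#'   of analytes, with a warning), default 100.
#' @param seed fold-assignment seed.
#' @param n_lv latent variables, default 2.
#' @return A list of class `step_forward_curve`: `curve` (data frame: size,
#'   cv/calibration metrics), `order` (ranked analytes), `optimal_size`,
#'   `optimal_features`, and `optimal` (the [kfold_cv_evaluate()] result at
#'   the optimal size).
#' @export
step_forward_search <- function(ranking, X, classes, k = 6, max_size = 100,
                                seed = 1L, n_lv = 2) {
  ord <- if (is.data.frame(ranking)) ranking$analyte else as.character(ranking)
  if (inherits(X, "proteomic_matrix")) X <- X$values
  missing <- setdiff(colnames(X), ord)
  if (length(missing)) {
    stop("ranking does not cover X analytes: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  if (max_size > length(ord)) {
    warning("max_size exceeds analyte count; clipping to ", length(ord))
    max_size <- length(ord)
  }
  evals <- vector("list", max_size)
  for (s in seq_len(max_size)) {
    evals[[s]] <- kfold_cv_evaluate(ord[seq_len(s)], X, classes,
                                    k = k, seed = seed, n_lv = n_lv)
  }
  curve <- data.frame(
    size = seq_len(max_size),
    cv_balanced_accuracy = vapply(evals, function(e) e$cv$balanced_accuracy,
                                  numeric(1)),
    cv_sensitivity = vapply(evals, function(e) e$cv$sensitivity, numeric(1)),
    cv_specificity = vapply(evals, function(e) e$cv$specificity, numeric(1)),
    cv_auc = vapply(evals, function(e) e$cv$auc, numeric(1)),
    cv_rmse = vapply(evals, function(e) e$cv$rmse, numeric(1)),
    cal_balanced_accuracy = vapply(
      evals, function(e) e$calibration$balanced_accuracy, numeric(1)
    )
  )
  # highest CV balanced accuracy; accuracy ties (common once the curve
  # saturates) resolved by the lowest cross-validated response error, then
  # the smallest size
  ord_opt <- order(-curve$cv_balanced_accuracy, curve$cv_rmse, curve$size)
  optimal_size <- curve$size[ord_opt[1]]
  structure(list(
    curve = curve,
    order = ord,
    optimal_size = optimal_size,
    optimal_features = ord[seq_len(optimal_size)],
    optimal = evals[[optimal_size]]
  ), class = "step_forward_curve")
}

#' Minimal signatures from a step-forward curve
#'
#' Candidate parsimonious signatures: steps with fewer than `max_size`
#' features and CV balanced accuracy strictly above `min_cv_accuracy`
#' (a step at exactly the threshold is excluded). Local maxima of the CV
#' accuracy curve are flagged.
#'
#' @param sf a [step_forward_search()] result (or its `curve` data frame).
#' @param max_size exclusive size bound, default 15.
#' @param min_cv_accuracy exclusive CV balanced-accuracy bound, default 0.80.
#' @return Data frame of qualifying steps (size, metrics, `local_max`),
#'   possibly empty.
#' @export
minimal_signatures <- function(sf, max_size = 15, min_cv_accuracy = 0.80) {
  curve <- if (inherits(sf, "step_forward_curve")) sf$curve else sf
  acc <- curve$cv_balanced_accuracy
  n <- length(acc)
  local_max <- vapply(seq_len(n), function(i) {
    left <- if (i == 1) -Inf else acc[i - 1]
    right <- if (i == n) -Inf else acc[i + 1]
    acc[i] >= left && acc[i] >= right
  }, logical(1))
  out <- curve[curve$size < max_size & acc > min_cv_accuracy, , drop = FALSE]
  out$local_max <- local_max[curve$size < max_size & acc > min_cv_accuracy]
  rownames(out) <- NULL
  out
}

#' Random-signature null distribution
#'
#' Evaluates `n_random` random feature sets of a given size by k-fold CV and
#' compares an observed signature's CV balanced accuracy against the null:
#' empirical `p = (1 + #null >= observed) / (1 + n_random)`, plus the
#' two-tailed two-sample t-test of the observed signature's per-fold
#' accuracies against the null accuracies.
#'
#' @param X,classes data as in [kfold_cv_evaluate()].
#' @param signature_size features per random signature.
#' @param n_random number of random signatures, default 2000 (a warning is
#'   issued below 20).
#' @param k folds, default 6.
#' @param seed master seed.
#' @param observed optional `signature_evaluation` (or numeric CV balanced
#'   accuracy) to compare against.
#' @param n_lv latent variables, default 2.
#' @return A list of class `signature_null`: `null_accuracy` (CV balanced
#'   accuracies), `observed`, `p_empirical`, `p_ttest` (NA when no observed
#'   evaluation with fold accuracies is given).
#' @export
random_signature_null <- function(X, classes, signature_size,
                                  n_random = 2000, k = 6, seed = 1L,
                                  observed = NULL, n_lv = 2) {
  if (inherits(X, "proteomic_matrix")) X <- X$values
  X <- as.matrix(X)
  if (signature_size > ncol(X)) {
    stop("signature_size exceeds the analyte count")
  }
  if (n_random < 20) warning("n_random < 20 gives an unstable null")
  seeds <- spawn_seeds(seed, n_random)
  null_acc <- vapply(seq_len(n_random), function(i) {
    feats <- with_seed(seeds[i], sample(colnames(X), signature_size))
    ev <- kfold_cv_evaluate(feats, X, classes, k = k, seed = seeds[i],
                            n_lv = n_lv)
    ev$cv$balanced_accuracy
  }, numeric(1))

  obs_acc <- NA_real_
  p_ttest <- NA_real_
  if (!is.null(observed)) {
    if (inherits(observed, "signature_evaluation")) {
      obs_acc <- observed$cv$balanced_accuracy
      p_ttest <- tryCatch(
        stats::t.test(observed$fold_accuracy, null_acc)$p.value,
        error = function(e) NA_real_   # both samples essentially constant
      )
    } else {
      obs_acc <- as.numeric(observed)
    }
  }
  p_emp <- if (is.na(obs_acc)) NA_real_ else {
    (1 + sum(null_acc >= obs_acc)) / (1 + n_random)
  }
  structure(list(
    null_accuracy = null_acc,
    observed = obs_acc,
    p_empirical = p_emp,
    p_ttest = p_ttest
  ), class = "signature_null")
}
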