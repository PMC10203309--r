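test_that("balanced resampling draws at the size of the smallest class", {
  cls <- toy_classes(14, 31)
  idx <- balanced_resample(cls, seed = 1)
  expect_length(idx, 28)
  expect_true(all(which(cls == "greater") %in% idx))  # minority fully kept
  expect_equal(sum(cls[idx] == "lesser"), 14)
  # equal classes: every resample is the full dataset
  expect_equal(balanced_resample(toy_classes(10, 10), seed = 2), 1:20)
  # determinism per seed
  expect_equal(balanced_resample(cls, seed = 7), balanced_resample(cls, seed = 7))
  expect_error(balanced_resample(toy_classes(1, 5)), "n >= 2")
})

test_that("majority-class inclusion frequency matches the sampling expectation", {
  cls <- toy_classes(14, 31)
  lesser_idx <- which(cls == "lesser")
  counts <- integer(45)
  n_draw <- 500
  for (s in seq_len(n_draw)) {
    idx <- balanced_resample(cls, seed = s)
    counts[idx] <- counts[idx] + 1L
  }
  freq <- counts[lesser_idx] / n_draw
  expect_lt(max(abs(freq - 14 / 31)), 4 * sqrt((14 / 31) * (17 / 31) / n_draw))
})

test_that("elastic-net ranking recovers planted analytes", {
  set.seed(50)
  n <- 45
  cls <- toy_classes(14, 31)
  p_noise <- 200
  X <- matrix(rnorm(n * p_noise), n, p_noise,
              dimnames = list(paste0("S", 1:n), sprintf("N%03d", 1:p_noise)))
  planted <- sprintf("P%d", 1:5)
  sig <- sapply(planted, function(a) rnorm(n) + 2.0 * (cls == "greater"))
  X <- cbind(X, sig)
  rk <- enet_selection_frequencies(X, cls, n_iterations = 500, seed = 60)
  expect_true(all(planted %in% rk$analyte[1:10]))
  expect_true(all(diff(rk$frequency) <= 0))
  expect_setequal(rk$analyte, colnames(X))
  # determinism
  rk2 <- enet_selection_frequencies(X, cls, n_iterations = 50, seed = 61)
  rk3 <- enet_selection_frequencies(X, cls, n_iterations = 50, seed = 61)
  expect_identical(rk2, rk3)
})

test_that("the elastic net's grouping keeps duplicated signal analytes together", {
  set.seed(52)
  cls <- toy_classes(10, 12)
  base <- rnorm(22) + 1.8 * (cls == "greater")
  X <- cbind(
    matrix(rnorm(22 * 30), 22, 30,
           dimnames = list(NULL, sprintf("N%02d", 1:30))),
    D1 = base + rnorm(22, sd = 0.01),
    D2 = base + rnorm(22, sd = 0.01)
  )
  rownames(X) <- paste0("S", 1:22)
  rk <- enet_selection_frequencies(X, cls, n_iterations = 100, seed = 53)
  expect_gt(rk$frequency[rk$analyte == "D1"], 0)
  expect_gt(rk$frequency[rk$analyte == "D2"], 0)
})

test_that("pure-noise selection frequencies stay near the permutation baseline", {
  set.seed(55)
  cls <- toy_classes(14, 31)
  X <- matrix(rnorm(45 * 60), 45, 60,
              dimnames = list(paste0("S", 1:45), sprintf("V%02d", 1:60)))
  rk <- enet_selection_frequencies(X, cls, n_iterations = 100, seed = 56)
  # permutation baseline: same data, permuted labels
  perm_cls <- cls[sample(45)]
  rk_perm <- enet_selection_frequencies(X, perm_cls, n_iterations = 100,
                                        seed = 57)
  expect_lt(max(rk$frequency), max(rk_perm$frequency) + 0.35)
})

test_that("step-forward search finds the separating analyte and is reproducible", {
  set.seed(70)
  cls <- toy_classes(8, 10)
  X <- cbind(
    SEP = c(rnorm(8, 8, 0.2), rnorm(10, 0, 0.2)),
    matrix(rnorm(18 * 10), 18, 10, dimnames = list(NULL, sprintf("N%02d", 1:10)))
  )
  rownames(X) <- paste0("S", 1:18)
  ranking <- c("SEP", sprintf("N%02d", 1:10))
  sf <- step_forward_search(ranking, X, cls, k = 6, max_size = 5, seed = 71)
  expect_equal(sf$curve$cv_balanced_accuracy[1], 1)
  expect_equal(sf$optimal_size, 1)   # ties resolve to the smallest size
  sf2 <- step_forward_search(ranking, X, cls, k = 6, max_size = 5, seed = 71)
  expect_equal(sf$curve, sf2$curve)
  expect_warning(
    step_forward_search(ranking, X, cls, k = 6, max_size = 50, seed = 71),
    "clipping"
  )
})

test_that("k-fold CV pools out-of-fold predictions without leakage", {
  prep <- small_prepared()
  ev <- kfold_cv_evaluate(prep$planted, prep$merged, prep$classes,
                          k = 6, seed = 80)
  expect_length(ev$fold_accuracy, 6)
  expect_true(ev$cv$balanced_accuracy > 0.8)  # strong planted signal
  expect_equal(sort(unique(ev$fold)), 1:6)
  # stratification: every fold carries both classes
  expect_true(all(table(ev$fold, prep$classes) > 0))
  expect_error(
    kfold_cv_evaluate(prep$planted, prep$merged, prep$classes, k = 20),
    "smaller k"
  )
})

test_that("leave-one-out CV equals a brute-force oracle", {
  X <- toy_matrix(10, 4, seed = 85)
  cls <- toy_classes(5, 5)
  ev <- kfold_cv_evaluate(colnames(X), X, cls, k = 10, seed = 1)
  oracle_resp <- numeric(10)
  oracle_cls <- character(10)
  for (i in 1:10) {
    fit <- fit_plsda(X[-i, ], cls[-i], n_lv = 2)
    pr <- predict(fit, X[i, , drop = FALSE])
    oracle_resp[i] <- pr$response
    oracle_cls[i] <- as.character(pr$class)
  }
  expect_equal(ev$cv_response, oracle_resp)
  expect_equal(as.character(ev$cv_class), oracle_cls)
})

test_that("permuted labels on null data give chance-level CV accuracy", {
  set.seed(90)
  X <- matrix(rnorm(30 * 12), 30, 12,
              dimnames = list(paste0("S", 1:30), sprintf("V%02d", 1:12)))
  accs <- sapply(1:5, function(s) {
    cls <- factor(sample(rep(c("greater", "lesser"), c(13, 17))),
                  levels = c("greater", "lesser"))
    kfold_cv_evaluate(colnames(X), X, cls, k = 6, seed = s)$cv$balanced_accuracy
  })
  expect_lt(abs(mean(accs) - 0.5), 0.16)
})

test_that("minimal signatures apply the size and accuracy bounds strictly", {
  curve <- data.frame(
    size = 1:5,
    cv_balanced_accuracy = c(0.6, 0.82, 0.85, 0.80, 0.79),
    cv_sensitivity = 0.8, cv_specificity = 0.8, cv_auc = 0.8,
    cal_balanced_accuracy = 0.9
  )
  out <- minimal_signatures(curve, max_size = 15, min_cv_accuracy = 0.80)
  expect_equal(out$size, c(2, 3))            # 0.80 exactly is excluded
  expect_true(out$local_max[out$size == 3])
  none <- minimal_signatures(
    transform(curve, cv_balanced_accuracy = c(0.5, 0.6, 0.7, 0.8, 0.75))
  )
  expect_equal(nrow(none), 0)
  # size bound is exclusive
  out2 <- minimal_signatures(curve, max_size = 3)
  expect_equal(out2$size, 2)
})

test_that("random-signature null separates planted signal from chance", {
  prep <- small_prepared()
  ev <- kfold_cv_evaluate(prep$planted, prep$merged, prep$classes,
                          k = 6, seed = 80)
  nl <- random_signature_null(prep$merged, prep$classes,
                              signature_size = length(prep$planted),
                              n_random = 60, k = 6, seed = 81, observed = ev)
  expect_length(nl$null_accuracy, 60)
  # a planted signature beats nearly every random draw of the same size
  expect_lt(nl$p_empirical, 0.1)
  expect_lt(nl$p_ttest, 0.01)
  # determinism
  nl2 <- random_signature_null(prep$merged, prep$classes,
                               signature_size = length(prep$planted),
                               n_random = 60, k = 6, seed = 81, observed = ev)
  expect_equal(nl$null_accuracy, nl2$null_accuracy)
  expect_warning(
    random_signature_null(prep$merged, prep$classes, 3, n_random = 5,
                          k = 6, seed = 1),
    "unstable"
  )
  expect_error(
    random_signature_null(prep$merged, prep$classes, 10000, n_random = 20),
    "exceeds"
  )
})
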