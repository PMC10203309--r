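#' Autoscaled principal component analysis
#'
#' Mean-centers and variance-scales every analyte, then computes principal
#' components. Constant columns are dropped with a warning.
#'
#' @param X samples x analytes matrix or [proteomic_matrix].
#' @param n_components components to retain (default
#'   `min(n - 1, p)`).
#' @return A list of class `pca_profile`: `scores`, `loadings`,
#'   `variance_explained` (fractions of total autoscaled variance), `center`,
#'   `scale_sd`, `n_components`.
#' @export
pca_fit <- function(X, n_components = NULL) {
  if (inherits(X, "proteomic_matrix")) X <- X$values
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stop("PCA needs at least 3 samples")
  sdv <- apply(X, 2, stats::sd)
  if (any(sdv == 0)) {
    warning("dropping constant analytes: ",
            paste(colnames(X)[sdv == 0], collapse = ", "))
    X <- X[, sdv > 0, drop = FALSE]
  }
  p <- ncol(X)
  max_comp <- min(n - 1, p)
  if (is.null(n_components)) n_components <- max_comp
  if (n_components > max_comp) stop("n_components exceeds min(n - 1, p)")
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  keep <- seq_len(n_components)
  structure(list(
    scores = pc$x[, keep, drop = FALSE],
    loadings = pc$rotation[, keep, drop = FALSE],
    variance_explained = (pc$sdev^2 / sum(pc$sdev^2))[keep],
    sdev = pc$sdev[keep],
    center = pc$center,
    scale_sd = pc$scale,
    n_samples = n,
    n_components = n_components
  ), class = "pca_profile")
}

#' @export
print.pca_profile <- function(x, ...) {
  cat(sprintf(
    "pca_profile: %d samples, %d components; variance explained: %s\n",
    x$n_samples, x$n_components,
    paste(sprintf("%.1f%%",
                  100 * utils::head(x$variance_explained, 5)),
          collapse = ", ")
  ))
  invisible(x)
}

#' Hotelling reduced-T2 outlier flags
#'
#' Per-sample Hotelling T2 over the retained components, normalized by the
#' 95% confidence limit `A(n-1)/(n-A) * F(0.95; A, n-A)` (the "reduced" T2).
#' Samples with reduced T2 above `threshold` (default 2) are flagged; callers
#' refit after removal.
#'
#' @param profile a [pca_fit()] result.
#' @param threshold reduced-T2 cutoff, default 2.
#' @return A list: `t2`, `reduced_t2`, `limit` (the 95% confidence limit),
#'   `outlier` (logical flags).
#' @export
hotelling_outliers <- function(profile, threshold = 2) {
  stopifnot(inherits(profile, "pca_profile"))
  if (threshold <= 0) stop("threshold must be positive")
  A <- profile$n_components
  n <- profile$n_samples
  if (n <= A) stop("need more samples than components for the T2 limit")
  t2 <- rowSums(sweep(profile$scores^2, 2, profile$sdev^2, "/"))
  limit <- A * (n - 1) / (n - A) * stats::qf(0.95, A, n - A)
  reduced <- t2 / limit
  list(t2 = t2, reduced_t2 = reduced, limit = limit,
       outlier = reduced > threshold)
}

#' Permutation test of group separation in the PC1-PC2 plane
#'
#' Statistic: Euclidean distance between the two group centroids in the space
#' of the first two component scores. Labels are permuted; the p-value is
#' `(1 + #perm >= observed) / (1 + n_perm)`.
#'
#' @param scores samples x >=2 score matrix (only the first two columns are
#'   used).
#' @param groups two-level labels, each group n >= 2.
#' @param n_perm permutations, default 10000 (a warning is issued below 100).
#' @param seed RNG seed.
#' @return A list: `statistic` (observed centroid distance), `p`, `n_perm`.
#' @export
permutation_group_test <- function(scores, groups, n_perm = 10000,
                                   seed = 1L) {
  scores <- as.matrix(scores)[, 1:2, drop = FALSE]
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) != 2) stop("exactly two groups required")
  if (any(table(groups) < 2)) stop("each group needs n >= 2")
  if (n_perm < 100) warning("n_perm < 100 gives an unstable p-value")
  centroid_dist <- function(g) {
    m <- apply(scores, 2, function(col) tapply(col, g, mean))
    sqrt(sum((m[1, ] - m[2, ])^2))
  }
  obs <- centroid_dist(groups)
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    centroid_dist(sample(groups))
  }, numeric(1)))
  list(statistic = obs, p = (1 + sum(perm >= obs)) / (1 + n_perm),
       n_perm = n_perm)
}

#' Spearman-distance average-linkage clustering of a signature
#'
#' Sample-to-sample distance is one minus the Spearman correlation of the two
#' samples' profiles across the signature analytes; average-linkage
#' agglomeration is cut at two clusters, clusters are mapped to decline
#' classes by majority (ties toward the larger class), and confusion metrics
#' are returned.
#'
#' @param X_signature samples x analytes matrix or [proteomic_matrix]
#'   restricted to the signature.
#' @param classes labels, levels greater/lesser.
#' @return A list: `hclust` (the tree), `cluster` (1/2 per sample),
#'   `assigned` (mapped class labels), `sensitivity`, `specificity`,
#'   `misclassified` (count), `distance` (the dist object).
#' @export
hierarchical_cluster_eval <- function(X_signature, classes) {
  if (inherits(X_signature, "proteomic_matrix")) {
    X_signature <- X_signature$values
  }
  X_signature <- as.matrix(X_signature)
  classes <- check_binary_classes(classes)
  if (ncol(X_signature) < 2) stop("need at least 2 analytes")
  if (any(table(classes) < 2)) stop("each class needs n >= 2")
  const <- apply(X_signature, 1, function(r) stats::sd(r) == 0)
  if (any(const)) {
    stop("constant sample profile (rank correlation undefined): ",
         paste(rownames(X_signature)[const], collapse = ", "))
  }
  rho <- stats::cor(t(X_signature), method = "spearman")
  d <- stats::as.dist(1 - rho)
  hc <- stats::hclust(d, method = "average")
  cl <- stats::cutree(hc, k = 2)

  # majority mapping of the two clusters onto the classes
  tab <- table(cluster = cl, class = classes)
  maj1 <- if (tab["1", "greater"] > tab["1", "lesser"]) "greater"
          else if (tab["1", "greater"] < tab["1", "lesser"]) "lesser"
          else "lesser"                      # tie -> the larger class
  map <- c("1" = maj1, "2" = setdiff(c("greater", "lesser"), maj1))
  assigned <- factor(unname(map[as.character(cl)]),
                     levels = c("greater", "lesser"))
  conf <- confusion_metrics(assigned, classes)
  list(
    hclust = hc,
    cluster = cl,
    assigned = assigned,
    sensitivity = conf$sensitivity,
    specificity = conf$specificity,
    balanced_accuracy = conf$balanced_accuracy,
    misclassified = sum(assigned != classes),
    distance = d
  )
}

#' Write a dendrogram as Newick text
#'
#' @param hc an `hclust` tree.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  stopifnot(inherits(hc, "hclust"))
  if (requireNamespace("ape", quietly = TRUE)) {
    ape::write.tree(ape::as.phylo(hc), file = path)
  } else {
    # minimal recursive fallback: heights become branch lengths
    lab <- hc$labels
    if (is.null(lab)) lab <- as.character(seq_along(hc$order))
    node_str <- function(i, parent_h) {
      if (i < 0) {
        sprintf("%s:%g", lab[-i], parent_h)
      } else {
        h <- hc$height[i]
        sprintf("(%s,%s):%g",
                node_str(hc$merge[i, 1], h / 2),
                node_str(hc$merge[i, 2], h / 2),
                parent_h - h)
      }
    }
    top <- nrow(hc$merge)
    writeLines(paste0(
      "(", node_str(hc$merge[top, 1], hc$height[top] / 2), ",",
      node_str(hc$merge[top, 2], hc$height[top] / 2), ");"
    ), path)
  }
  invisible(path)
}

#' One-way ANOVA on component scores with a post-hoc family
#'
#' Standard one-way ANOVA F-test of scores across groups, followed by the
#' requested pairwise post-hoc procedure: Tukey HSD, Dunnett (vs the first
#' factor level), Holm-Sidak step-down, or Bonferroni.
#'
#' @param scores numeric scores on one component.
#' @param groups group labels (>= 2 groups, each n >= 2).
#' @param posthoc one of `"tukey"`, `"dunnett"`, `"holm_sidak"`,
#'   `"bonferroni"`.
#' @return A list: `f`, `p_anova`, and `posthoc` (data frame: comparison,
#'   p_adj).
#' @export
group_score_anova <- function(scores, groups,
                              posthoc = c("tukey", "dunnett", "holm_sidak",
                                          "bonferroni")) {
  posthoc <- match.arg(posthoc)
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(table(groups) < 2)) stop("each group needs n >= 2")
  dat <- data.frame(score = scores, group = groups)
  fit <- stats::aov(score ~ group, data = dat)
  sm <- summary(fit)[[1]]
  out <- list(f = sm["group", "F value"], p_anova = sm["group", "Pr(>F)"])

  if (posthoc == "tukey") {
    tk <- stats::TukeyHSD(fit)$group
    ph <- data.frame(comparison = rownames(tk), p_adj = tk[, "p adj"],
                     stringsAsFactors = FALSE)
  } else if (posthoc == "dunnett") {
    gl <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
    sm2 <- summary(gl)
    ph <- data.frame(
      comparison = names(sm2$test$coefficients),
      p_adj = as.numeric(sm2$test$pvalues),
      stringsAsFactors = FALSE
    )
  } else {
    # all pairwise pooled-variance t-tests, then the requested correction
    lev <- levels(groups)
    pairs <- utils::combn(lev, 2)
    p_raw <- apply(pairs, 2, function(pr) {
      two_sample_ttest(scores[groups == pr[1]], scores[groups == pr[2]])$p
    })
    p_adj <- if (posthoc == "bonferroni") {
      pmin(1, p_raw * length(p_raw))
    } else {
      holm_sidak_adjust(p_raw)
    }
    ph <- data.frame(
      comparison = apply(pairs, 2, paste, collapse = "-"),
      p_adj = p_adj,
      stringsAsFactors = FALSE
    )
  }
  rownames(ph) <- NULL
  out$posthoc <- ph
  out
}

#' Holm-Sidak step-down adjustment
#'
#' Step-down Sidak: the i-th smallest of m p-values is adjusted to
#' `1 - (1 - p)^(m - i + 1)`, with a running maximum to enforce monotonicity.
#'
#' @param p raw p-values.
#' @return Adjusted p-values in the input order.
#' @export
holm_sidak_adjust <- function(p) {
  if (any(p < 0) || any(p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  ord <- order(p)
  adj <- 1 - (1 - p[ord])^(m - seq_len(m) + 1)
  adj <- cummax(adj)
  out <- numeric(m)
  out[ord] <- pmin(adj, 1)
  out
}
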