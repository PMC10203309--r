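#' Two-sample two-tailed t-test
#'
#' Student pooled-variance test by default (the convention that reproduces the
#' cohort table's printed p-values from its summary statistics); Welch
#' optionally. Degenerate input with zero variance in both groups and equal
#' means returns p = 1 by convention.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return A list with `t` and two-tailed `p`.
#' @export
two_sample_ttest <- function(x, y, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (length(x) < 2 || length(y) < 2) stop("each group needs n >= 2")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("values must be finite")
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  d <- mean(x) - mean(y)
  if (vx == 0 && vy == 0) {
    if (d == 0) return(list(t = 0, p = 1))
    return(list(t = sign(d) * Inf, p = 0))
  }
  if (variant == "pooled") {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  t <- d / se
  list(t = t, p = 2 * stats::pt(-abs(t), df))
}

#' Summary-statistic two-sample t-test
#'
#' Pooled-variance t-test reconstructed from group means, SDs and sizes (for
#' checking published cohort-table p-values).
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group summary statistics.
#' @return A list with `t` and two-tailed `p`.
#' @export
ttest_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * stats::pt(-abs(t), n1 + n2 - 2))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_raw vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values (monotone over the sorted sequence, capped at 1).
#' @export
bh_adjust <- function(p_raw) {
  if (any(!is.finite(p_raw)) || any(p_raw < 0) || any(p_raw > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_raw, method = "BH")
}

#' Per-analyte screen: fold changes, t-tests, FDR
#'
#' For each analyte: log2 fold change of the greater-decliner mean over the
#' lesser-decliner mean computed from raw-scale (back-transformed) arithmetic
#' means; a two-sample t-test on the log-scale values; Benjamini-Hochberg
#' adjustment across all analytes.
#'
#' @param matrix log-scale [proteomic_matrix].
#' @param classes per-sample labels, levels greater/lesser, aligned with rows.
#' @param variant t-test variant, default pooled.
#' @param alpha significance level for the reported counts, default 0.05.
#' @return A data frame (analyte, compartment, fc, t, p_raw, p_adj,
#'   sig_05, sig_01) with attributes `"n_significant"` (raw p < alpha) and
#'   `"n_significant_adj"` (BH-adjusted p < alpha).
#' @export
univariate_screen <- function(matrix, classes, variant = "pooled",
                              alpha = 0.05) {
  stopifnot_pm(matrix, scale = "log")
  classes <- check_binary_classes(classes)
  if (any(table(classes) < 2)) stop("each class needs n >= 2")
  g <- classes == "greater"
  raw <- 2^matrix$values
  fc <- log2(colMeans(raw[g, , drop = FALSE]) /
             colMeans(raw[!g, , drop = FALSE]))
  res <- apply(matrix$values, 2, function(col) {
    unlist(two_sample_ttest(col[g], col[!g], variant = variant))
  })
  p_raw <- res["p", ]
  p_raw[p_raw == 0] <- .Machine$double.xmin   # underflow guard for volcano use
  out <- data.frame(
    analyte = colnames(matrix$values),
    compartment = unname(matrix$compartment),
    fc = unname(fc),
    t = unname(res["t", ]),
    p_raw = unname(p_raw),
    stringsAsFactors = FALSE
  )
  out$p_adj <- bh_adjust(out$p_raw)
  out$sig_05 <- out$p_raw < 0.05
  out$sig_01 <- out$p_raw < 0.01
  attr(out, "n_significant") <- sum(out$p_raw < alpha)
  attr(out, "n_significant_adj") <- sum(out$p_adj < alpha)
  out
}
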