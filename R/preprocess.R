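#' Detection-limit specification for an immunoassay panel
#'
#' Per-analyte lower and upper limits of detection, plus the global imputation
#' constant used for below-LLOD values: half the lowest minimum detectable
#' concentration across all analytes' standard curves, i.e. `min(llod) / 2`.
#'
#' @param analyte character analyte ids.
#' @param llod,ulod numeric lower/upper limits of detection (concentration
#'   units), one per analyte, with `llod < ulod`.
#' @return A data frame of class `lod_spec` with attribute
#'   `"imputation_constant"`.
#' @export
lod_spec <- function(analyte, llod, ulod) {
  stopifnot(length(analyte) == length(llod), length(llod) == length(ulod))
  if (any(!is.finite(llod)) || any(!is.finite(ulod))) stop("non-finite limits")
  if (any(llod <= 0)) stop("LLODs must be positive")
  if (any(llod >= ulod)) stop("each analyte needs LLOD < ULOD")
  out <- data.frame(analyte = as.character(analyte), llod = llod, ulod = ulod,
                    stringsAsFactors = FALSE)
  attr(out, "imputation_constant") <- min(llod) / 2
  class(out) <- c("lod_spec", "data.frame")
  out
}

#' Censor BAL concentrations at the detection limits
#'
#' Values above an analyte's upper limit of detection are set to that limit
#' (the maximum detectable concentration); values below its lower limit are
#' set to the global imputation constant (half the lowest minimum detectable
#' concentration across all analytes). Everything in between is unchanged.
#'
#' @param raw a raw-scale BAL [proteomic_matrix].
#' @param lod a [lod_spec()] covering every analyte in `raw`.
#' @return A list: `matrix` (censored [proteomic_matrix]) and `flags`
#'   (character matrix, `"ok"`, `"below_llod"` or `"above_ulod"` per cell).
#' @export
censor_bal_lod <- function(raw, lod) {
  stopifnot_pm(raw, scale = "raw")
  missing <- setdiff(colnames(raw$values), lod$analyte)
  if (length(missing)) {
    stop("configuration error: analytes missing from LOD spec: ",
         paste(missing, collapse = ", "))
  }
  idx <- match(colnames(raw$values), lod$analyte)
  llod <- lod$llod[idx]
  ulod <- lod$ulod[idx]
  impute <- attr(lod, "imputation_constant")
  v <- raw$values
  below <- sweep(v, 2, llod, "<")
  above <- sweep(v, 2, ulod, ">")
  v[below] <- impute
  v <- pmin(v, matrix(ulod, nrow(v), ncol(v), byrow = TRUE))
  flags <- matrix("ok", nrow(v), ncol(v), dimnames = dimnames(v))
  flags[below] <- "below_llod"
  flags[above] <- "above_ulod"
  list(
    matrix = proteomic_matrix(v, raw$compartment, "raw"),
    flags = flags
  )
}

#' Remove BAL analytes mostly below the detection limit
#'
#' Drops every analyte for which at least 50% of measurements across all
#' samples fall below its LLOD (the rule is `>=`, so an analyte with exactly
#' half its values censored is removed). Survivor column order is preserved.
#'
#' @param censored a BAL [proteomic_matrix] as returned by [censor_bal_lod()].
#' @param flags the matching censoring-flag matrix.
#' @return The filtered [proteomic_matrix], with attribute `"removed"` naming
#'   the dropped analytes.
#' @export
filter_bal_analytes <- function(censored, flags) {
  stopifnot_pm(censored)
  if (ncol(censored$values) == 0) stop("empty matrix")
  if (!identical(dim(flags), dim(censored$values))) {
    stop("flags not aligned with matrix")
  }
  frac_below <- colMeans(flags == "below_llod")
  drop <- frac_below >= 0.5
  if (all(drop)) {
    warning("all BAL analytes fail the 50%-below-LLOD rule; returning empty panel")
  }
  keep <- which(!drop)
  out <- proteomic_matrix(
    censored$values[, keep, drop = FALSE],
    censored$compartment[keep],
    censored$scale
  )
  attr(out, "removed") <- colnames(censored$values)[drop]
  out
}

#' Total-protein normalization and log2 transform
#'
#' Divides each BAL measurement by its sample's total BAL protein, then
#' log2-transforms every analyte (blood and BAL) for normality.
#'
#' @param bal raw-scale BAL [proteomic_matrix] (post LOD handling).
#' @param totals named per-sample total protein, strictly positive, covering
#'   all BAL samples.
#' @param blood raw-scale blood [proteomic_matrix] (or `NULL` to process BAL
#'   alone).
#' @return A list with log-scale `blood` and `bal` matrices.
#' @export
normalize_and_log <- function(bal, totals, blood = NULL) {
  stopifnot_pm(bal, scale = "raw")
  samp <- rownames(bal$values)
  if (!all(samp %in% names(totals))) {
    stop("total protein missing for samples: ",
         paste(setdiff(samp, names(totals)), collapse = ", "))
  }
  tot <- totals[samp]
  if (any(tot <= 0)) {
    stop("nonpositive total protein for samples: ",
         paste(samp[tot <= 0], collapse = ", "))
  }
  norm <- sweep(bal$values, 1, tot, "/")
  log_pm <- function(v, compartment) {
    if (any(v <= 0)) stop("nonpositive concentration at log step")
    proteomic_matrix(log2(v), compartment, "log")
  }
  out <- list(bal = log_pm(norm, bal$compartment))
  if (!is.null(blood)) {
    stopifnot_pm(blood, scale = "raw")
    out$blood <- log_pm(blood$values, blood$compartment)
  }
  out
}

#' Remove analytes associated with sex
#'
#' Runs a two-tailed two-sample t-test by sex on every analyte (log scale),
#' adjusts across all tested analytes by Benjamini-Hochberg, and removes
#' analytes with adjusted p below `alpha`.
#'
#' @param matrix a log-scale [proteomic_matrix].
#' @param sex per-sample labels (two levels, e.g. male/female), aligned with
#'   the matrix rows.
#' @param alpha FDR level, default 0.05.
#' @param variant t-test variant, `"pooled"` (default) or `"welch"`.
#' @return A list: `filtered` matrix, `removed` analyte ids, and the
#'   per-analyte `tests` table (t, p_raw, p_adj).
#' @export
sex_association_filter <- function(matrix, sex, alpha = 0.05,
                                   variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot_pm(matrix, scale = "log")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  sex <- as.character(sex)
  lev <- unique(sex)
  if (length(lev) != 2) stop("both sexes must be present")
  a <- sex == lev[1]
  res <- apply(matrix$values, 2, function(col) {
    unlist(two_sample_ttest(col[a], col[!a], variant = variant))
  })
  tests <- data.frame(
    analyte = colnames(matrix$values),
    t = res["t", ],
    p_raw = res["p", ],
    stringsAsFactors = FALSE
  )
  tests$p_adj <- bh_adjust(tests$p_raw)
  removed <- tests$analyte[tests$p_adj < alpha]
  keep <- setdiff(colnames(matrix$values), removed)
  list(
    filtered = pm_select(matrix, keep),
    removed = removed,
    tests = tests
  )
}

#' Merge blood and BAL panels into one multi-compartment matrix
#'
#' Column-concatenates the two compartments over the shared sample set,
#' prefixing analyte ids with `blood:` / `bal:` so an analyte measured in both
#' compartments remains two distinct features.
#'
#' @param blood,bal log-scale [proteomic_matrix] objects over the same
#'   samples (order reconciled by sample id). `bal` may have zero columns.
#' @return The merged [proteomic_matrix].
#' @export
merge_compartments <- function(blood, bal) {
  stopifnot_pm(blood)
  stopifnot_pm(bal)
  if (blood$scale != bal$scale) stop("compartments on different scales")
  sb <- rownames(blood$values)
  sl <- rownames(bal$values)
  if (!setequal(sb, sl)) {
    stop("sample mismatch between compartments: ",
         paste(c(setdiff(sb, sl), setdiff(sl, sb)), collapse = ", "))
  }
  bl <- blood$values
  ba <- bal$values[sb, , drop = FALSE]
  colnames(bl) <- paste0("blood:", colnames(bl))
  if (ncol(ba)) colnames(ba) <- paste0("bal:", colnames(ba))
  merged <- cbind(bl, ba)
  proteomic_matrix(
    merged,
    rep(c("blood", "bal"), c(ncol(bl), ncol(ba))),
    blood$scale
  )
}
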