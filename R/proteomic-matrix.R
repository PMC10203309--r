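#' Samples-by-analytes concentration matrix with compartment tags
#'
#' Lightweight S3 container for a proteomic panel: a numeric matrix (rows =
#' samples, columns = analytes), a per-analyte compartment tag (`"blood"` or
#' `"bal"`), and a scale flag (`"raw"` concentrations or `"log"`, i.e. log2).
#'
#' @param values numeric matrix, samples x analytes, with dimnames.
#' @param compartment character scalar or per-analyte vector, `"blood"`/`"bal"`.
#' @param scale `"raw"` or `"log"`.
#' @return An object of class `proteomic_matrix` with elements `values`,
#'   `compartment` (named per analyte) and `scale`.
#' @export
proteomic_matrix <- function(values, compartment, scale = c("raw", "log")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(colnames(values)) && ncol(values) > 0) {
    stop("`values` must have analyte column names")
  }
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("S", seq_len(nrow(values)))
  }
  if (length(compartment) == 1L) {
    compartment <- rep(compartment, ncol(values))
  }
  if (length(compartment) != ncol(values)) {
    stop("`compartment` must be length 1 or one entry per analyte")
  }
  if (!all(compartment %in% c("blood", "bal"))) {
    stop("compartment tags must be 'blood' or 'bal'")
  }
  names(compartment) <- colnames(values)
  structure(
    list(values = values, compartment = compartment, scale = scale),
    class = "proteomic_matrix"
  )
}

#' @export
print.proteomic_matrix <- function(x, ...) {
  cat(sprintf(
    "proteomic_matrix: %d samples x %d analytes (%s blood, %s bal), %s scale\n",
    nrow(x$values), ncol(x$values),
    sum(x$compartment == "blood"), sum(x$compartment == "bal"), x$scale
  ))
  invisible(x)
}

#' @export
dim.proteomic_matrix <- function(x) dim(x$values)

#' Number of samples / analytes in a proteomic matrix
#' @param pm a [proteomic_matrix].
#' @return Integer count.
#' @export
n_samples <- function(pm) nrow(pm$values)

#' @rdname n_samples
#' @export
n_analytes <- function(pm) ncol(pm$values)

#' Subset analytes of a proteomic matrix
#' @param pm a [proteomic_matrix].
#' @param analytes character vector of analyte ids or logical/integer index.
#' @return A [proteomic_matrix] restricted to the requested analytes.
#' @export
pm_select <- function(pm, analytes) {
  if (is.character(analytes)) {
    missing <- setdiff(analytes, colnames(pm$values))
    if (length(missing)) {
      stop("analytes not present: ", paste(missing, collapse = ", "))
    }
  }
  proteomic_matrix(
    pm$values[, analytes, drop = FALSE],
    pm$compartment[analytes],
    pm$scale
  )
}

stopifnot_pm <- function(pm, scale = NULL) {
  if (!inherits(pm, "proteomic_matrix")) {
    stop("expected a proteomic_matrix")
  }
  if (!is.null(scale) && pm$scale != scale) {
    stop(sprintf("expected matrix on %s scale, got %s", scale, pm$scale))
  }
  invisible(pm)
}
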