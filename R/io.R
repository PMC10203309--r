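# Delimited-text formats: tab-separated; matrices carry a header row of
# compartment-prefixed analyte ids ("blood:PROT0001") and a first column of
# sample ids; participant tables use ISO-8601 dates.

#' Read / write a proteomic matrix as tab-separated text
#'
#' @param pm a [proteomic_matrix].
#' @param path file path.
#' @return `write_proteomic_matrix` invisibly returns `path`;
#'   `read_proteomic_matrix` returns the [proteomic_matrix].
#' @export
write_proteomic_matrix <- function(pm, path) {
  stopifnot_pm(pm)
  v <- pm$values
  unprefixed <- !grepl("^(blood|bal):", colnames(v))
  colnames(v)[unprefixed] <- paste0(
    pm$compartment[unprefixed], ":", colnames(v)[unprefixed]
  )
  df <- data.frame(sample = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# scale=", pm$scale), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_proteomic_matrix
#' @export
read_proteomic_matrix <- function(path) {
  first <- readLines(path, n = 1)
  scale <- sub("^# scale=", "", first)
  df <- utils::read.delim(path, skip = 1, check.names = FALSE,
                          stringsAsFactors = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df$sample
  comp <- sub(":.*$", "", colnames(v))
  plain <- sub("^(blood|bal):", "", colnames(v))
  # keep prefixed ids only when needed for uniqueness (i.e. post-merge)
  if (!anyDuplicated(plain) && length(unique(comp)) == 1) {
    colnames(v) <- plain
  }
  proteomic_matrix(v, comp, scale)
}

#' Read / write a participant table
#'
#' @param participants participant data frame.
#' @param path file path.
#' @return `write_participants` invisibly returns `path`;
#'   `read_participants` the data frame with typed date/logical columns.
#' @export
write_participants <- function(participants, path) {
  df <- participants
  df$v1_date <- as.character(df$v1_date)
  df$v5_date <- as.character(df$v5_date)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_participants
#' @export
read_participants <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$v1_date <- as.Date(df$v1_date)
  df$v5_date <- as.Date(df$v5_date)
  if ("ics_use" %in% names(df)) df$ics_use <- as.logical(df$ics_use)
  df
}

#' Read / write a detection-limit specification
#'
#' Three tab-separated columns: analyte, llod, ulod.
#'
#' @param lod a [lod_spec()].
#' @param path file path.
#' @return `write_lod_spec` invisibly returns `path`; `read_lod_spec` the
#'   [lod_spec()].
#' @export
write_lod_spec <- function(lod, path) {
  utils::write.table(as.data.frame(lod), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_lod_spec
#' @export
read_lod_spec <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  lod_spec(df$analyte, df$llod, df$ulod)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
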