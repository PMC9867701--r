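# Plain-text readers and writers for the pipeline's tabular interchange
# formats: count tables (rows = genes or genera, columns = samples), MSP
# definitions, and GMT-like pathway databases.

#' Read / write a count table (genes or genera x samples) as TSV
#'
#' First column holds the feature id, remaining columns are integer
#' counts per sample; sample names follow `<subject>_<M0|M4>` for paired
#' cohorts.
#'
#' @param x integer matrix with feature rownames and sample colnames.
#' @param path file path.
#' @return `read_count_table` returns an integer matrix.
#' @export
write_count_table <- function(x, path) {
  df <- data.frame(feature_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}

#' Read / write MSP definitions as TSV
#'
#' Columns `msp_id`, `gene_id`, `is_marker` (0/1).
#'
#' @param defs data.frame as above.
#' @param path file path.
#' @return `read_msp_definition` returns the data.frame.
#' @export
write_msp_definition <- function(defs, path) {
  utils::write.table(defs[, c("msp_id", "gene_id", "is_marker")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_msp_definition
#' @export
read_msp_definition <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Read / write a pathway database in GMT-like format
#'
#' One pathway per line: id, description, then tab-separated KO ids.
#'
#' @param db named list pathway -> KO character vector.
#' @param path file path.
#' @param descriptions optional named descriptions.
#' @return `read_gmt` returns the named list.
#' @export
write_gmt <- function(db, path, descriptions = NULL) {
  lines <- vapply(names(db), function(nm) {
    desc <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else "na"
    paste(c(nm, desc, db[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  db <- lapply(parts, function(p) p[-(1:2)])
  names(db) <- vapply(parts, `[[`, "", 1L)
  db
}

#' Write a differential-abundance or enrichment result as TSV
#'
#' @param df result data.frame.
#' @param path file path.
#' @export
write_result_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
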