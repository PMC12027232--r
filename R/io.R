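#' @name refstab-io
#' @title Delimited-text readers and writers
#' @description Readers and writers for the package's tables: TPM expression
#'   matrices, Cq matrices, sample annotations and ranking reports. All formats
#'   are plain delimited text (comma or tab); the delimiter is auto-detected
#'   from the header line and can be overridden. Numeric values are serialized
#'   at full double precision so write-then-read round-trips are exact.
NULL

detect_delim <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty input file: ", path)
  if (grepl("\t", header)) "\t" else ","
}

read_labelled_table <- function(path, delim, na_strings = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  delim <- detect_delim(path, delim)
  raw <- utils::read.table(path, sep = delim, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = na_strings, colClasses = "character",
                           quote = "\"", comment.char = "")
  if (nrow(raw) == 0L || ncol(raw) < 2L) stop("empty table body in ", path)
  raw
}

parse_numeric_body <- function(raw, row_labels, what, allow_na = FALSE) {
  body <- as.matrix(raw)
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- is.na(num) & !is.na(body)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop("non-numeric ", what, " value '", body[idx[1], idx[2]],
         "' at row ", row_labels[idx[1]], ", column ", colnames(raw)[idx[2]])
  }
  if (!allow_na && anyNA(num)) {
    idx <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop("missing ", what, " value at row ", row_labels[idx[1]],
         ", column ", colnames(raw)[idx[2]])
  }
  dimnames(num) <- list(row_labels, colnames(raw))
  num
}

orient_genes_in_rows <- function(mat, orientation) {
  orientation <- match.arg(orientation, c("genes_in_rows", "samples_in_rows"))
  if (orientation == "samples_in_rows") t(mat) else mat
}

#' Read a TPM expression table
#'
#' Reads a delimited text file whose first column holds labels and whose header
#' holds the other dimension's labels. Cells must be non-negative numbers;
#' negative or non-numeric cells raise an error naming the offending cell.
#'
#' @param path Path to a CSV/TSV file.
#' @param orientation `"genes_in_rows"` (default) or `"samples_in_rows"`.
#' @param annotation Optional [sample_annotation()] (or path to one readable by
#'   [read_sample_annotation()]) covering every sample.
#' @param delim Field delimiter; auto-detected between comma and tab when NULL.
#' @return An [expression_matrix()].
#' @seealso [write_expression_table()]
#' @export
read_expression_table <- function(path, orientation = "genes_in_rows",
                                  annotation = NULL, delim = NULL) {
  raw <- read_labelled_table(path, delim)
  labels <- check_labels(raw[[1]], if (identical(orientation, "samples_in_rows"))
    "sample" else "gene")
  mat <- parse_numeric_body(raw[, -1, drop = FALSE], labels, "TPM")
  mat <- orient_genes_in_rows(mat, orientation)
  check_labels(colnames(mat), "sample")
  if (is.character(annotation)) annotation <- read_sample_annotation(annotation)
  expression_matrix(mat, annotation = annotation)
}

#' Write a TPM expression table
#'
#' @param expr An [expression_matrix()].
#' @param path Output path.
#' @param delim Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(expr, path, delim = "\t") {
  write_matrix_tsv(expr$tpm, path, delim, label = "gene_id")
}

write_matrix_tsv <- function(mat, path, delim, label, extra_cols = NULL,
                             missing_token = "NA") {
  df <- data.frame(label = rownames(mat), stringsAsFactors = FALSE)
  names(df) <- label
  if (!is.null(extra_cols)) df <- cbind(df, extra_cols)
  chr <- matrix(ifelse(is.na(mat), missing_token, sprintf("%.15g", mat)),
                nrow = nrow(mat), dimnames = dimnames(mat))
  body <- as.data.frame(chr, stringsAsFactors = FALSE, optional = TRUE)
  df <- cbind(df, body)
  ok <- tryCatch({
    utils::write.table(df, path, sep = delim, quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write to ", path, ": ", conditionMessage(ok))
  invisible(path)
}

#' Read a Cq table
#'
#' Reads a gene-by-sample table of qPCR quantification cycles. Cells equal to
#' `missing_token` are flagged missing (stored as `NA`) and excluded pairwise
#' from downstream statistics; any other non-numeric cell is an error. A column
#' named `efficiency` (case-insensitive, genes-in-rows orientation only) is
#' stripped from the body and used as per-gene amplification efficiency, in
#' either base-E or percent convention ([normalize_efficiency()]); without such
#' a column every gene gets E = 2.
#'
#' @inheritParams read_expression_table
#' @param missing_token String marking a missing Cq cell (default `"NA"`).
#' @return A [cq_matrix()]. Genes whose every Cq is missing are retained with
#'   a warning.
#' @seealso [write_cq_table()]
#' @export
read_cq_table <- function(path, missing_token = "NA",
                          orientation = "genes_in_rows",
                          annotation = NULL, delim = NULL) {
  raw <- read_labelled_table(path, delim)
  labels <- check_labels(raw[[1]], if (identical(orientation, "samples_in_rows"))
    "sample" else "gene")
  body <- raw[, -1, drop = FALSE]
  efficiency <- 2
  eff_col <- which(tolower(colnames(body)) == "efficiency")
  if (length(eff_col) == 1L && identical(orientation, "genes_in_rows")) {
    efficiency <- stats::setNames(
      normalize_efficiency(as.numeric(body[[eff_col]])), labels)
    body <- body[, -eff_col, drop = FALSE]
  }
  body[] <- lapply(body, function(x) ifelse(x == missing_token, NA, x))
  mat <- parse_numeric_body(body, labels, "Cq", allow_na = TRUE)
  mat <- orient_genes_in_rows(mat, orientation)
  check_labels(colnames(mat), "sample")
  all_missing <- rownames(mat)[rowSums(!is.na(mat)) == 0L]
  if (length(all_missing) > 0L) {
    warning("gene(s) with all Cq values missing, retained: ",
            paste(all_missing, collapse = ", "))
  }
  if (is.character(annotation)) annotation <- read_sample_annotation(annotation)
  cq_matrix(mat, annotation = annotation, efficiency = efficiency)
}

#' Write a Cq table
#'
#' @param cq A [cq_matrix()].
#' @param path Output path.
#' @param delim Field delimiter (default tab).
#' @param missing_token Token written for flagged-missing cells.
#' @param include_efficiency Write the per-gene `efficiency` column (default:
#'   only when any efficiency differs from 2).
#' @return `path`, invisibly.
#' @export
write_cq_table <- function(cq, path, delim = "\t", missing_token = "NA",
                           include_efficiency = any(cq$efficiency != 2)) {
  extra <- NULL
  if (include_efficiency) {
    extra <- data.frame(efficiency = sprintf("%.15g", cq$efficiency),
                        stringsAsFactors = FALSE)
  }
  write_matrix_tsv(cq$cq, path, delim, label = "gene_id", extra_cols = extra,
                   missing_token = missing_token)
}

#' Read a sample annotation table
#'
#' Expects columns `sample_id` and any of `tissue`, `group`, `replicate`.
#'
#' @inheritParams read_expression_table
#' @return A [sample_annotation()].
#' @export
read_sample_annotation <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  delim <- detect_delim(path, delim)
  df <- utils::read.table(path, sep = delim, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("annotation needs a sample_id column")
  sample_annotation(
    df$sample_id,
    tissue = if ("tissue" %in% names(df)) df$tissue else NA_character_,
    group = if ("group" %in% names(df)) df$group else NA_character_,
    replicate = if ("replicate" %in% names(df)) df$replicate else NA_integer_
  )
}

#' Write a sample annotation table
#'
#' @param annotation A [sample_annotation()].
#' @param path Output path.
#' @param delim Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_sample_annotation <- function(annotation, path, delim = "\t") {
  utils::write.table(as.data.frame(annotation), path, sep = delim,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a stability ranking report
#'
#' Serializes a [comprehensive_ranking()] table (per-method scores and ranks,
#' comprehensive score, final rank) as delimited text with a stable column
#' order, one row per gene, ordered by ascending final rank. Re-reading with
#' [read_ranking_report()] reproduces the table.
#'
#' @param table A `stability_table` data frame from [comprehensive_ranking()]
#'   or [evaluate_stability()].
#' @param path Output path.
#' @param delim Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_ranking_report <- function(table, path, delim = "\t") {
  if (!is.data.frame(table) || nrow(table) == 0L) {
    stop("ranking table must be a nonempty data frame")
  }
  tab <- table[order(table$final_rank), , drop = FALSE]
  out <- tab
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x)
    ifelse(is.na(x), "NA", sprintf("%.15g", x)))
  ok <- tryCatch({
    utils::write.table(out, path, sep = delim, quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write to ", path, ": ", conditionMessage(ok))
  invisible(path)
}

#' Read a stability ranking report
#'
#' @inheritParams read_expression_table
#' @return A `stability_table` data frame.
#' @export
read_ranking_report <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  delim <- detect_delim(path, delim)
  df <- utils::read.table(path, sep = delim, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  class(df) <- c("stability_table", "data.frame")
  df
}
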