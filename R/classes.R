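#' Build a sample annotation table
#'
#' One row per sample, carrying the experimental design labels the rest of the
#' package keys on: tissue (for transcriptome screening) and physiological
#' group (for qPCR stability scoring, e.g. control / overmating-aging /
#' natural-aging).
#'
#' @param sample_id Character vector of unique sample labels.
#' @param tissue Tissue label per sample (recycled if length 1).
#' @param group Physiological-group label per sample (recycled if length 1).
#' @param replicate Positive integer replicate index (recycled if length 1).
#' @return A `data.frame` of class `sample_annotation` with columns
#'   `sample_id`, `tissue`, `group`, `replicate`.
#' @examples
#' sample_annotation(c("m1", "m2"), tissue = "muscle", group = "control",
#'                   replicate = 1:2)
#' @export
sample_annotation <- function(sample_id, tissue = NA_character_,
                              group = NA_character_, replicate = NA_integer_) {
  sample_id <- as.character(sample_id)
  if (length(sample_id) == 0L) stop("annotation needs at least one sample")
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample_id in annotation: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  }
  n <- length(sample_id)
  ann <- data.frame(
    sample_id = sample_id,
    tissue = rep_len(as.character(tissue), n),
    group = rep_len(as.character(group), n),
    replicate = rep_len(as.integer(replicate), n),
    stringsAsFactors = FALSE
  )
  if (any(!is.na(ann$replicate) & ann$replicate < 1L)) {
    stop("replicate indices must be positive")
  }
  class(ann) <- c("sample_annotation", "data.frame")
  ann
}

check_labels <- function(labels, what) {
  labels <- as.character(labels)
  if (length(labels) == 0L) stop("empty ", what, " label set")
  if (anyDuplicated(labels)) {
    stop("duplicate ", what, " labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  labels
}

match_annotation <- function(annotation, sample_ids) {
  if (is.null(annotation)) {
    return(sample_annotation(sample_ids))
  }
  if (!all(c("sample_id") %in% names(annotation))) {
    stop("annotation must contain a sample_id column")
  }
  missing <- setdiff(sample_ids, annotation$sample_id)
  if (length(missing) > 0L) {
    stop("samples without annotation record: ", paste(missing, collapse = ", "))
  }
  ann <- annotation[match(sample_ids, annotation$sample_id), , drop = FALSE]
  rownames(ann) <- NULL
  class(ann) <- unique(c("sample_annotation", class(ann)))
  ann
}

#' Construct an expression matrix of TPM values
#'
#' @param tpm Numeric matrix of non-negative TPM values, genes in rows and
#'   samples in columns; `dimnames` give the gene and sample labels.
#' @param annotation Optional [sample_annotation()] covering every column of
#'   `tpm`; a minimal one is built when omitted.
#' @return An object of class `expression_matrix`: a list with elements
#'   `tpm` (the validated matrix) and `annotation`.
#' @examples
#' m <- matrix(2^c(6, 7, 6.5, 7.5), 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' expression_matrix(m)
#' @export
expression_matrix <- function(tpm, annotation = NULL) {
  tpm <- as.matrix(tpm)
  storage.mode(tpm) <- "double"
  gene_ids <- check_labels(rownames(tpm), "gene")
  sample_ids <- check_labels(colnames(tpm), "sample")
  if (anyNA(tpm) || any(!is.finite(tpm))) {
    bad <- which(!is.finite(tpm), arr.ind = TRUE)[1, ]
    stop("non-finite TPM value at gene ", gene_ids[bad[1]],
         ", sample ", sample_ids[bad[2]])
  }
  if (any(tpm < 0)) {
    bad <- which(tpm < 0, arr.ind = TRUE)[1, ]
    stop("negative TPM value at gene ", gene_ids[bad[1]],
         ", sample ", sample_ids[bad[2]])
  }
  structure(
    list(tpm = tpm, annotation = match_annotation(annotation, sample_ids)),
    class = "expression_matrix"
  )
}

#' Convert amplification efficiency to base E
#'
#' qPCR efficiencies are reported either as the per-cycle amplification base E
#' (about 2) or as a percentage (about 100). Values above 10 are taken to be
#' percentages and mapped to `E = 1 + pct / 100`, so 104.0 becomes 2.04.
#'
#' @param e Numeric vector of efficiencies in either convention.
#' @return Numeric vector of base-E efficiencies, validated to lie in (1, 2.2].
#' @examples
#' normalize_efficiency(c(2, 104, 94))
#' @export
normalize_efficiency <- function(e) {
  e <- as.numeric(e)
  pct <- !is.na(e) & e > 10
  e[pct] <- 1 + e[pct] / 100
  if (any(!is.na(e) & (e <= 1 | e > 2.2))) {
    stop("amplification efficiency must lie in (1, 2.2] after conversion; got ",
         paste(signif(e[!is.na(e) & (e <= 1 | e > 2.2)], 4), collapse = ", "))
  }
  e
}

#' Construct a Cq (quantification cycle) matrix
#'
#' @param cq Numeric matrix of Cq values, genes in rows and samples in
#'   columns. `NA` entries are explicitly flagged missing values, excluded
#'   pairwise from the downstream statistics.
#' @param annotation Optional [sample_annotation()] covering every sample.
#' @param efficiency Per-gene amplification efficiency, either a scalar
#'   (recycled) or a vector named by gene. Accepted as base E (e.g. 2.04) or
#'   percent (e.g. 104); see [normalize_efficiency()]. Default 2 (100%).
#' @return An object of class `cq_matrix`: list with elements `cq`,
#'   `efficiency` (named per-gene base E) and `annotation`.
#' @examples
#' m <- matrix(c(21, 22, 24, 25, 21.5, 24.5), 2,
#'             dimnames = list(c("eif5a", "rps18"), c("s1", "s2", "s3")))
#' cq_matrix(m, efficiency = c(eif5a = 104, rps18 = 98))
#' @export
cq_matrix <- function(cq, annotation = NULL, efficiency = 2) {
  cq <- as.matrix(cq)
  storage.mode(cq) <- "double"
  gene_ids <- check_labels(rownames(cq), "gene")
  sample_ids <- check_labels(colnames(cq), "sample")
  if (any(is.nan(cq) | is.infinite(cq))) {
    bad <- which(is.nan(cq) | is.infinite(cq), arr.ind = TRUE)[1, ]
    stop("non-finite Cq value at gene ", gene_ids[bad[1]],
         ", sample ", sample_ids[bad[2]], " (use NA to flag missing)")
  }
  if (is.null(names(efficiency))) {
    efficiency <- stats::setNames(rep_len(efficiency, length(gene_ids)), gene_ids)
  } else {
    missing <- setdiff(gene_ids, names(efficiency))
    eff <- stats::setNames(rep(2, length(gene_ids)), gene_ids)
    eff[intersect(gene_ids, names(efficiency))] <-
      efficiency[intersect(gene_ids, names(efficiency))]
    if (length(missing) > 0L) eff[missing] <- 2
    efficiency <- eff
  }
  efficiency <- stats::setNames(normalize_efficiency(efficiency), gene_ids)
  structure(
    list(cq = cq, efficiency = efficiency,
         annotation = match_annotation(annotation, sample_ids)),
    class = "cq_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$tpm), "genes x", ncol(x$tpm), "samples\n")
  tis <- unique(stats::na.omit(x$annotation$tissue))
  if (length(tis) > 0) cat("tissues:", paste(tis, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.cq_matrix <- function(x, ...) {
  cat("cq_matrix:", nrow(x$cq), "genes x", ncol(x$cq), "samples\n")
  n_na <- sum(is.na(x$cq))
  if (n_na > 0) cat("flagged missing Cq values:", n_na, "\n")
  grp <- unique(stats::na.omit(x$annotation$group))
  if (length(grp) > 0) cat("groups:", paste(grp, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$tpm)

#' @export
dim.cq_matrix <- function(x) dim(x$cq)

gene_ids <- function(x) rownames(if (inherits(x, "cq_matrix")) x$cq else x$tpm)
sample_ids <- function(x) colnames(if (inherits(x, "cq_matrix")) x$cq else x$tpm)
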