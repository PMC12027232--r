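#' Per-sample reference Cq aggregate
#'
#' Combines one or more reference genes into a single per-sample reference Cq.
#' A single reference contributes its own Cq; several references contribute
#' the arithmetic mean of their Cq values, which (at E = 2) equals the log2 of
#' the geometric mean of their linear quantities — the multi-reference
#' normalization-factor convention.
#'
#' @param cq A [cq_matrix()].
#' @param reference_genes Nonempty character vector of gene ids present in
#'   `cq`.
#' @return Named numeric vector, one reference Cq per sample.
#' @export
reference_aggregate <- function(cq, reference_genes) {
  cq <- as_cq(cq)
  if (length(reference_genes) == 0L) {
    stop("at least one reference gene is required")
  }
  missing <- setdiff(reference_genes, rownames(cq$cq))
  if (length(missing) > 0L) {
    stop("reference gene(s) not in matrix: ", paste(missing, collapse = ", "))
  }
  colMeans(cq$cq[reference_genes, , drop = FALSE], na.rm = TRUE)
}

#' Relative quantification by 2^-ddCt
#'
#' Classic comparative-Ct normalization of a target gene against one or more
#' reference genes: per sample,
#' `dCt = Cq_target - reference aggregate`, `ddCt = dCt - baseline`, and
#' `fold_change = E^-ddCt` with E = 2 by default. The baseline is the mean
#' dCt over the calibrator samples — either a single sample id or a group
#' label from the annotation (in which case the group's arithmetic mean dCt
#' is the baseline, so the calibrator group's fold changes have geometric
#' mean 1).
#'
#' @param cq A [cq_matrix()].
#' @param target Target gene id (must not be among the references).
#' @param references Character vector of reference gene ids.
#' @param calibrator Sample id or group label to baseline against.
#' @param efficiency_corrected Use the target gene's stored amplification
#'   efficiency as the exponent base instead of 2 (default FALSE).
#' @return A data frame of class `normalization_result`: `sample_id`,
#'   `group`, `delta_ct`, `ddct`, `fold_change`; the target, references and
#'   calibrator are attached as attributes.
#' @references Livak & Schmittgen (2001) Methods 25:402-408.
#' @export
ddct <- function(cq, target, references, calibrator,
                 efficiency_corrected = FALSE) {
  cq <- as_cq(cq)
  m <- cq$cq
  if (!target %in% rownames(m)) stop("unknown target gene: ", target)
  if (target %in% references) {
    stop("target gene '", target, "' must not be among the references")
  }
  ref <- reference_aggregate(cq, references)
  dct <- m[target, ] - ref

  ann <- cq$annotation
  if (calibrator %in% ann$sample_id) {
    cal_samples <- calibrator
  } else if (calibrator %in% ann$group) {
    cal_samples <- ann$sample_id[!is.na(ann$group) & ann$group == calibrator]
  } else {
    stop("calibrator '", calibrator,
         "' is neither a sample id nor a group label")
  }
  baseline <- mean(dct[cal_samples], na.rm = TRUE)
  ddct_s <- dct - baseline
  base_e <- if (efficiency_corrected) cq$efficiency[target] else 2
  fold <- base_e^(-ddct_s)

  out <- data.frame(sample_id = colnames(m),
                    group = ann$group[match(colnames(m), ann$sample_id)],
                    delta_ct = unname(dct), ddct = unname(ddct_s),
                    fold_change = unname(fold), stringsAsFactors = FALSE)
  attr(out, "target") <- target
  attr(out, "references") <- references
  attr(out, "calibrator") <- calibrator
  attr(out, "efficiency_base") <- unname(base_e)
  class(out) <- c("normalization_result", "data.frame")
  out
}
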