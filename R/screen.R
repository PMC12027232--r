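#' Screening thresholds for candidate reference genes
#'
#' The transcriptome-wide screen keeps genes that are (I) detectable (TPM > 0)
#' in every sample of each required tissue, (II) stable across samples
#' (standard deviation of log2(TPM) below `sd_max`), (III) free of outlying
#' samples (every sample's |log2(TPM) - mean log2(TPM)| below `dev_max`), and
#' (IV) well expressed (mean log2(TPM) above `mean_min`). Survivors are then
#' shortlisted by coefficient of variation (`cv` = sd / mean of log2(TPM))
#' below `cv_max`.
#'
#' @param required_tissues Tissues in which criterion I demands detection.
#' @param sd_max Criterion II threshold on the log2(TPM) standard deviation.
#' @param dev_max Criterion III threshold on the max per-sample deviation from
#'   the gene's mean log2(TPM).
#' @param mean_min Criterion IV floor on mean log2(TPM).
#' @param cv_max Shortlist threshold on CV of log2(TPM).
#' @param mode `"sequential"` chains criteria I -> II -> III -> IV, each
#'   filtering the previous stage's survivors; `"per_stage"` evaluates II-IV
#'   independently on criterion I's survivors (stage counts need not be
#'   monotone) and keeps genes passing all four.
#' @param min_detect_fraction Fraction of samples per required tissue that must
#'   have TPM > 0 (default 1, i.e. every sample).
#' @return A list of class `screen_criteria`.
#' @export
screen_criteria <- function(required_tissues = c("muscle", "hepatopancreas",
                                                 "testis", "heart"),
                            sd_max = 1, dev_max = 2, mean_min = 5,
                            cv_max = 0.1,
                            mode = c("sequential", "per_stage"),
                            min_detect_fraction = 1) {
  mode <- match.arg(mode)
  stopifnot(sd_max > 0, dev_max > 0, mean_min > 0, cv_max > 0,
            min_detect_fraction > 0, min_detect_fraction <= 1)
  structure(list(required_tissues = as.character(required_tissues),
                 sd_max = sd_max, dev_max = dev_max, mean_min = mean_min,
                 cv_max = cv_max, mode = mode,
                 min_detect_fraction = min_detect_fraction),
            class = "screen_criteria")
}

#' Per-gene log2(TPM) summary statistics
#'
#' Mean, sample standard deviation (n - 1 denominator) and coefficient of
#' variation (sd / mean) of log2(TPM) across samples, the summaries used for
#' criteria II-IV and the CV shortlist. log2 is taken on raw TPM with no
#' pseudocount, so every selected gene must have TPM > 0 in all samples used.
#'
#' @param expr An [expression_matrix()].
#' @param genes Optional character vector restricting to a gene subset.
#' @param samples Optional character vector restricting to a sample subset.
#' @return A data frame with one row per gene: `gene_id`, `mean_log2tpm`,
#'   `sd_log2tpm`, `cv` (NA when the mean is not positive).
#' @examples
#' m <- matrix(2^c(5, 6, 7, 8), 1, dimnames = list("g", paste0("s", 1:4)))
#' gene_stats(expression_matrix(m))
#' @export
gene_stats <- function(expr, genes = NULL, samples = NULL) {
  tpm <- expr$tpm
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(tpm))
    if (length(missing) > 0L) stop("unknown gene(s): ",
                                   paste(missing, collapse = ", "))
    tpm <- tpm[genes, , drop = FALSE]
  }
  if (!is.null(samples)) tpm <- tpm[, samples, drop = FALSE]
  if (any(tpm <= 0)) {
    bad <- which(tpm <= 0, arr.ind = TRUE)[1, ]
    stop("log2(TPM) undefined: TPM <= 0 at gene ", rownames(tpm)[bad[1]],
         ", sample ", colnames(tpm)[bad[2]])
  }
  lt <- log2(tpm)
  mean_l <- rowMeans(lt)
  sd_l <- apply(lt, 1, stats::sd)
  data.frame(gene_id = rownames(tpm),
             mean_log2tpm = unname(mean_l),
             sd_log2tpm = unname(sd_l),
             cv = unname(ifelse(mean_l > 0, sd_l / mean_l, NA_real_)),
             stringsAsFactors = FALSE)
}

#' Apply the four-stage reference-gene screen
#'
#' Runs criteria I-IV of [screen_criteria()] over a TPM matrix and reports the
#' stage survivor counts, the survivor statistics and the CV shortlist.
#' Summary statistics are computed across the samples belonging to the
#' required tissues.
#'
#' @param expr An [expression_matrix()] whose annotation assigns every sample
#'   a tissue; each required tissue must have at least one sample.
#' @param criteria A [screen_criteria()].
#' @return A list of class `screen_result`: `total_genes`, `stage_counts`
#'   (named I-IV), `stage_percentages` (100 x count / total), `survivors`
#'   (gene ids passing all criteria), `stats` (a [gene_stats()] frame for
#'   criterion I survivors with per-criterion pass flags), `shortlist`
#'   (survivors with cv below `cv_max`, ascending cv) and `mode`.
#' @export
apply_criteria <- function(expr, criteria = screen_criteria()) {
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(criteria, "screen_criteria"))
  ann <- expr$annotation
  tissues <- criteria$required_tissues
  sample_sets <- lapply(tissues, function(t) ann$sample_id[!is.na(ann$tissue) &
                                                            ann$tissue == t])
  empty <- tissues[lengths(sample_sets) == 0L]
  if (length(empty) > 0L) {
    stop("required tissue(s) with zero samples: ", paste(empty, collapse = ", "))
  }
  tpm <- expr$tpm
  total <- nrow(tpm)

  pass1 <- rep(TRUE, total)
  for (s in sample_sets) {
    frac <- rowMeans(tpm[, s, drop = FALSE] > 0)
    pass1 <- pass1 & frac >= criteria$min_detect_fraction
  }
  names(pass1) <- rownames(tpm)
  used_samples <- unique(unlist(sample_sets))
  g1 <- rownames(tpm)[pass1]
  if (length(g1) == 0L) {
    stats_df <- data.frame(gene_id = character(), mean_log2tpm = numeric(),
                           sd_log2tpm = numeric(), cv = numeric())
  } else {
    stats_df <- gene_stats(expr, genes = g1, samples = used_samples)
    lt <- log2(tpm[g1, used_samples, drop = FALSE])
    stats_df$max_dev <- apply(abs(lt - rowMeans(lt)), 1, max)
  }

  pass2 <- stats_df$sd_log2tpm < criteria$sd_max
  pass3 <- stats_df$max_dev < criteria$dev_max
  pass4 <- stats_df$mean_log2tpm > criteria$mean_min

  if (criteria$mode == "sequential") {
    p2 <- pass2
    p3 <- p2 & pass3
    p4 <- p3 & pass4
    counts <- c(I = length(g1), II = sum(p2), III = sum(p3), IV = sum(p4))
    survivors <- stats_df$gene_id[p4]
  } else {
    counts <- c(I = length(g1), II = sum(pass2), III = sum(pass3),
                IV = sum(pass4))
    survivors <- stats_df$gene_id[pass2 & pass3 & pass4]
  }
  stats_df$pass_detectable <- TRUE
  stats_df$pass_sd <- pass2
  stats_df$pass_dev <- pass3
  stats_df$pass_mean <- pass4

  surv_stats <- stats_df[stats_df$gene_id %in% survivors, , drop = FALSE]
  shortlist <- shortlist_by_cv(surv_stats, criteria$cv_max)

  structure(list(total_genes = total, stage_counts = counts,
                 stage_percentages = stage_percentages(counts, total,
                                                       digits = NA),
                 survivors = survivors, stats = stats_df,
                 shortlist = shortlist, mode = criteria$mode,
                 criteria = criteria),
            class = "screen_result")
}

#' Stage survivor percentages
#'
#' Converts per-criterion survivor counts into percentages of the screened
#' gene total, as printed in screening reports (2 decimals by default).
#'
#' @param stage_counts Numeric vector of survivor counts per criterion.
#' @param total_genes Total number of genes screened.
#' @param digits Decimal places for rounding; `NA` for no rounding.
#' @return Numeric vector, `100 * stage_counts / total_genes`.
#' @examples
#' stage_percentages(c(7598, 776, 320, 328), 43155)
#' @export
stage_percentages <- function(stage_counts, total_genes, digits = 2) {
  stopifnot(total_genes > 0, all(stage_counts >= 0))
  pct <- 100 * stage_counts / total_genes
  if (!is.na(digits)) pct <- round(pct, digits)
  pct
}

#' Shortlist genes by coefficient of variation
#'
#' @param stats A data frame with columns `gene_id` and `cv`, e.g. from
#'   [gene_stats()].
#' @param cv_max Retain genes with `cv < cv_max`.
#' @return Character vector of gene ids ordered by ascending cv, ties broken
#'   lexicographically. An empty shortlist is a valid result.
#' @export
shortlist_by_cv <- function(stats, cv_max = 0.1) {
  stopifnot(is.data.frame(stats), all(c("gene_id", "cv") %in% names(stats)))
  keep <- stats[!is.na(stats$cv) & stats$cv < cv_max, , drop = FALSE]
  keep$gene_id[order(keep$cv, keep$gene_id)]
}

#' @export
print.screen_result <- function(x, ...) {
  cat("reference-gene screen (", x$mode, " mode): ", x$total_genes,
      " genes\n", sep = "")
  pct <- stage_percentages(x$stage_counts, x$total_genes)
  for (i in seq_along(x$stage_counts)) {
    cat(sprintf("  criterion %-3s %6d (%.2f%%)\n", names(x$stage_counts)[i],
                x$stage_counts[i], pct[i]))
  }
  cat("shortlist (cv < ", x$criteria$cv_max, "): ",
      length(x$shortlist), " genes\n", sep = "")
  invisible(x)
}

#' Write a screening report
#'
#' One row per criterion-I survivor with its log2(TPM) summaries (rounded as
#' in the published convention: means/sds 2 decimals, cv 3), pass flags and
#' shortlist membership.
#'
#' @param result A [apply_criteria()] result.
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_screen_report <- function(result, path, delim = "\t") {
  stopifnot(inherits(result, "screen_result"))
  df <- result$stats
  df$mean_log2tpm <- round(df$mean_log2tpm, 2)
  df$sd_log2tpm <- round(df$sd_log2tpm, 2)
  df$max_dev <- round(df$max_dev, 2)
  df$cv <- round(df$cv, 3)
  df$shortlisted <- df$gene_id %in% result$shortlist
  utils::write.table(df, path, sep = delim, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Published candidate-gene screening summaries
#'
#' Loads the bundled log2(TPM) summary table (mean, standard deviation and
#' printed CV) for the twelve reference-gene candidates evaluated in male
#' *Macrobrachium rosenbergii* across 36 RNA-seq libraries: nine
#' transcriptome-derived candidates plus the three conventional reference
#' genes (*eef1a*, *actb*, *gapdh*).
#'
#' @return A data frame with columns `gene_id`, `description`,
#'   `mean_log2tpm`, `sd_log2tpm`, `cv_printed` and `candidate` (FALSE for the
#'   three literature genes).
#' @examples
#' stats <- candidate_gene_stats()
#' shortlist_by_cv(transform(stats, cv = sd_log2tpm / mean_log2tpm), 0.1)
#' @export
candidate_gene_stats <- function() {
  path <- system.file("extdata", "mrosenbergii_candidate_stats.tsv",
                      package = "refstab", mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
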