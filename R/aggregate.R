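#' Average-tie ranks from stability scores
#'
#' Ascending scores map to ranks 1..G; exact ties receive the average of the
#' positions they span, so the rank sum always equals G(G+1)/2.
#'
#' @param scores Named numeric vector of finite stability scores (lower =
#'   more stable).
#' @return Named numeric rank vector.
#' @examples
#' ranks_from_scores(c(a = 0.2, b = 0.2, c = 0.9))
#' @export
ranks_from_scores <- function(scores) {
  if (any(!is.finite(scores))) {
    stop("non-finite score for gene(s): ",
         paste(names(scores)[!is.finite(scores)], collapse = ", "))
  }
  rank(scores, ties.method = "average")
}

#' Comprehensive geometric-mean ranking
#'
#' RefFinder-style aggregation: each gene's comprehensive score is the
#' unweighted geometric mean of its per-method ranks; genes are ordered by
#' ascending comprehensive score, ties broken by comparative delta-Ct rank
#' (when that method is present) and then lexicographically by gene id.
#'
#' @param rankings Named list (one element per method) of named rank vectors
#'   over an identical gene set, e.g. from [ranks_from_scores()] and
#'   [genorm_ranks()]. At least 2 methods.
#' @param scores Optional named list of named score vectors, included in the
#'   output as `<method>_score` columns.
#' @return A data frame of class `stability_table`, sorted by `final_rank`:
#'   `gene_id`, per-method score and rank columns, `comprehensive_score`,
#'   `final_rank` (1..G, distinct integers).
#' @examples
#' r <- list(delta_ct = c(a = 1, b = 2, c = 3), genorm = c(a = 2, b = 1, c = 3))
#' comprehensive_ranking(r)
#' @export
comprehensive_ranking <- function(rankings, scores = NULL) {
  stopifnot(is.list(rankings), length(rankings) >= 2L)
  genes <- sort(names(rankings[[1]]))
  for (m in names(rankings)) {
    if (!identical(sort(names(rankings[[m]])), genes)) {
      stop("method '", m, "' ranks a different gene set")
    }
  }
  rank_mat <- vapply(rankings, function(r) r[genes], numeric(length(genes)))
  if (is.null(dim(rank_mat))) rank_mat <- matrix(rank_mat, nrow = 1,
                                                 dimnames = list(genes,
                                                                 names(rankings)))
  comp <- exp(rowMeans(log(rank_mat)))

  tie_key <- if ("delta_ct" %in% names(rankings)) {
    rank_mat[, "delta_ct"]
  } else {
    rep(0, length(genes))
  }
  ord <- order(comp, tie_key, genes)

  tab <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (m in names(rankings)) {
    if (!is.null(scores) && m %in% names(scores)) {
      tab[[paste0(m, "_score")]] <- unname(scores[[m]][genes])
    }
    tab[[paste0(m, "_rank")]] <- unname(rank_mat[, m])
  }
  tab$comprehensive_score <- unname(comp)
  tab <- tab[ord, , drop = FALSE]
  tab$final_rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  class(tab) <- c("stability_table", "data.frame")
  tab
}

#' @export
print.stability_table <- function(x, ...) {
  cat("comprehensive stability ranking (", nrow(x), " genes)\n", sep = "")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, 4))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Compare final ranks across experimental conditions
#'
#' Lays out per-condition final ranks side by side for genes evaluated under
#' several condition sets (different tissues, developmental stages, stress
#' treatments), with a mean-rank summary over the conditions in which each
#' gene was evaluated. Gene/condition pairs missing from a condition's panel
#' are flagged `NA` and excluded from that gene's mean.
#'
#' @param tables Named list of `stability_table` objects, one per condition.
#' @return A data frame: `gene_id`, one final-rank column per condition,
#'   `mean_rank`, `n_conditions`; sorted by ascending `mean_rank`.
#' @export
rank_across_conditions <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1L)
  if (is.null(names(tables)) || any(names(tables) == "")) {
    names(tables) <- paste0("condition_", seq_along(tables))
  }
  genes <- sort(unique(unlist(lapply(tables, function(t) t$gene_id))))
  wide <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (cond in names(tables)) {
    t <- tables[[cond]]
    wide[[cond]] <- t$final_rank[match(genes, t$gene_id)]
  }
  rank_cols <- as.matrix(wide[, names(tables), drop = FALSE])
  wide$mean_rank <- rowMeans(rank_cols, na.rm = TRUE)
  wide$n_conditions <- rowSums(!is.na(rank_cols))
  wide <- wide[order(wide$mean_rank, wide$gene_id), , drop = FALSE]
  rownames(wide) <- NULL
  wide
}
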