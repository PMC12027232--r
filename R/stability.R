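#' @name refstab-stability
#' @title Reference-gene stability statistics
#' @description Four statistics score how stably each candidate gene is
#'   expressed across a panel of qPCR samples; lower is always more stable.
#'   The comparative delta-Ct method scores a gene by the mean, over all other
#'   candidates, of the sample-to-sample standard deviation of their Cq
#'   difference (cycles). geNorm works on relative quantities
#'   `Q = E^(minCq - Cq)` and scores a gene by its M-value, the mean SD of its
#'   pairwise log2 expression ratios, with iterative exclusion of the least
#'   stable gene and a pairwise-variation series `V(n/n+1)` that gauges how
#'   many reference genes suffice. BestKeeper summarizes each gene's raw Cq
#'   dispersion (mean absolute deviation, cycles) along with its correlation
#'   to the BestKeeper index (per-sample geometric mean Cq). NormFinder
#'   removes per-sample RNA-load effects and combines each gene's intergroup
#'   shift with its within-group variability into a stability value (cycles).
#'   Missing Cq values are excluded pairwise/groupwise; statistics based on
#'   fewer than 3 values are flagged unreliable in the diagnostics.
NULL

as_cq <- function(cq) {
  if (inherits(cq, "cq_matrix")) return(cq)
  if (is.matrix(cq)) return(cq_matrix(cq))
  stop("expected a cq_matrix (or a genes-by-samples matrix)")
}

method_scores <- function(method, scores, diagnostics = NULL) {
  df <- data.frame(gene_id = names(scores), score = unname(scores),
                   stringsAsFactors = FALSE)
  if (!is.null(diagnostics)) df <- cbind(df, diagnostics)
  attr(df, "method") <- method
  class(df) <- c("method_scores", "data.frame")
  df
}

# sample SD of the difference of two rows, pairwise complete
pair_sd <- function(x, y) {
  d <- x - y
  d <- d[!is.na(d)]
  if (length(d) < 2L) return(NA_real_)
  stats::sd(d)
}

pairwise_sd_matrix <- function(mat) {
  g <- nrow(mat)
  v <- matrix(NA_real_, g, g, dimnames = list(rownames(mat), rownames(mat)))
  for (j in seq_len(g)) {
    for (k in seq_len(g)) {
      if (k > j) v[j, k] <- v[k, j] <- pair_sd(mat[j, ], mat[k, ])
    }
  }
  v
}

#' Comparative delta-Ct stability
#'
#' For every ordered gene pair (j, k) the per-sample difference
#' `dCt = Cq_j - Cq_k` is formed; gene j's score is the mean over partners k
#' of the sample standard deviation of `dCt`, in cycles. Genes whose Cq
#' tracks all others (any shared per-sample effect cancels in the difference)
#' score near zero.
#'
#' @param cq A [cq_matrix()] (or plain genes-by-samples matrix) with at least
#'   2 genes and 3 samples.
#' @return A `method_scores` data frame: `gene_id`, `score` (mean pairwise SD,
#'   cycles), `n_unreliable_pairs` (partner pairs with fewer than 3 shared
#'   samples).
#' @references Silver et al. (2006) BMC Mol Biol 7:33.
#' @export
delta_ct_stability <- function(cq) {
  cq <- as_cq(cq)
  m <- cq$cq
  if (nrow(m) < 2L) stop("comparative delta-Ct needs at least 2 genes")
  if (ncol(m) < 3L) stop("comparative delta-Ct needs at least 3 samples")
  v <- pairwise_sd_matrix(m)
  if (any(is.na(v[upper.tri(v)]))) {
    stop("gene pair with no usable shared samples")
  }
  n_shared <- matrix(0L, nrow(m), nrow(m))
  for (j in seq_len(nrow(m))) {
    for (k in seq_len(nrow(m))) {
      n_shared[j, k] <- sum(!is.na(m[j, ]) & !is.na(m[k, ]))
    }
  }
  scores <- vapply(seq_len(nrow(m)),
                   function(j) mean(v[j, -j]), numeric(1))
  names(scores) <- rownames(m)
  unreliable <- vapply(seq_len(nrow(m)),
                       function(j) sum(n_shared[j, -j] < 3L), integer(1))
  method_scores("delta_ct", scores,
                data.frame(n_unreliable_pairs = unreliable))
}

# log2 relative quantities: Q = E^(minCq - Cq), max Q = 1 per gene
genorm_log_quantities <- function(cq) {
  m <- cq$cq
  e <- cq$efficiency[rownames(m)]
  mins <- apply(m, 1, min, na.rm = TRUE)
  (mins - m) * log2(e)
}

#' geNorm stability analysis
#'
#' Converts Cq to relative quantities `Q = E^(minCq - Cq)` (so the most
#' abundant sample of each gene has Q = 1), computes each gene's M-value (the
#' mean over partners of the sample SD of their pairwise log2 ratio), and
#' iteratively excludes the gene with the largest M until two genes — the best
#' pair — remain. The pairwise variation `V(n/n+1)` is the sample SD of
#' `log2(NF_n / NF_(n+1))`, where `NF_n` is the per-sample geometric mean of Q
#' over the n most stable genes; it gauges the benefit of adding an (n+1)-th
#' reference gene.
#'
#' Ties in the exclusion step are broken by removing the lexicographically
#' last gene id, for determinism.
#'
#' @param cq A [cq_matrix()] with at least 3 genes and 3 samples.
#' @return A list of class `genorm_result`: `m_values` (each gene's M at its
#'   exclusion step; the best pair share the final two-gene M),
#'   `m_initial` (full-panel M-values), `exclusion_order` (worst first),
#'   `best_pair`, `stability_order` (best first), `pairwise_variation`
#'   (named `V2/3`, `V3/4`, ...).
#' @references Vandesompele et al. (2002) Genome Biol 3:research0034.
#' @export
genorm <- function(cq) {
  cq <- as_cq(cq)
  m <- cq$cq
  if (nrow(m) < 3L) stop("geNorm needs at least 3 genes")
  if (ncol(m) < 3L) stop("geNorm needs at least 3 samples")
  logq <- genorm_log_quantities(cq)
  genes <- rownames(logq)

  m_of <- function(active) {
    v <- pairwise_sd_matrix(logq[active, , drop = FALSE])
    vapply(seq_along(active), function(j) mean(v[j, -j], na.rm = TRUE),
           numeric(1))
  }

  active <- genes
  excluded <- character(0)
  m_at_exclusion <- stats::setNames(numeric(length(genes)), genes)
  m_initial <- stats::setNames(m_of(genes), genes)
  while (length(active) > 2L) {
    mv <- stats::setNames(m_of(active), active)
    worst_m <- max(mv)
    worst <- max(active[mv == worst_m])  # lexicographic tie-break
    m_at_exclusion[worst] <- worst_m
    excluded <- c(excluded, worst)
    active <- setdiff(active, worst)
  }
  final_m <- m_of(active)
  m_at_exclusion[active] <- final_m
  pair <- active[order(m_initial[active], active)]

  stability_order <- c(pair, rev(excluded))
  nf <- vapply(seq_along(stability_order), function(n)
    colMeans(logq[stability_order[seq_len(n)], , drop = FALSE], na.rm = TRUE),
    numeric(ncol(logq)))
  if (is.null(dim(nf))) nf <- matrix(nf, nrow = 1)
  v_series <- vapply(2:(length(genes) - 1L), function(n)
    stats::sd(nf[, n] - nf[, n + 1L], na.rm = TRUE), numeric(1))
  names(v_series) <- paste0("V", 2:(length(genes) - 1L), "/",
                            3:length(genes))

  structure(list(m_values = m_at_exclusion, m_initial = m_initial,
                 exclusion_order = excluded, best_pair = pair,
                 stability_order = stability_order,
                 pairwise_variation = v_series),
            class = "genorm_result")
}

#' @export
print.genorm_result <- function(x, ...) {
  cat("geNorm: best pair", paste(x$best_pair, collapse = " + "),
      sprintf("(M = %.3f)\n", x$m_values[x$best_pair[1]]))
  cat("stability order:", paste(x$stability_order, collapse = " > "), "\n")
  cat("pairwise variation:\n")
  print(round(x$pairwise_variation, 4))
  invisible(x)
}

#' Ranks from a geNorm result
#'
#' The exclusion order read backwards gives the geNorm ranking; the jointly
#' best pair is assigned tied rank 1.5 each by default (preserving the
#' rank-sum invariant) or ranks 1 and 2 (ordered by full-panel M) with
#' `pair_rank = "split"`.
#'
#' @param result A [genorm()] result.
#' @param pair_rank `"tied"` (default) or `"split"`.
#' @return Named numeric rank vector over all genes.
#' @export
genorm_ranks <- function(result, pair_rank = c("tied", "split")) {
  pair_rank <- match.arg(pair_rank)
  ord <- result$stability_order
  ranks <- stats::setNames(seq_along(ord), ord)
  if (pair_rank == "tied") ranks[result$best_pair] <- 1.5
  ranks[names(result$m_values)]
}

#' Smallest sufficient number of reference genes
#'
#' Applies the conventional cutoff to the geNorm pairwise-variation series:
#' the smallest n with `V(n/n+1)` below `threshold` is the number of reference
#' genes deemed sufficient for normalization.
#'
#' @param result A [genorm()] result.
#' @param threshold Cutoff on V (default 0.15).
#' @return Integer n, or `NA_integer_` when no V falls below the threshold
#'   (flagged "none").
#' @export
pairwise_variation_cutoff <- function(result, threshold = 0.15) {
  v <- result$pairwise_variation
  ok <- which(v < threshold)
  if (length(ok) == 0L) return(NA_integer_)
  as.integer(ok[1] + 1L)
}

#' BestKeeper descriptive stability statistics
#'
#' Summarizes each gene's raw Cq variability: the primary score is the mean
#' absolute deviation (MAD) of Cq around its arithmetic mean, in cycles; the
#' coefficient of variation is `100 * MAD / mean Cq`. The BestKeeper index is
#' the per-sample geometric mean of all genes' Cq values, and each gene's
#' Pearson correlation with that index is reported as a diagnostic (undefined
#' — flagged `NA` — for a constant gene, whose dispersion score of 0 is
#' retained).
#'
#' @param cq A [cq_matrix()] with at least 2 genes and 3 samples.
#' @return A `method_scores` data frame with `score` (MAD, cycles), `mean_cq`,
#'   `sd_cq` (classical SD diagnostic), `cv_pct` and `r_index`; the index
#'   itself is attached as attribute `"index"` (named per-sample vector).
#' @references Pfaffl et al. (2004) Biotechnol Lett 26:509-515.
#' @export
bestkeeper <- function(cq) {
  cq <- as_cq(cq)
  m <- cq$cq
  if (nrow(m) < 2L) stop("BestKeeper needs at least 2 genes")
  if (ncol(m) < 3L) stop("BestKeeper needs at least 3 samples")
  mean_cq <- rowMeans(m, na.rm = TRUE)
  mad_cq <- rowMeans(abs(m - mean_cq), na.rm = TRUE)
  sd_cq <- apply(m, 1, stats::sd, na.rm = TRUE)
  cv_pct <- 100 * mad_cq / mean_cq
  index <- exp(colMeans(log(m), na.rm = TRUE))
  r_index <- vapply(seq_len(nrow(m)), function(j) {
    ok <- !is.na(m[j, ]) & !is.na(index)
    if (sum(ok) < 3L || stats::sd(m[j, ok]) == 0 || stats::sd(index[ok]) == 0)
      return(NA_real_)
    stats::cor(m[j, ok], index[ok])
  }, numeric(1))
  out <- method_scores("bestkeeper", stats::setNames(mad_cq, rownames(m)),
                       data.frame(mean_cq = unname(mean_cq),
                                  sd_cq = unname(sd_cq),
                                  cv_pct = unname(cv_pct),
                                  r_index = r_index))
  attr(out, "index") <- index
  out
}

#' NormFinder stability values
#'
#' Treats Cq as log2 abundance. Each sample is centered by its mean Cq across
#' genes, removing the shared RNA-load effect; per gene i and group g the
#' centered mean `m_ig` and sample variance `s2_ig` are formed. The intergroup
#' variation is `c_ig = m_ig - mean_g(m_ig)` and the stability value is
#'
#'   `rho_i = mean_g( |c_ig| + sqrt(s2_ig / n_g) )`
#'
#' in cycles, combining systematic between-group shifts with within-group
#' noise. With a single group, `rho_i` is simply the SD of the gene's centered
#' values. This is the direct (shrinkage-free) variance decomposition.
#'
#' @param cq A [cq_matrix()] with at least 3 genes; every group needs at least
#'   2 samples.
#' @param groups Group label per sample; defaults to the annotation's `group`
#'   column. A single shared label yields the single-group analysis.
#' @return A `method_scores` data frame with `score` (rho, cycles),
#'   `intergroup` (mean |c_ig|) and `intragroup` (mean sqrt(s2_ig / n_g)).
#' @references Andersen et al. (2004) Cancer Res 64:5245-5250.
#' @export
normfinder <- function(cq, groups = NULL) {
  cq <- as_cq(cq)
  m <- cq$cq
  if (nrow(m) < 3L) stop("NormFinder needs at least 3 genes")
  if (is.null(groups)) groups <- cq$annotation$group
  groups <- as.character(groups)
  if (length(groups) != ncol(m) || anyNA(groups)) {
    stop("need one group label per sample")
  }
  z <- sweep(m, 2, colMeans(m, na.rm = TRUE))
  levels <- unique(groups)
  sizes <- vapply(levels, function(g)
    min(rowSums(!is.na(z[, groups == g, drop = FALSE]))), numeric(1))
  if (any(sizes < 2)) {
    stop("group(s) with fewer than 2 usable samples: ",
         paste(levels[sizes < 2], collapse = ", "))
  }
  if (length(levels) == 1L) {
    rho <- apply(z, 1, stats::sd, na.rm = TRUE)
    return(method_scores("normfinder", stats::setNames(rho, rownames(m)),
                         data.frame(intergroup = 0,
                                    intragroup = unname(rho))))
  }
  mg <- sapply(levels, function(g)
    rowMeans(z[, groups == g, drop = FALSE], na.rm = TRUE))
  vg <- sapply(levels, function(g)
    apply(z[, groups == g, drop = FALSE], 1, stats::var, na.rm = TRUE))
  ng <- sapply(levels, function(g)
    rowSums(!is.na(z[, groups == g, drop = FALSE])))
  cg <- mg - rowMeans(mg)
  inter <- rowMeans(abs(cg))
  intra <- rowMeans(sqrt(vg / ng))
  rho <- inter + intra
  method_scores("normfinder", stats::setNames(rho, rownames(m)),
                data.frame(intergroup = unname(inter),
                           intragroup = unname(intra)))
}

#' Run all stability methods and rank comprehensively
#'
#' Convenience wrapper: runs the requested stability methods on one Cq matrix,
#' converts the scores to average-tie ranks (geNorm contributing its
#' exclusion-order ranking) and aggregates them into the comprehensive
#' geometric-mean ranking.
#'
#' @param cq A [cq_matrix()].
#' @param methods Subset of `c("delta_ct", "genorm", "bestkeeper",
#'   "normfinder")`.
#' @param groups Group labels for NormFinder (default: annotation `group`).
#' @param pair_rank geNorm best-pair rank policy, see [genorm_ranks()].
#' @return A `stability_table` (see [comprehensive_ranking()]) with the
#'   per-method results attached as attribute `"method_results"`.
#' @export
evaluate_stability <- function(cq, methods = c("delta_ct", "genorm",
                                               "bestkeeper", "normfinder"),
                               groups = NULL,
                               pair_rank = c("tied", "split")) {
  cq <- as_cq(cq)
  methods <- match.arg(methods, several.ok = TRUE)
  pair_rank <- match.arg(pair_rank)
  results <- list()
  rankings <- list()
  scores <- list()
  for (meth in methods) {
    if (meth == "delta_ct") {
      res <- delta_ct_stability(cq)
      scores$delta_ct <- stats::setNames(res$score, res$gene_id)
      rankings$delta_ct <- ranks_from_scores(scores$delta_ct)
    } else if (meth == "genorm") {
      res <- genorm(cq)
      scores$genorm <- res$m_values
      rankings$genorm <- genorm_ranks(res, pair_rank)
    } else if (meth == "bestkeeper") {
      res <- bestkeeper(cq)
      scores$bestkeeper <- stats::setNames(res$score, res$gene_id)
      rankings$bestkeeper <- ranks_from_scores(scores$bestkeeper)
    } else {
      res <- normfinder(cq, groups = groups)
      scores$normfinder <- stats::setNames(res$score, res$gene_id)
      rankings$normfinder <- ranks_from_scores(scores$normfinder)
    }
    results[[meth]] <- res
  }
  tab <- comprehensive_ranking(rankings, scores = scores)
  attr(tab, "method_results") <- results
  tab
}
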