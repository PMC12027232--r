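#' @name refstab-simulate
#' @title Synthetic TPM and Cq data with planted truth
#' @description Seeded generators that emulate the two data types the pipeline
#'   consumes: a multi-tissue RNA-seq TPM matrix containing housekeeping-like
#'   genes plus several classes of screening-criterion violators, and a
#'   grouped qPCR Cq matrix with planted stable and unstable genes, shared
#'   per-sample RNA-load offsets and per-group condition shifts. Every
#'   generated gene carries a truth record, so screening and ranking can be
#'   validated by parameter-recovery experiments. Each gene class draws from
#'   its own seeded sub-stream, so changing one class's gene count does not
#'   perturb another class's values.
NULL

derive_seed <- function(seed, offset) {
  as.integer((abs(as.numeric(seed)) * 48271 + offset * 9973) %% 2147483647)
}

# standard normal truncated at +/- bound sd
rnorm_trunc <- function(n, sd, bound = 3) {
  p <- stats::runif(n, stats::pnorm(-bound), stats::pnorm(bound))
  stats::qnorm(p) * sd
}

#' Configuration for the TPM matrix generator
#'
#' Defaults mirror a four-tissue, 36-library screening design. Gene classes:
#' `housekeeping` genes satisfy all four screening criteria by construction
#' when `hk_noise_sd <= 0.5` (their noise is truncated at 3 sigma, keeping
#' every per-sample deviation well below the criterion-III bound);
#' `tissue_variable` genes carry tissue effects standardized to
#' `tissue_effect_sd`, so their log2(TPM) SD structurally exceeds the
#' criterion-II bound; `low_expressed` genes sit below the criterion-IV mean
#' floor; `tissue_restricted` genes are zero in one tissue and fail
#' criterion I.
#'
#' @param n_housekeeping,n_tissue_variable,n_low_expressed,n_tissue_restricted
#'   Gene counts per class.
#' @param tissues Tissue labels.
#' @param samples_per_tissue Samples per tissue.
#' @param hk_mean_range Range of housekeeping base means, log2(TPM) scale.
#' @param hk_noise_sd Housekeeping noise SD, log2 units.
#' @param tissue_effect_sd Dispersion of tissue effects for variable genes,
#'   log2 units.
#' @param low_expr_mean_max Upper bound on low-expressed base means.
#' @param seed Integer seed; same config + seed gives bit-identical output.
#' @return A list of class `tpm_sim_config`.
#' @export
tpm_sim_config <- function(n_housekeeping = 20, n_tissue_variable = 40,
                           n_low_expressed = 20, n_tissue_restricted = 20,
                           tissues = c("muscle", "hepatopancreas", "testis",
                                       "heart"),
                           samples_per_tissue = 9,
                           hk_mean_range = c(5.5, 10), hk_noise_sd = 0.5,
                           tissue_effect_sd = 2, low_expr_mean_max = 4,
                           seed = 1) {
  stopifnot(n_housekeeping >= 0, n_tissue_variable >= 0, n_low_expressed >= 0,
            n_tissue_restricted >= 0, samples_per_tissue >= 1,
            hk_noise_sd >= 0, tissue_effect_sd >= 0,
            hk_mean_range[1] > 5, low_expr_mean_max < 5)
  structure(as.list(environment()), class = "tpm_sim_config")
}

#' Simulate a multi-tissue TPM expression matrix
#'
#' log2 expression is `base + tissue effect + noise` per class as described in
#' [tpm_sim_config()]; TPM is `2^value`, with tissue-restricted genes set to 0
#' in their designated tissue.
#'
#' @param config A [tpm_sim_config()].
#' @return A list with elements `expr` (an [expression_matrix()], annotation
#'   carrying tissue labels) and `truth` (data frame: `gene_id`, `class`,
#'   `base_log2`, `noise_sd`, `detail`).
#' @export
simulate_tpm <- function(config = tpm_sim_config()) {
  stopifnot(inherits(config, "tpm_sim_config"))
  tissues <- config$tissues
  n_t <- length(tissues)
  n_s <- n_t * config$samples_per_tissue
  tissue_of <- rep(tissues, each = config$samples_per_tissue)
  sample_id <- paste0(tissue_of, "_", rep(seq_len(config$samples_per_tissue),
                                          times = n_t))
  ann <- sample_annotation(sample_id, tissue = tissue_of, group = tissue_of,
                          replicate = rep(seq_len(config$samples_per_tissue),
                                          times = n_t))

  gen_class <- function(n, offset, fun) {
    if (n == 0L) return(NULL)
    set.seed(derive_seed(config$seed, offset))
    fun(n)
  }

  rows <- list()
  truth <- list()

  rows$hk <- gen_class(config$n_housekeeping, 1L, function(n) {
    base <- stats::runif(n, config$hk_mean_range[1], config$hk_mean_range[2])
    noise <- matrix(rnorm_trunc(n * n_s, config$hk_noise_sd), n, n_s)
    truth$hk <<- data.frame(gene_id = sprintf("hk_%03d", seq_len(n)),
                            class = "housekeeping", base_log2 = base,
                            noise_sd = config$hk_noise_sd, detail = "")
    out <- base + noise
    rownames(out) <- truth$hk$gene_id
    out
  })

  rows$tv <- gen_class(config$n_tissue_variable, 2L, function(n) {
    base <- stats::runif(n, config$hk_mean_range[1], config$hk_mean_range[2])
    # per-gene tissue effects, centered and standardized so the per-sample
    # effect vector has population SD exactly tissue_effect_sd
    eff <- t(vapply(seq_len(n), function(i) {
      e <- stats::rnorm(n_t)
      e_s <- e[match(tissue_of, tissues)]
      e_s <- e_s - mean(e_s)
      sd_pop <- sqrt(mean(e_s^2))
      if (sd_pop == 0) e_s else e_s * config$tissue_effect_sd / sd_pop
    }, numeric(n_s)))
    noise <- matrix(stats::rnorm(n * n_s, sd = config$hk_noise_sd), n, n_s)
    truth$tv <<- data.frame(gene_id = sprintf("tv_%03d", seq_len(n)),
                            class = "tissue_variable", base_log2 = base,
                            noise_sd = config$hk_noise_sd,
                            detail = sprintf("tissue_effect_sd=%g",
                                             config$tissue_effect_sd))
    out <- base + eff + noise
    rownames(out) <- truth$tv$gene_id
    out
  })

  rows$lo <- gen_class(config$n_low_expressed, 3L, function(n) {
    base <- stats::runif(n, max(0.5, config$low_expr_mean_max - 3),
                         config$low_expr_mean_max)
    noise <- matrix(rnorm_trunc(n * n_s, config$hk_noise_sd), n, n_s)
    truth$lo <<- data.frame(gene_id = sprintf("lo_%03d", seq_len(n)),
                            class = "low_expressed", base_log2 = base,
                            noise_sd = config$hk_noise_sd, detail = "")
    out <- base + noise
    rownames(out) <- truth$lo$gene_id
    out
  })

  restricted <- NULL
  rows$tr <- gen_class(config$n_tissue_restricted, 4L, function(n) {
    base <- stats::runif(n, config$hk_mean_range[1], config$hk_mean_range[2])
    noise <- matrix(rnorm_trunc(n * n_s, config$hk_noise_sd), n, n_s)
    restricted <<- sample(tissues, n, replace = TRUE)
    truth$tr <<- data.frame(gene_id = sprintf("tr_%03d", seq_len(n)),
                            class = "tissue_restricted", base_log2 = base,
                            noise_sd = config$hk_noise_sd,
                            detail = sprintf("zero_in=%s", restricted))
    out <- base + noise
    rownames(out) <- truth$tr$gene_id
    out
  })

  log2tpm <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  colnames(log2tpm) <- sample_id
  tpm <- 2^log2tpm
  if (!is.null(rows$tr)) {
    for (i in seq_along(restricted)) {
      tpm[rownames(rows$tr)[i], tissue_of == restricted[i]] <- 0
    }
  }
  truth_df <- do.call(rbind, truth[!vapply(truth, is.null, logical(1))])
  rownames(truth_df) <- NULL
  list(expr = expression_matrix(tpm, annotation = ann), truth = truth_df)
}

#' Configuration for the Cq matrix generator
#'
#' Defaults mirror a 12-gene, three-group qPCR validation panel with six
#' biological replicates per group. Stable genes vary only through the shared
#' per-sample RNA-load offset plus small noise; unstable genes add larger
#' noise and per-group condition shifts of 1-2 cycles.
#'
#' @param n_stable,n_unstable Gene counts per class.
#' @param groups Physiological-group labels.
#' @param samples_per_group Biological replicates per group.
#' @param base_cq_range Range of per-gene baseline Cq values, cycles.
#' @param load_sd SD of the shared per-sample RNA-load offset, cycles.
#' @param stable_noise_sd Per-measurement noise SD for stable genes, cycles.
#' @param unstable_noise_sd Noise SD for unstable genes, cycles.
#' @param shift_range Magnitude range of per-group shifts for unstable genes,
#'   cycles (sign random; the first group is the unshifted baseline).
#' @param seed Integer seed.
#' @return A list of class `cq_sim_config`.
#' @export
cq_sim_config <- function(n_stable = 6, n_unstable = 6,
                          groups = c("control", "overmating_aging",
                                     "natural_aging"),
                          samples_per_group = 6,
                          base_cq_range = c(20, 26), load_sd = 0.5,
                          stable_noise_sd = 0.15, unstable_noise_sd = 0.6,
                          shift_range = c(1, 2), seed = 1) {
  stopifnot(n_stable >= 0, n_unstable >= 0, samples_per_group >= 2,
            load_sd >= 0, stable_noise_sd >= 0, unstable_noise_sd >= 0,
            shift_range[1] <= shift_range[2], shift_range[1] >= 0)
  structure(as.list(environment()), class = "cq_sim_config")
}

#' Simulate a grouped qPCR Cq matrix
#'
#' `Cq_gs = base_g + load_s + shift_(g, group(s)) + noise_gs`: the load offset
#' is shared by every gene within a sample (and therefore cancels from all
#' load-invariant stability statistics), stable genes have zero shift and
#' small noise, unstable genes have per-group shifts and larger noise.
#'
#' @param config A [cq_sim_config()].
#' @return A list with `cq` (a [cq_matrix()], annotation carrying group
#'   labels) and `truth` (data frame: `gene_id`, `class`, `base_cq`,
#'   `noise_sd`, `shifts` as a comma-separated per-group string).
#' @export
simulate_cq <- function(config = cq_sim_config()) {
  stopifnot(inherits(config, "cq_sim_config"))
  groups <- config$groups
  n_g <- length(groups)
  n_s <- n_g * config$samples_per_group
  group_of <- rep(groups, each = config$samples_per_group)
  sample_id <- paste0(group_of, "_", rep(seq_len(config$samples_per_group),
                                         times = n_g))
  ann <- sample_annotation(sample_id, group = group_of,
                          replicate = rep(seq_len(config$samples_per_group),
                                          times = n_g))

  set.seed(derive_seed(config$seed, 10L))
  load <- stats::rnorm(n_s, sd = config$load_sd)

  rows <- list()
  truth <- list()

  if (config$n_stable > 0) {
    set.seed(derive_seed(config$seed, 11L))
    n <- config$n_stable
    base <- stats::runif(n, config$base_cq_range[1], config$base_cq_range[2])
    noise <- matrix(stats::rnorm(n * n_s, sd = config$stable_noise_sd), n, n_s)
    rows$stable <- base + noise
    rownames(rows$stable) <- sprintf("stable_%02d", seq_len(n))
    truth$stable <- data.frame(gene_id = rownames(rows$stable),
                               class = "stable", base_cq = base,
                               noise_sd = config$stable_noise_sd,
                               shifts = paste(rep(0, n_g), collapse = ","))
  }
  if (config$n_unstable > 0) {
    set.seed(derive_seed(config$seed, 12L))
    n <- config$n_unstable
    base <- stats::runif(n, config$base_cq_range[1], config$base_cq_range[2])
    # first group is baseline; other groups shift by +/- U(shift_range)
    shift <- matrix(0, n, n_g)
    if (n_g > 1) {
      mag <- matrix(stats::runif(n * (n_g - 1), config$shift_range[1],
                                 config$shift_range[2]), n, n_g - 1)
      sgn <- matrix(sample(c(-1, 1), n * (n_g - 1), replace = TRUE),
                    n, n_g - 1)
      shift[, -1] <- mag * sgn
    }
    noise <- matrix(stats::rnorm(n * n_s, sd = config$unstable_noise_sd),
                    n, n_s)
    rows$unstable <- base + shift[, match(group_of, groups), drop = FALSE] +
      noise
    rownames(rows$unstable) <- sprintf("unstable_%02d", seq_len(n))
    truth$unstable <- data.frame(gene_id = rownames(rows$unstable),
                                 class = "unstable", base_cq = base,
                                 noise_sd = config$unstable_noise_sd,
                                 shifts = apply(round(shift, 6), 1, paste,
                                                collapse = ","))
  }

  m <- do.call(rbind, rows)
  m <- sweep(m, 2, load, `+`)
  colnames(m) <- sample_id
  truth_df <- do.call(rbind, truth)
  rownames(truth_df) <- NULL
  list(cq = cq_matrix(m, annotation = ann), truth = truth_df)
}

#' Parameter-recovery experiment for the ranking pipeline
#'
#' Repeatedly simulates a Cq panel, runs the four stability methods and the
#' comprehensive ranking, and records how often the planted stable set is
#' recovered as the top-k (k = number of planted stable genes) — by the
#' comprehensive ranking and by each method alone.
#'
#' @param config A [cq_sim_config()]; replicate r uses seed `config$seed + r
#'   - 1`.
#' @param n_reps Number of simulation replicates (>= 1).
#' @param methods Stability methods to run (default all four).
#' @return A list of class `recovery_result`: `rate` (comprehensive recovery
#'   fraction), `per_method` (named vector), `n_reps`, `k`.
#' @export
recovery_experiment <- function(config = cq_sim_config(), n_reps = 100,
                                methods = c("delta_ct", "genorm",
                                            "bestkeeper", "normfinder")) {
  stopifnot(n_reps >= 1)
  k <- config$n_stable
  hits <- 0L
  method_hits <- stats::setNames(integer(length(methods)), methods)
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    sim <- simulate_cq(cfg)
    stable_set <- sort(sim$truth$gene_id[sim$truth$class == "stable"])
    tab <- evaluate_stability(sim$cq, methods = methods)
    top_k <- tab$gene_id[tab$final_rank <= k]
    if (identical(sort(top_k), stable_set)) hits <- hits + 1L
    for (m in methods) {
      rk <- tab[[paste0(m, "_rank")]]
      top_m <- tab$gene_id[order(rk)][seq_len(k)]
      if (identical(sort(top_m), stable_set)) {
        method_hits[m] <- method_hits[m] + 1L
      }
    }
  }
  structure(list(rate = hits / n_reps, per_method = method_hits / n_reps,
                 n_reps = n_reps, k = k),
            class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf("recovery of planted stable set as top-%d over %d reps\n",
              x$k, x$n_reps))
  cat(sprintf("  comprehensive: %.3f\n", x$rate))
  for (m in names(x$per_method)) {
    cat(sprintf("  %-13s %.3f\n", paste0(m, ":"), x$per_method[m]))
  }
  invisible(x)
}

#' Write a simulation truth table
#'
#' @param truth Truth data frame from [simulate_tpm()] or [simulate_cq()].
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_simulation_truth <- function(truth, path, delim = "\t") {
  utils::write.table(truth, path, sep = delim, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
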