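# Shared fixtures and independent oracle implementations.
# The oracles deliberately use naive explicit loops (not the package's
# internals) so that fixture comparisons are genuine dual-route checks.

label_matrix <- function(m, prefix = "g") {
  dimnames(m) <- list(paste0(prefix, seq_len(nrow(m))),
                      paste0("s", seq_len(ncol(m))))
  m
}

# frozen 4 genes x 6 samples Cq fixture (values drawn once)
frozen_cq_4x6 <- function() {
  m <- matrix(c(26.903, 22.434, 21.609, 24.681, 24.920, 26.542, 25.748,
                21.180, 24.632, 26.189, 21.139, 23.924, 20.171, 25.758,
                25.560, 26.798, 21.420, 24.885, 22.960, 20.920, 20.601,
                24.706, 21.072, 24.379), 4, 6)
  cq_matrix(label_matrix(m))
}

# frozen 5 genes x 9 samples Cq fixture
frozen_cq_5x9 <- function() {
  m <- matrix(c(20.585, 21.454, 20.766, 19.328, 20.888, 17.822, 21.850,
                19.932, 20.347, 18.829, 19.788, 19.759, 19.852, 21.085,
                18.215, 22.571, 17.712, 20.873, 17.910, 18.524, 21.732,
                20.526, 18.387, 21.349, 18.128, 18.354, 23.709, 18.951,
                19.689, 19.360, 22.523, 19.505, 18.607, 18.940, 22.130,
                19.600, 20.051, 20.088, 20.969, 19.718, 19.064, 20.266,
                22.235, 22.259, 19.717), 5, 9)
  cq_matrix(label_matrix(m))
}

# frozen 6 genes x 18 samples (3 groups x 6) Cq fixture
frozen_cq_6x18 <- function() {
  m <- matrix(c(21.782, 23.154, 21.859, 21.197, 22.333, 22.523, 22.574,
                20.954, 21.939, 22.166, 22.058, 22.729, 23.548, 22.987,
                21.225, 23.673, 22.389, 21.534, 22.093, 22.017, 21.888,
                22.133, 21.766, 21.657, 22.508, 21.111, 23.426, 22.611,
                21.143, 22.922, 20.866, 22.262, 20.037, 21.852, 21.830,
                21.823, 23.584, 21.797, 20.951, 22.073, 22.785, 21.637,
                22.577, 21.573, 21.882, 21.637, 20.747, 22.975, 22.276,
                22.725, 21.636, 21.036, 21.728, 22.364, 20.313, 21.591,
                22.815, 23.047, 22.481, 20.562, 22.568, 21.845, 22.342,
                21.017, 23.282, 22.759, 22.998, 22.815, 22.135, 21.541,
                21.023, 22.101, 21.982, 21.257, 20.780, 21.827, 21.435,
                19.901, 22.682, 21.255, 22.184, 21.916, 22.059, 22.138,
                21.999, 23.190, 20.180, 22.612, 21.440, 20.949, 22.047,
                20.623, 21.504, 21.142, 22.017, 22.843, 21.529, 21.658,
                22.253, 21.391, 21.477, 21.815, 21.205, 20.835, 21.620,
                21.401, 22.992, 21.476), 6, 18)
  m <- label_matrix(m)
  grp <- rep(c("a", "b", "c"), each = 6)
  ann <- sample_annotation(colnames(m), group = grp,
                          replicate = rep(1:6, 3))
  cq_matrix(m, annotation = ann)
}

random_cq <- function(n_genes, n_samples, sd = 1,
                      groups = NULL) {
  m <- label_matrix(matrix(stats::rnorm(n_genes * n_samples, 22, sd),
                           n_genes, n_samples))
  ann <- if (is.null(groups)) NULL else
    sample_annotation(colnames(m), group = groups)
  cq_matrix(m, annotation = ann)
}

# ---- independent oracles -------------------------------------------------

sd_naive <- function(x) {
  x <- x[!is.na(x)]
  mu <- sum(x) / length(x)
  sqrt(sum((x - mu)^2) / (length(x) - 1))
}

oracle_delta_ct <- function(m) {
  g <- nrow(m)
  out <- numeric(g)
  for (j in seq_len(g)) {
    sds <- c()
    for (k in seq_len(g)) {
      if (k != j) sds <- c(sds, sd_naive(m[j, ] - m[k, ]))
    }
    out[j] <- sum(sds) / length(sds)
  }
  names(out) <- rownames(m)
  out
}

# step-by-step geNorm recomputation: returns exclusion order with the M value
# at each exclusion, the final pair and its M
oracle_genorm <- function(m, e = rep(2, nrow(m))) {
  names(e) <- rownames(m)
  logq <- m
  for (g in rownames(m)) logq[g, ] <- (min(m[g, ]) - m[g, ]) * log2(e[g])
  m_values <- function(active) {
    sapply(active, function(j) {
      others <- setdiff(active, j)
      mean(sapply(others, function(k) sd_naive(logq[j, ] - logq[k, ])))
    })
  }
  active <- rownames(m)
  order_out <- character(0)
  m_out <- numeric(0)
  while (length(active) > 2) {
    mv <- m_values(active)
    worst <- names(mv)[mv == max(mv)]
    worst <- max(worst)
    order_out <- c(order_out, worst)
    m_out <- c(m_out, max(mv))
    active <- setdiff(active, worst)
  }
  list(exclusion_order = order_out, m_at_exclusion = m_out,
       pair = sort(active), pair_m = unname(m_values(active)[1]),
       logq = logq)
}

oracle_bestkeeper <- function(m) {
  g <- nrow(m)
  mad <- cv <- r <- numeric(g)
  index <- apply(m, 2, function(col) prod(col)^(1 / length(col)))
  for (j in seq_len(g)) {
    mu <- mean(m[j, ])
    mad[j] <- mean(abs(m[j, ] - mu))
    cv[j] <- 100 * mad[j] / mu
    r[j] <- stats::cor(m[j, ], index)
  }
  list(mad = stats::setNames(mad, rownames(m)), cv_pct = cv, r = r,
       index = index)
}

oracle_normfinder <- function(m, groups) {
  z <- m
  for (s in seq_len(ncol(m))) z[, s] <- m[, s] - mean(m[, s])
  lv <- unique(groups)
  rho <- numeric(nrow(m))
  for (j in seq_len(nrow(m))) {
    mg <- sapply(lv, function(g) mean(z[j, groups == g]))
    vg <- sapply(lv, function(g) sd_naive(z[j, groups == g])^2)
    ng <- sapply(lv, function(g) sum(groups == g))
    cg <- mg - mean(mg)
    rho[j] <- mean(abs(cg) + sqrt(vg / ng))
  }
  stats::setNames(rho, rownames(m))
}

oracle_geometric_mean_ranks <- function(rank_mat) {
  out <- numeric(nrow(rank_mat))
  for (i in seq_len(nrow(rank_mat))) {
    out[i] <- prod(rank_mat[i, ])^(1 / ncol(rank_mat))
  }
  stats::setNames(out, rownames(rank_mat))
}
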