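test_that("delta-Ct scores constant-difference and shifted genes correctly", {
  # two genes whose Cq differ by an exact constant: both scores 0
  m <- label_matrix(rbind(c(20, 21, 22, 23), c(23, 24, 25, 26)))
  sc <- delta_ct_stability(m)
  expect_equal(sc$score, c(0, 0))

  # adding a per-gene constant leaves all scores unchanged
  cqm <- frozen_cq_4x6()
  base <- delta_ct_stability(cqm)$score
  shifted <- cqm$cq
  shifted[2, ] <- shifted[2, ] + 3
  expect_equal(delta_ct_stability(cq_matrix(shifted))$score, base)

  expect_error(delta_ct_stability(label_matrix(matrix(1:4 + 0.1, 1, 4))),
               "2 genes")
})

test_that("delta-Ct matches the brute-force pairwise-SD oracle", {
  cqm <- frozen_cq_4x6()
  got <- delta_ct_stability(cqm)
  expect_equal(stats::setNames(got$score, got$gene_id),
               oracle_delta_ct(cqm$cq))
})

test_that("geNorm degenerates to zero on identical expression profiles", {
  m <- label_matrix(rbind(c(20, 21, 22, 23), c(20, 21, 22, 23),
                          c(20, 21, 22, 23)))
  res <- genorm(m)
  expect_equal(unname(res$m_values), rep(0, 3))
  expect_equal(unname(res$pairwise_variation), 0)
})

test_that("geNorm initial M equals delta-Ct scores when all E = 2", {
  set.seed(55)
  for (i in 1:20) {
    cqm <- random_cq(5, 8)
    dct <- delta_ct_stability(cqm)
    gn <- genorm(cqm)
    expect_equal(gn$m_initial[dct$gene_id],
                 stats::setNames(dct$score, dct$gene_id), tolerance = 1e-9)
  }
})

test_that("geNorm exclusion trajectory matches stepwise recomputation", {
  cqm <- frozen_cq_5x9()
  got <- genorm(cqm)
  want <- oracle_genorm(cqm$cq)
  expect_identical(got$exclusion_order, want$exclusion_order)
  expect_equal(unname(got$m_values[got$exclusion_order]),
               unname(want$m_at_exclusion))
  expect_identical(sort(got$best_pair), want$pair)
  expect_equal(unname(got$m_values[got$best_pair]), rep(want$pair_m, 2))

  # V series against direct NF recomputation from the oracle's quantities
  ord <- got$stability_order
  logq <- want$logq
  for (n in 2:(nrow(cqm$cq) - 1)) {
    nf_n <- colMeans(logq[ord[1:n], , drop = FALSE])
    nf_n1 <- colMeans(logq[ord[1:(n + 1)], , drop = FALSE])
    expect_equal(unname(got$pairwise_variation[n - 1]),
                 sd_naive(nf_n - nf_n1))
  }
})

test_that("geNorm with non-default efficiencies uses log-base E quantities", {
  cqm <- frozen_cq_4x6()
  eff <- c(g1 = 2.04, g2 = 1.94, g3 = 2.0, g4 = 1.98)
  cqe <- cq_matrix(cqm$cq, efficiency = eff)
  got <- genorm(cqe)
  want <- oracle_genorm(cqe$cq, e = eff)
  expect_identical(got$exclusion_order, want$exclusion_order)
  expect_equal(unname(got$m_values[got$exclusion_order]),
               unname(want$m_at_exclusion))
})

test_that("geNorm with 3 genes keeps the pair with smallest pairwise V", {
  set.seed(31)
  for (i in 1:25) {
    cqm <- random_cq(3, 7)
    res <- genorm(cqm)
    logq <- (apply(cqm$cq, 1, min) - cqm$cq)  # E = 2, log2E = 1
    pairs <- utils::combn(rownames(cqm$cq), 2, simplify = FALSE)
    v <- vapply(pairs, function(p) sd_naive(logq[p[1], ] - logq[p[2], ]),
                numeric(1))
    best <- sort(pairs[[which.min(v)]])
    expect_identical(sort(res$best_pair), best)
  }
})

test_that("BestKeeper statistics match direct computation", {
  cqm <- frozen_cq_4x6()
  got <- bestkeeper(cqm)
  want <- oracle_bestkeeper(cqm$cq)
  expect_equal(stats::setNames(got$score, got$gene_id), want$mad)
  expect_equal(got$cv_pct, want$cv_pct)
  expect_equal(got$r_index, want$r)
  expect_equal(unname(attr(got, "index")), unname(want$index))
})

test_that("BestKeeper flags a constant gene's correlation as undefined", {
  m <- frozen_cq_4x6()$cq
  m[1, ] <- 24
  got <- bestkeeper(cq_matrix(m))
  expect_equal(got$score[1], 0)
  expect_equal(got$cv_pct[1], 0)
  expect_true(is.na(got$r_index[1]))
  expect_false(anyNA(got$r_index[-1]))
})

test_that("NormFinder trivial cases follow the variance decomposition", {
  # centered values identical within and across groups: rho = 0
  m <- label_matrix(rbind(c(20, 21, 20, 21), c(22, 23, 22, 23),
                          c(24, 25, 24, 25)))
  ann <- sample_annotation(colnames(m), group = c("a", "a", "b", "b"))
  got <- normfinder(cq_matrix(m, annotation = ann))
  expect_equal(got$score, rep(0, 3))

  # centered group means differing by d with zero within-group variance:
  # rho = d/2 (c_ig = +/- d/2)
  d <- 1.2
  m2 <- label_matrix(rbind(c(20, 20, 20 + d, 20 + d),
                           c(22, 22, 22, 22),
                           c(24, 24, 24, 24)))
  # re-center contributions: sample means shift by d/3 in group b
  got2 <- normfinder(cq_matrix(m2, annotation = ann))
  want <- oracle_normfinder(m2, c("a", "a", "b", "b"))
  expect_equal(stats::setNames(got2$score, got2$gene_id), want)
  expect_equal(unname(got2$score[1]), (d - d / 3) / 2)

  expect_error(
    normfinder(cq_matrix(m, annotation = sample_annotation(
      colnames(m), group = c("a", "a", "a", "b")))),
    "fewer than 2")
})

test_that("NormFinder matches the oracle and flags the shifted gene worst", {
  cqm <- frozen_cq_6x18()
  got <- normfinder(cqm)
  want <- oracle_normfinder(cqm$cq, cqm$annotation$group)
  expect_equal(stats::setNames(got$score, got$gene_id), want)

  # plant a strong condition shift on gene 1: it must become the least stable
  m <- cqm$cq
  m["g1", cqm$annotation$group == "b"] <- m["g1", cqm$annotation$group == "b"] + 3
  shifted <- normfinder(cq_matrix(m, annotation = cqm$annotation))
  expect_equal(which.max(shifted$score), 1L)

  # single-group input reduces to the SD of centered values
  ann1 <- sample_annotation(colnames(cqm$cq), group = "all")
  g1 <- normfinder(cq_matrix(cqm$cq, annotation = ann1))
  z <- sweep(cqm$cq, 2, colMeans(cqm$cq))
  expect_equal(g1$score, unname(apply(z, 1, sd_naive)))
})

test_that("NormFinder rho rises with injected within-group noise", {
  sigmas <- c(0.1, 0.3, 0.6, 1.0)
  mean_rho <- vapply(seq_along(sigmas), function(i) {
    set.seed(1000 + i)
    rhos <- replicate(25, {
      m <- label_matrix(matrix(22 + rnorm(5 * 12, sd = sigmas[i]), 5, 12))
      ann <- sample_annotation(colnames(m), group = rep(c("a", "b"), each = 6))
      mean(normfinder(cq_matrix(m, annotation = ann))$score)
    })
    mean(rhos)
  }, numeric(1))
  expect_equal(cor(sigmas, mean_rho, method = "spearman"), 1)
})

test_that("pairwise-variation cutoff returns the smallest adequate n", {
  res <- list(pairwise_variation = c("V2/3" = 0.05, "V3/4" = 0.2))
  expect_identical(pairwise_variation_cutoff(res), 2L)
  res2 <- list(pairwise_variation = c("V2/3" = 0.3, "V3/4" = 0.12))
  expect_identical(pairwise_variation_cutoff(res2), 3L)
  res3 <- list(pairwise_variation = c("V2/3" = 0.3, "V3/4" = 0.31))
  expect_identical(pairwise_variation_cutoff(res3), NA_integer_)

  # a panel of 2 tight + 4 moderately noisy genes needs only the tight pair
  set.seed(77)
  tight <- matrix(22 + rnorm(2 * 10, sd = 0.05), 2, 10)
  noisy <- matrix(24 + rnorm(4 * 10, sd = 0.35), 4, 10)
  m <- label_matrix(rbind(tight, noisy))
  gn <- genorm(m)
  expect_identical(sort(gn$best_pair), c("g1", "g2"))
  expect_identical(pairwise_variation_cutoff(gn), 2L)
})

test_that("stability scores are invariant to per-sample and per-gene shifts", {
  cqm <- frozen_cq_6x18()
  ann <- cqm$annotation
  per_sample <- sweep(cqm$cq, 2, seq(-2, 2, length.out = 18), `+`)
  per_gene <- sweep(cqm$cq, 1, c(3, -1, 0, 2, 5, -2), `+`)

  base_d <- delta_ct_stability(cqm)$score
  base_g <- genorm(cqm)
  base_b <- bestkeeper(cqm)$score
  base_n <- normfinder(cqm)$score

  cs <- cq_matrix(per_sample, annotation = ann)
  expect_equal(delta_ct_stability(cs)$score, base_d)
  expect_equal(genorm(cs)$m_values, base_g$m_values)
  expect_equal(normfinder(cs)$score, base_n)

  cg <- cq_matrix(per_gene, annotation = ann)
  expect_equal(delta_ct_stability(cg)$score, base_d)
  expect_equal(genorm(cg)$m_values, base_g$m_values)
  expect_equal(normfinder(cg)$score, base_n)
  expect_equal(bestkeeper(cg)$score, base_b)
})

test_that("sample permutation preserves scores; gene permutation tracks them", {
  cqm <- frozen_cq_5x9()
  perm_s <- cq_matrix(cqm$cq[, c(5, 1, 9, 2, 8, 3, 7, 4, 6)])
  perm_g <- cq_matrix(cqm$cq[c(4, 2, 5, 1, 3), ])

  d0 <- delta_ct_stability(cqm)
  ds <- delta_ct_stability(perm_s)
  dg <- delta_ct_stability(perm_g)
  expect_equal(ds$score, d0$score)
  expect_equal(stats::setNames(dg$score, dg$gene_id)[d0$gene_id],
               stats::setNames(d0$score, d0$gene_id))

  b0 <- bestkeeper(cqm)
  bs <- bestkeeper(perm_s)
  expect_equal(bs$score, b0$score)
})
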