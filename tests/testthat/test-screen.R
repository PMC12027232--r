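test_that("gene_stats reproduces hand arithmetic and degenerate cases", {
  # log2(TPM) values {5, 6, 7, 8}: mean 6.5, sd sqrt(5/3), cv sd/mean
  m <- label_matrix(matrix(2^c(5, 6, 7, 8), 1, 4))
  st <- gene_stats(expression_matrix(m))
  expect_equal(st$mean_log2tpm, 6.5)
  expect_equal(st$sd_log2tpm, sqrt(5 / 3))
  expect_equal(st$cv, sqrt(5 / 3) / 6.5)

  # constant gene: zero variance, zero cv
  mc <- label_matrix(matrix(2^6, 1, 5))
  stc <- gene_stats(expression_matrix(mc))
  expect_equal(stc$mean_log2tpm, 6)
  expect_equal(stc$sd_log2tpm, 0)
  expect_equal(stc$cv, 0)

  # TPM <= 0 among selected genes names gene and sample
  mz <- label_matrix(matrix(c(4, 0, 2, 8), 2, 2))
  expect_error(gene_stats(expression_matrix(mz)), "g2.*s1")
})

test_that("the published (mean, sd) pairs reproduce the printed CV column", {
  tab <- candidate_gene_stats()
  cv <- round(tab$sd_log2tpm / tab$mean_log2tpm, 3)
  # eleven of the twelve rows agree exactly at 3-decimal rounding; the eif5a
  # row's printed CV (0.099) is internally inconsistent with its printed
  # mean/sd (0.60 / 6.02 = 0.0997 -> 0.100), plausibly computed from
  # unrounded summaries, and is the published table's own inconsistency
  other <- tab$gene_id != "eif5a"
  expect_equal(cv[other], tab$cv_printed[other])
  expect_equal(cv[!other], 0.100)
  expect_lte(max(abs(cv - tab$cv_printed)), 0.001 + 1e-12)
  # the rps2 row: mean 9.20, sd 0.57 -> cv 0.062
  rps2 <- tab[tab$gene_id == "rps2", ]
  expect_equal(round(rps2$sd_log2tpm / rps2$mean_log2tpm, 3), 0.062)
})

test_that("cv shortlist filters, sorts ascending and breaks ties by id", {
  tab <- candidate_gene_stats()
  stats <- data.frame(gene_id = tab$gene_id,
                      cv = tab$sd_log2tpm / tab$mean_log2tpm)
  kept <- shortlist_by_cv(stats, 0.1)
  expect_length(kept, 9)
  expect_false(any(c("eef1a", "actb", "gapdh") %in% kept))
  expect_equal(kept[1], "rps2")

  # brute-force filter + sort oracle on a randomized table
  set.seed(21)
  rnd <- data.frame(gene_id = sprintf("g%02d", sample(30)),
                    cv = round(runif(30, 0, 0.2), 2))
  got <- shortlist_by_cv(rnd, 0.1)
  keep <- rnd[rnd$cv < 0.1, ]
  oracle <- keep$gene_id[order(keep$cv, keep$gene_id)]
  expect_identical(got, oracle)

  # cv_max = 0 retains only zero-variance genes
  zv <- data.frame(gene_id = c("a", "b"), cv = c(0, 0.01))
  expect_identical(shortlist_by_cv(zv, 1e-12), "a")
})

test_that("stage percentages follow the printed two-decimal convention", {
  expect_equal(stage_percentages(c(7598, 776, 320, 328), 43155),
               c(17.61, 1.80, 0.74, 0.76))
})

test_that("criteria I-IV gate genes as defined", {
  tissues <- c("muscle", "hepatopancreas", "testis", "heart")
  tissue_of <- rep(tissues, each = 3)
  base <- matrix(2^7, 6, 12,
                 dimnames = list(paste0("g", 1:6), paste0("s", 1:12)))
  # g2 undetectable in one muscle sample; g3 high sd; g4 one outlier sample;
  # g5 low mean; g6 low mean AND high sd (sequential never reaches IV for it)
  lt <- log2(base)
  lt["g3", ] <- 7 + rep(c(-1.2, 1.2), 6)
  lt["g4", ] <- 7; lt["g4", 5] <- 9.5
  lt["g5", ] <- 4.5
  lt["g6", ] <- 4.5 + rep(c(-1.3, 1.3), 6)
  tpm <- 2^lt
  tpm["g2", 2] <- 0
  ann <- sample_annotation(colnames(tpm), tissue = tissue_of)
  expr <- expression_matrix(tpm, annotation = ann)

  seq_res <- apply_criteria(expr, screen_criteria(mode = "sequential"))
  expect_identical(seq_res$survivors, "g1")
  expect_equal(unname(seq_res$stage_counts), c(5, 3, 2, 1))
  expect_true(all(diff(seq_res$stage_counts) <= 0))

  per_res <- apply_criteria(expr, screen_criteria(mode = "per_stage"))
  expect_identical(per_res$survivors, "g1")
  # per-stage counts are independent of one another: III admits the high-sd
  # genes g3/g6 (small per-sample deviations), IV admits the outlier gene g4
  expect_equal(unname(per_res$stage_counts), c(5, 3, 4, 3))

  # percentages always refer to the full gene total
  expect_equal(unname(seq_res$stage_percentages),
               100 * unname(seq_res$stage_counts) / 6)

  # a required tissue with zero samples is a configuration error
  expect_error(
    apply_criteria(expr, screen_criteria(required_tissues = c("muscle",
                                                              "eyestalk"))),
    "eyestalk")
})

test_that("screen recovers exactly the planted housekeeping set", {
  sim <- simulate_tpm(tpm_sim_config(seed = 303))
  res <- apply_criteria(sim$expr)
  planted <- sort(sim$truth$gene_id[sim$truth$class == "housekeeping"])
  expect_identical(sort(res$survivors), planted)
})

test_that("relaxing any threshold never shrinks the survivor set", {
  sim <- simulate_tpm(tpm_sim_config(seed = 77, n_housekeeping = 10,
                                     n_tissue_variable = 10,
                                     n_low_expressed = 10,
                                     n_tissue_restricted = 5))
  base <- apply_criteria(sim$expr, screen_criteria())$survivors
  relaxed <- list(
    screen_criteria(sd_max = 2),
    screen_criteria(dev_max = 4),
    screen_criteria(mean_min = 3),
    screen_criteria(cv_max = 0.5)
  )
  for (crit in relaxed) {
    surv <- apply_criteria(sim$expr, crit)$survivors
    expect_true(all(base %in% surv))
  }
})

test_that("adding a constant to log2(TPM) shifts mean, preserves sd", {
  set.seed(9)
  lt <- matrix(rnorm(24, 8, 0.5), 2, 12)
  m <- label_matrix(2^lt)
  st0 <- gene_stats(expression_matrix(m))
  st1 <- gene_stats(expression_matrix(label_matrix(2^(lt + 3))))
  expect_equal(st1$mean_log2tpm, st0$mean_log2tpm + 3)
  expect_equal(st1$sd_log2tpm, st0$sd_log2tpm)
  expect_equal(st1$cv, st0$sd_log2tpm / (st0$mean_log2tpm + 3))
})
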