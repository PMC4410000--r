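test_that("scaled and observed densities follow the model formulas", {
  # one X gene with N_i = 10 in a male library of N_total = 1000
  # (N_x = 100): S_i = 2*10/1100; female N_i = 20 of N_ftotal = 1100:
  # A_i = 20/1100, so A/S = 1
  ann <- gene_annotation(
    c(sprintf("x%02d", 1:10), sprintf("a%02d", 1:18), "y1"),
    c(rep("chrX", 10), rep("chr1", 18), "chrY"),
    seq(0, by = 10000, length.out = 29),
    seq(0, by = 10000, length.out = 29) + 3000,
    rep("+", 29)
  )
  vm <- stats::setNames(c(rep(10, 10), rep(50, 18), 7), ann$gene_id)
  vf <- stats::setNames(c(rep(20, 10), rep(50, 18), 0), ann$gene_id)
  tm <- tss_window_counts(vm, ann, "male")
  tf <- tss_window_counts(vf, ann, "female")
  fit <- fit_dosage_model(tm, tf, ann)
  expect_equal(attr(fit, "N_total"), 1000)
  expect_equal(attr(fit, "N_x"), 100)
  expect_equal(attr(fit, "N_ftotal"), 1100)
  expect_equal(fit$S, rep(20 / 1100, 10))
  expect_equal(fit$A, rep(20 / 1100, 10))
  expect_equal(set_fold_enrichment(fit, fit$gene_id[1:4]), 1)
})

test_that("exact 2x female X signal with matched totals gives A = S", {
  sim_ann <- simulate_annotation(sim_config(n_autosomal = 50, n_x = 20,
                                            n_y = 2, seed = 3))
  vm <- stats::setNames(seq_len(nrow(sim_ann)) + 5, sim_ann$gene_id)
  vf <- vm
  vf[sim_ann$class == "X"] <- 2 * vm[sim_ann$class == "X"]
  vf[sim_ann$class == "Y"] <- 0
  fit <- fit_dosage_model(tss_window_counts(vm, sim_ann, "male"),
                          tss_window_counts(vf, sim_ann, "female"),
                          sim_ann)
  expect_equal(fit$A, fit$S)
  expect_equal(set_fold_enrichment(fit, fit$gene_id), 1)
})

test_that("densities are invariant to rescaling either track", {
  sim_ann <- simulate_annotation(sim_config(n_autosomal = 50, n_x = 20,
                                            n_y = 2, seed = 3))
  cov <- simulate_tss_coverage(sim_ann, seed = 4)
  fit <- fit_dosage_model(cov$male, cov$female, sim_ann)
  m5 <- cov$male; m5$value <- m5$value * 5
  f3 <- cov$female; f3$value <- f3$value * 3
  fit2 <- fit_dosage_model(m5, f3, sim_ann)
  expect_equal(fit2$S, fit$S)
  expect_equal(fit2$A, fit$A)
})

test_that("replicate tracks are averaged before totals", {
  sim_ann <- simulate_annotation(sim_config(n_autosomal = 20, n_x = 5,
                                            n_y = 1, seed = 6))
  c1 <- simulate_tss_coverage(sim_ann, seed = 1)
  c2 <- simulate_tss_coverage(sim_ann, seed = 2)
  fit <- fit_dosage_model(list(c1$male, c2$male),
                          list(c1$female, c2$female), sim_ann)
  avg_m <- (c1$male$value + c2$male$value) / 2
  x_idx <- sim_ann$class == "X"
  expect_equal(fit$n_male, unname(avg_m[x_idx]))
})

test_that("set fold enrichment follows the hand example", {
  fit <- manual_dosage_fit(S = c(0.01, 0.01), A = c(0.02, 0.01))
  expect_equal(set_fold_enrichment(fit, fit$gene_id), 1.5)
  expect_error(set_fold_enrichment(fit, "nope"), "nope")
  zero <- manual_dosage_fit(S = c(0, 0), A = c(0.1, 0.1))
  expect_error(set_fold_enrichment(zero, zero$gene_id), "undefined")
})

test_that("simulated set effects are recovered as fold enrichment", {
  ann <- simulate_annotation(sim_config(n_autosomal = 300, n_x = 400,
                                        n_y = 2, seed = 5))
  x_ids <- ann$gene_id[ann$class == "X"]
  set <- x_ids[seq(1, 400, by = 8)]   # 50 genes
  cov <- simulate_tss_coverage(ann, dosage_ratio_female_over_male = 2,
                               enriched_set = set, set_effect = 1.5,
                               mean_reads = 500, seed = 7)
  fit <- fit_dosage_model(cov$male, cov$female, ann)
  expect_lt(abs(set_fold_enrichment(fit, set) - 1.5), 0.1)

  cov0 <- simulate_tss_coverage(ann, 2, set_effect = 1, mean_reads = 500,
                                seed = 8)
  fit0 <- fit_dosage_model(cov0$male, cov0$female, ann)
  expect_lt(abs(set_fold_enrichment(fit0, set) - 1), 0.05)
})

test_that("permutation p-values detect planted enrichment and are bounded", {
  ann <- simulate_annotation(sim_config(n_autosomal = 100, n_x = 500,
                                        n_y = 2, seed = 9))
  x_ids <- ann$gene_id[ann$class == "X"]
  set <- x_ids[1:50]
  cov <- simulate_tss_coverage(ann, 2, enriched_set = set, set_effect = 2,
                               mean_reads = 300, seed = 10)
  fit <- fit_dosage_model(cov$male, cov$female, ann)
  res <- permutation_pvalue(fit, set, n_perm = 1000, seed = 11)
  expect_lte(res$p_value, 0.01)
  expect_gte(res$p_value, 1 / 1001)   # (b+1)/(n+1) lower bound, never 0

  # constant fit: every null FE equals the observed -> p = 1
  const <- manual_dosage_fit(S = rep(0.01, 20), A = rep(0.01, 20))
  expect_equal(permutation_pvalue(const, const$gene_id[1:5], n_perm = 200,
                                  seed = 1)$p_value, 1)
  expect_error(permutation_pvalue(const, const$gene_id, n_perm = 10,
                                  seed = 1), "smaller than the background")
})

test_that("degenerate tracks are rejected", {
  ann <- tiny_annotation()
  vm <- stats::setNames(rep(5, 5), ann$gene_id)
  v0 <- stats::setNames(rep(0, 5), ann$gene_id)
  tm <- tss_window_counts(vm, ann, "male")
  t0 <- tss_window_counts(v0, ann, "female")
  expect_error(fit_dosage_model(tm, t0, ann), "degenerate")
  expect_error(fit_dosage_model(t0, tm, ann), "degenerate")
})
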