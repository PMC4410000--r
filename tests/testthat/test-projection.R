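test_that("projection onto the defining dataset reproduces every sign", {
  sim <- small_sim(seed = 1)
  tab <- test_dimorphism(sim$counts)
  sig <- define_signature(tab, 0.1, 0.5, annotation = sim$annotation)
  proj <- project_logfc(sig, sim$counts, dataset = "self")
  expect_equal(sign(proj$log2fc), sign(proj$signature_log2fc))
  expect_length(attr(proj, "absent"), 0)
})

test_that("projection onto a null target centres per-class log2FC at 0", {
  sim <- small_sim(seed = 2)
  tab <- test_dimorphism(sim$counts)
  sig <- define_signature(tab, 0.1, 0.5, annotation = sim$annotation)
  null_cfg <- sim_config(n_autosomal = 300, n_x = 30, n_y = 2,
                         n_male = 10, n_female = 10,
                         dimorphic_fraction = 0, x_dosage_log2 = 0,
                         xist_log2fc = -9.01, seed = 33)
  null_sim <- simulate_counts(simulate_annotation(null_cfg), null_cfg)
  proj <- project_logfc(sig, null_sim$counts)
  auto <- proj$log2fc[proj$class == "autosome"]
  x_no_marker <- proj$log2fc[proj$class == "X" & proj$gene_id != "Xist"]
  if (length(auto)) expect_lt(abs(median(auto)), 0.1)
  expect_lt(abs(median(x_no_marker)), 0.15)
})

test_that("an X-dosage-only target flags X genes conserved, autosomes not", {
  sim <- small_sim(seed = 3, dimorphic_fraction = 0.1,
                   effect_size_log2 = 2)
  tab <- test_dimorphism(sim$counts)
  sig <- define_signature(tab, 0.1, 0.5, annotation = sim$annotation)
  tgt_cfg <- sim_config(n_autosomal = 300, n_x = 30, n_y = 2,
                        n_male = 12, n_female = 12,
                        dimorphic_fraction = 0, x_dosage_log2 = 1, seed = 44)
  tgt <- simulate_counts(simulate_annotation(tgt_cfg), tgt_cfg)
  proj <- project_logfc(sig, tgt$counts)
  x_rows <- proj$class == "X"
  auto_rows <- proj$class == "autosome"
  expect_gt(mean(proj$conserved[x_rows]), 0.8)
  if (any(auto_rows)) expect_lt(mean(proj$conserved[auto_rows]), 0.2)
})

test_that("projection is invariant to per-sample depth scaling", {
  sim <- small_sim(seed = 4)
  tab <- test_dimorphism(sim$counts)
  sig <- define_signature(tab, 0.1, 0.5, annotation = sim$annotation)
  proj <- project_logfc(sig, sim$counts)
  scaled <- sim$counts$counts
  scale <- rep(c(1, 2, 4), length.out = ncol(scaled))
  scaled <- sweep(scaled, 2, scale, `*`)
  proj2 <- project_logfc(sig, count_matrix(scaled, sim$counts$metadata))
  d <- abs(proj$log2fc - proj2$log2fc)
  # the VST pseudocount leaves a small depth sensitivity at low counts
  expect_lt(median(d), 0.05)
  expect_lt(max(d[proj$gene_id %in%
                    tab$gene_id[tab$baseMean >= 50]]), 0.05)
})

test_that("directional consistency counts signs and matches hand arithmetic", {
  a <- stats::setNames(c(1, -2, 0.5, -0.1, 3), paste0("g", 1:5))
  expect_equal(directional_consistency(a, a)$fraction_consistent, 1)

  # (n_same, n_opp) = (20, 10): X2 = 25/15 + 25/15 = 10/3, p ~ 0.068
  a2 <- stats::setNames(rep(1, 30), paste0("g", 1:30))
  b2 <- stats::setNames(c(rep(1, 20), rep(-1, 10)), paste0("g", 1:30))
  cc <- directional_consistency(a2, b2)
  expect_equal(cc$n_same, 20)
  expect_equal(cc$statistic, 10 / 3, tolerance = 1e-12)
  expect_equal(cc$p_value, stats::pchisq(10 / 3, 1, lower.tail = FALSE))
  expect_equal(round(cc$p_value, 3), 0.068)
})

test_that("the chi-square matches brute force on all small splits and is symmetric", {
  for (n in 1:30) {
    for (ns in 0:n) {
      a <- stats::setNames(rep(1, n), paste0("g", seq_len(n)))
      b <- stats::setNames(c(rep(1, ns), rep(-1, n - ns)),
                           paste0("g", seq_len(n)))
      cc <- directional_consistency(a, b)
      expect_equal(cc$statistic, (ns - (n - ns))^2 / n, tolerance = 1e-12)
      cc_swap <- directional_consistency(b, a)
      expect_equal(cc_swap$statistic, cc$statistic)
      expect_equal(cc_swap$fraction_consistent, cc$fraction_consistent)
    }
  }
})

test_that("consistency p-values are calibrated under random signs", {
  set.seed(17)
  ps <- replicate(300, {
    a <- stats::setNames(runif(40, 0.5, 2), paste0("g", 1:40))
    b <- stats::setNames(a * sample(c(-1, 1), 40, replace = TRUE),
                         names(a))
    directional_consistency(a, b)$p_value
  })
  expect_gt(mean(ps < 0.05), 0.01)
  expect_lt(mean(ps < 0.05), 0.10)
})

test_that("log2FC correlations behave on monotone maps and noisy replicates", {
  a <- stats::setNames(rnorm(20), paste0("g", 1:20))
  expect_equal(correlate_logfc(a, 2 * a)$estimate, 1)
  expect_equal(correlate_logfc(a, -a)$estimate, -1)
  set.seed(5)
  rho <- replicate(20, {
    # planted effects of mean magnitude 2, measured twice with noise
    eff <- sample(c(-1, 1), 69, replace = TRUE) * runif(69, 1, 3)
    x <- stats::setNames(eff + rnorm(69, 0, 0.3), paste0("g", 1:69))
    y <- stats::setNames(eff + rnorm(69, 0, 0.3), paste0("g", 1:69))
    correlate_logfc(x, y, "spearman")$estimate
  })
  expect_gt(min(rho), 0.9)
  expect_error(correlate_logfc(a[1:2], a[1:2]), "3 shared")
  const <- stats::setNames(rep(1, 20), names(a))
  expect_error(correlate_logfc(const, a), "constant")
})

test_that("X:autosome expression ratios track the simulated dosage", {
  cfg <- sim_config(n_autosomal = 600, n_x = 100, n_y = 0,
                    dimorphic_fraction = 0, x_dosage_log2 = 0,
                    baseline_log_mean_sd = 0.8, seed = 12)
  ann <- simulate_annotation(cfg)
  sim <- simulate_counts(ann, cfg)
  r_m <- x_autosome_ratio(sim$counts, ann, "male")
  expect_lt(abs(r_m - 1), 0.25)

  cfg2 <- sim_config(n_autosomal = 600, n_x = 100, n_y = 0,
                     dimorphic_fraction = 0, x_dosage_log2 = 1,
                     baseline_log_mean_sd = 0.8, xist_log2fc = -1, seed = 12)
  sim2 <- simulate_counts(simulate_annotation(cfg2), cfg2)
  r_m2 <- x_autosome_ratio(sim2$counts, ann, "male")
  r_f2 <- x_autosome_ratio(sim2$counts, ann, "female")
  expect_lt(abs(r_f2 / r_m2 - 2), 0.3)
})
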