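test_that("size factors follow the median-of-ratios hand example", {
  m <- matrix(c(10, 20, 30, 100,
                20, 40, 60, 200), ncol = 2,
              dimnames = list(paste0("g", 1:4), c("A", "B")))
  sf <- size_factors(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))

  same <- cbind(A = c(5, 10), B = c(5, 10), C = c(5, 10))
  rownames(same) <- c("g1", "g2")
  expect_equal(unname(size_factors(same)), rep(1, 3))

  zero <- cbind(A = c(5, 10), B = c(0, 0))
  rownames(zero) <- c("g1", "g2")
  expect_error(size_factors(zero), "library-size")
})

test_that("size factors agree with the reference median-of-ratios estimator", {
  skip_if_not_installed("DESeq2")
  sim <- small_sim(seed = 5)
  m <- sim$counts$counts
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  mine <- size_factors(m)
  # same estimator up to the geometric-mean-1 rescaling convention
  expect_equal(unname(mine / exp(mean(log(mine)))),
               unname(ref / exp(mean(log(ref)))), tolerance = 1e-8)
})

test_that("expression detection rules behave at their boundaries", {
  m <- matrix(c(1, 1, 1, 0,
                2, 2, 2, 2,
                4, 4, 4, 4), nrow = 3, byrow = TRUE,
              dimnames = list(c("drop", "lo", "hi"), paste0("s", 1:4)))
  cm <- tiny_counts(m)
  expect_equal(sort(detect_expressed(cm)), c("hi", "lo"))
  # mean_ge is inclusive at the threshold (size factors cancel here: the
  # normalised means equal the raw means)
  expect_true("lo" %in% detect_expressed(cm, "mean_ge:2"))
  expect_false("lo" %in% detect_expressed(cm, "mean_ge:2.5"))
  expect_error(detect_expressed(cm, "bogus"), "unknown rule")
})

test_that("the NB Wald test is calibrated on null simulations", {
  cfg <- sim_config(n_autosomal = 2000, n_x = 0, n_y = 0,
                    dimorphic_fraction = 0, x_dosage_log2 = 0, seed = 11)
  ann <- simulate_annotation(cfg)
  sim <- simulate_counts(ann, cfg)
  tab <- test_dimorphism(sim$counts)
  p <- tab$pvalue[tab$tested]
  expect_gt(length(p), 1800)
  t1 <- mean(p < 0.05)
  expect_gt(t1, 0.03); expect_lt(t1, 0.07)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("a female-only gene gets a strongly negative log2FC", {
  sim <- small_sim(seed = 3)
  tab <- test_dimorphism(sim$counts)
  expect_lt(tab$log2fc[tab$gene_id == "Xist"], -6)
  expect_gt(tab$log2fc[tab$gene_id == "Eif2s3y"], 4)
})

test_that("log2FC is invariant to depth scaling and exactly sign-swaps", {
  sim <- small_sim(seed = 6)
  tab <- test_dimorphism(sim$counts)
  doubled <- count_matrix(sim$counts$counts * 2, sim$counts$metadata)
  tab2 <- test_dimorphism(doubled)
  keep <- tab$tested
  d <- abs(tab$log2fc - tab2$log2fc)
  # doubling shifts the effective dispersion by 1/(2*mu), so the residual
  # wobble is dispersion-driven and concentrates in low-count genes
  expect_lt(median(d[keep]), 0.01)
  expect_lt(max(d[keep & tab$baseMean >= 100]), 0.01)

  flipped <- ifelse(sim$counts$metadata$sex == "male", "female", "male")
  tab3 <- test_dimorphism(sim$counts, sex = flipped)
  expect_equal(tab3$log2fc[keep], -tab$log2fc[keep])
  expect_equal(tab3$pvalue[keep], tab$pvalue[keep])
})

test_that("BH adjustment matches the brute-force construction", {
  bh_brute <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    pmin(1, adj)[order(o)]
  }
  set.seed(21)
  for (rep in 1:20) {
    p <- runif(sample(1:30, 1))^sample(1:3, 1)
    expect_equal(stats::p.adjust(p, "BH"), bh_brute(p))
  }
  sim <- small_sim(seed = 7)
  tab <- test_dimorphism(sim$counts)
  sel <- tab$tested
  expect_equal(tab$padj[sel], bh_brute(tab$pvalue[sel]))
  expect_true(all(tab$padj[sel] >= tab$pvalue[sel]))
  expect_true(all(is.na(tab$padj[!sel])))
})

test_that("signature thresholds are strict and recorded", {
  tab <- data.frame(gene_id = c("a", "b", "c", "d"),
                    baseMean = 10, log2fc = c(1, 0.5, 1, -2),
                    se = 0.1, pvalue = c(0.001, 0.001, 0.05, 0.001),
                    padj = c(0.1, 0.05, 0.05, 0.01), tested = TRUE)
  class(tab) <- c("dimorphism_table", "data.frame")
  sig <- define_signature(tab, 0.1, 0.5)
  # a: padj exactly at threshold -> out; b: |lfc| exactly 0.5 -> out
  expect_equal(sig$gene_id, c("c", "d"))
  expect_equal(attr(sig, "padj_threshold"), 0.1)
  expect_error(define_signature(tab, 0, 0.5), "> 0")
  expect_error(define_signature(tab, 0.1, -1), "> 0")
})

test_that("planted effects are recovered under the published thresholds", {
  cfg <- sim_config(n_autosomal = 1200, n_x = 40, n_y = 2,
                    n_male = 12, n_female = 12, dispersion = 0.05,
                    dimorphic_fraction = 0.05, effect_size_log2 = 2,
                    x_dosage_log2 = 0, seed = 13)
  ann <- simulate_annotation(cfg)
  sim <- simulate_counts(ann, cfg)
  tab <- test_dimorphism(sim$counts)
  sig <- define_signature(tab, 0.1, 0.5, annotation = ann)
  planted <- sim$truth$gene_id[sim$truth$is_dimorphic &
                                 sim$truth$class == "autosome"]
  called <- sig$gene_id[sig$class == "autosome"]
  expect_gte(mean(planted %in% called), 0.9)
  expect_lte(sum(!(called %in% planted)), 5)
})

test_that("designs without two samples per sex are rejected", {
  sim <- small_sim(seed = 8)
  ids <- sim$counts$metadata$sample_id
  expect_error(test_dimorphism(subset_samples(sim$counts, ids[c(1, 2, 7)])),
               "2 samples per sex")
})
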