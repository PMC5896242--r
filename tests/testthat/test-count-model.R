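test_that("size factors match hand-derived median-of-ratios values", {
  two <- cbind(A = c(5L, 9L, 13L), B = c(5L, 9L, 13L))
  expect_equal(unname(estimate_size_factors(two)), c(1, 1))

  doubled <- cbind(A = c(3L, 7L, 11L), B = c(6L, 14L, 22L))
  sf <- estimate_size_factors(doubled)
  expect_equal(unname(sf["B"] / sf["A"]), 2)

  toy <- cbind(A = c(1L, 2L, 4L), B = c(2L, 4L, 8L))
  expect_equal(unname(estimate_size_factors(toy)),
               c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  expect_error(estimate_size_factors(matrix(0L, 3, 2)), "all-zero")
})

test_that("size factors are equivariant under sample rescaling", {
  set.seed(1)
  m <- matrix(rnbinom(300, mu = 50, size = 5), 100, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  sf1 <- estimate_size_factors(m)
  m2 <- m
  m2[, "b"] <- m2[, "b"] * 3L
  sf2 <- estimate_size_factors(m2)
  # ratio of b's factor to the others scales by 3 (up to geo-mean renorm)
  expect_equal(unname((sf2["b"] / sf2["a"]) / (sf1["b"] / sf1["a"])), 3,
               tolerance = 1e-12)
})

test_that("low-expression filter applies the quantile rule with ties retained", {
  m <- matrix(0L, 10, 2, dimnames = list(paste0("g", 1:10), c("s1", "s2")))
  m[, 1] <- 0:9
  m[, 2] <- rep(1L, 10)          # row sums 1..10
  kept <- filter_low_expression(m, 0.40)
  expect_setequal(kept, paste0("g", 5:10))

  eq <- matrix(3L, 5, 2, dimnames = list(paste0("g", 1:5), c("s1", "s2")))
  expect_setequal(filter_low_expression(eq, 0.40), paste0("g", 1:5))
  expect_error(filter_low_expression(m, 1), "quantile")
})

test_that("dispersion estimates are calibrated on Poisson and NB data", {
  d <- toy_design(n_reg = 3, biopsies = 2)
  withr::with_seed(2, {
    mu <- exp(runif(600, log(50), log(1000)))
    pois <- matrix(rpois(600 * 6, rep(mu, 6)), 600, 6,
                   dimnames = list(sprintf("g%03d", 1:600), d$sample_id))
    nb <- matrix(rnbinom(600 * 6, mu = rep(mu, 6), size = 1 / 0.2), 600, 6,
                 dimnames = list(sprintf("g%03d", 1:600), d$sample_id))
  })
  dp <- estimate_dispersions(pois, d)
  expect_lte(median(dp$alpha), 0.01)
  dn <- estimate_dispersions(nb, d)
  expect_gte(median(dn$alpha), 0.1)
  expect_lte(median(dn$alpha), 0.4)
  expect_true(all(dn$alpha >= 0 & is.finite(dn$alpha)))

  # constant gene: no error, trend value assigned
  cst <- pois
  cst[1, ] <- 40L
  dc <- estimate_dispersions(cst, d)
  expect_true(is.finite(dc$alpha[1]))
  expect_identical(dc$method[1], "trend")
})

test_that("null contrasts give approximately uniform p and planted effects are recovered", {
  cfg <- sim_config(n_genes = 1200, n_dogs_regressive = 3,
                    biopsies_per_dog = 2, dispersion = 0.05,
                    n_dogs_nonregressive = 0, frac_early = 0,
                    frac_late = 0, frac_progressive = 0, seed = 77)
  sim <- simulate_counts(cfg)
  keep <- filter_low_expression(sim$counts)
  r <- fit_contrasts(sim$counts[keep, ], sim$design)$B2_vs_B1
  p <- r$p[r$tested]
  expect_gt(mean(p < 0.05), 0.02)
  expect_lt(mean(p < 0.05), 0.09)
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
  # padj >= p after adjustment
  expect_true(all(r$padj[r$tested] >= r$p[r$tested]))

  cfg2 <- sim_config(n_genes = 400, n_dogs_regressive = 6,
                     n_dogs_nonregressive = 0, biopsies_per_dog = 2,
                     dispersion = 0.05,
                     baseline_log_mean_range = log(c(100, 1000)),
                     frac_early = 0.15, frac_late = 0,
                     frac_progressive = 0, seed = 78)
  sim2 <- simulate_counts(cfg2)
  r2 <- fit_contrasts(sim2$counts, sim2$design)$B2_vs_B1
  tr <- sim2$truth
  pl <- tr$class == "EARLY"
  err <- r2$log2fc[pl] - tr$log2fc_R_vs_P[pl]
  expect_gte(mean(abs(err) < 0.5, na.rm = TRUE), 0.9)
  expect_lt(abs(mean(err, na.rm = TRUE)), 0.1)
})

test_that("all-zero genes carry the not-tested marker", {
  cfg <- sim_config(n_genes = 50, n_dogs_regressive = 3,
                    n_dogs_nonregressive = 0, biopsies_per_dog = 2, seed = 3)
  sim <- simulate_counts(cfg)
  counts <- sim$counts
  counts[1, ] <- 0L
  r <- suppressWarnings(fit_contrasts(counts, sim$design))$B2_vs_B1
  expect_false(r$tested[1])
  expect_true(is.na(r$log2fc[1]))
  expect_true(is.na(r$padj[1]))
})

test_that("dog-wise scaling barely moves paired contrast estimates", {
  cfg <- sim_config(n_genes = 300, n_dogs_regressive = 3,
                    n_dogs_nonregressive = 0, biopsies_per_dog = 2,
                    baseline_log_mean_range = log(c(100, 1000)),
                    frac_early = 0.1, frac_late = 0, frac_progressive = 0,
                    seed = 31)
  sim <- simulate_counts(cfg)
  r1 <- fit_contrasts(sim$counts, sim$design)$B2_vs_B1
  scaled <- sim$counts
  cols <- sim$design$sample_id[sim$design$dog == "R1"]
  scaled[, cols] <- scaled[, cols] * 8L
  r2 <- fit_contrasts(scaled, sim$design)$B2_vs_B1
  ok <- r1$tested & r2$tested
  expect_gt(cor(r1$log2fc[ok], r2$log2fc[ok]), 0.99)
  expect_lt(median(abs(r1$log2fc[ok] - r2$log2fc[ok])), 0.1)
})

test_that("BH adjustment matches hand and brute-force oracles", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.3), 0.3)
  expect_error(adjust_bh(c(0.1, NA)), "NA")
  expect_error(adjust_bh(c(0.1, 1.2)), "0, 1")
  withr::with_seed(10, {
    for (i in 1:100) {
      p <- runif(sample(1:12, 1))
      expect_equal(adjust_bh(p), bh_bruteforce(p), tolerance = 1e-12)
    }
  })
  # sorted output is non-decreasing
  p <- runif(50)
  expect_true(all(diff(adjust_bh(p)[order(p)]) >= -1e-15))
})

test_that("significance calling applies strict cutoffs and is monotone", {
  res <- data.frame(gene_id = c("a", "b", "c", "d"),
                    base_mean = 100,
                    log2fc = c(3.5, log2(9.99), log2(100), -4),
                    se = 0.1,
                    p = c(1e-4, 1e-8, 1e-3, 1e-5),
                    padj = c(0.005, 1e-6, 0.02, 0.001),
                    tested = TRUE)
  sig <- call_significant(res)
  expect_setequal(sig$gene_id, c("a", "d"))
  expect_equal(sig$direction[sig$gene_id == "a"], 1)
  expect_equal(sig$direction[sig$gene_id == "d"], -1)
  # monotone: tightening thresholds never adds genes
  tighter_fc <- call_significant(res, fc_threshold = 20)
  tighter_a <- call_significant(res, alpha = 0.001)
  expect_true(all(tighter_fc$gene_id %in% sig$gene_id))
  expect_true(all(tighter_a$gene_id %in% sig$gene_id))
})

test_that("interaction test rejects degenerate designs and flags bad genes", {
  cfg <- sim_config(n_genes = 60, n_dogs_regressive = 3,
                    n_dogs_nonregressive = 3, biopsies_per_dog = 2, seed = 6)
  sim <- simulate_counts(cfg)
  single <- sim$design[sim$design$regression_status == "REGRESSIVE", ]
  expect_error(interaction_test(sim$counts[, single$sample_id], single),
               "both regression statuses")
  counts <- sim$counts
  counts[1, ] <- 0L
  r <- suppressWarnings(interaction_test(counts, sim$design))
  expect_false(r$tested[1])
})

test_that("size factors and fold changes agree with an independent NB implementation", {
  skip_if_not_installed("DESeq2")
  cfg <- sim_config(n_genes = 300, n_dogs_regressive = 4,
                    n_dogs_nonregressive = 0, biopsies_per_dog = 2,
                    dispersion = 0.05,
                    baseline_log_mean_range = log(c(50, 2000)),
                    frac_early = 0.15, frac_late = 0, frac_progressive = 0,
                    seed = 41)
  sim <- simulate_counts(cfg)
  sf_mine <- estimate_size_factors(sim$counts)
  sf_ref <- DESeq2::estimateSizeFactorsForMatrix(sim$counts)
  sf_ref <- sf_ref / exp(mean(log(sf_ref)))
  expect_equal(unname(sf_mine), unname(sf_ref), tolerance = 1e-8)

  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      sim$counts, S4Vectors::DataFrame(dog = factor(sim$design$dog),
                                       biopsy = factor(sim$design$biopsy)),
      ~ dog + biopsy)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    ref <- DESeq2::results(dds, name = "biopsy_2_vs_1")
  })
  mine <- fit_contrasts(sim$counts, sim$design)$B2_vs_B1
  ok <- mine$tested & is.finite(ref$log2FoldChange)
  expect_gt(cor(mine$log2fc[ok], ref$log2FoldChange[ok]), 0.95)
  # planted genes agree closely where the signal is strong
  pl <- sim$truth$class == "EARLY" & ok
  expect_lt(median(abs(mine$log2fc[pl] - ref$log2FoldChange[pl])), 0.3)
})
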