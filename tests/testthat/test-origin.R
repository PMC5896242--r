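test_that("origin calls follow the informative-site and unanimity rules", {
  pu <- function(depth, tumor, gene = "g") {
    data.frame(gene_id = rep(gene, length(depth)),
               pos = seq_along(depth) * 100,
               depth = depth, tumor_count = tumor,
               host_count = depth - tumor)
  }
  expect_identical(assign_origin(pu(c(20, 20, 20), c(20, 20, 20)))$call,
                   "TUMOR")
  expect_identical(assign_origin(pu(c(20, 20, 20), c(0, 0, 0)))$call, "HOST")
  # one informative site is never enough
  one <- assign_origin(pu(c(20, 5), c(20, 5)))
  expect_identical(one$call, "AMBIGUOUS")
  expect_equal(one$n_informative, 1L)
  # unanimity: 2 tumor votes + 1 host vote abstains the gene
  expect_identical(assign_origin(pu(c(20, 20, 20), c(20, 20, 0)))$call,
                   "AMBIGUOUS")
  # mixed-fraction sites abstain rather than vote
  expect_identical(assign_origin(pu(c(20, 20), c(10, 10)))$call, "AMBIGUOUS")
  # no sites at all: AMBIGUOUS with zero informative sites, not an error
  empty <- assign_origin(pu(numeric(), numeric()))
  expect_identical(empty$call, "AMBIGUOUS")
  expect_equal(empty$n_informative, 0L)
})

test_that("swapping allele labels swaps HOST and TUMOR calls exactly", {
  gm <- simulate_gene_models(30, seed = 14)
  cfg <- sim_config(n_genes = 30, allele_error_rate = 0.05, seed = 14)
  vp <- simulate_variant_pileups(gm, cfg)
  calls <- assign_origin_all(vp$pileups)
  swapped <- vp$pileups
  swapped$tumor_count <- vp$pileups$host_count
  swapped$host_count <- vp$pileups$tumor_count
  calls_sw <- assign_origin_all(swapped)
  map <- c(HOST = "TUMOR", TUMOR = "HOST", AMBIGUOUS = "AMBIGUOUS")
  expect_identical(unname(map[calls$call]), calls_sw$call)
})

test_that("raising thresholds never converts AMBIGUOUS into a call", {
  gm <- simulate_gene_models(40, seed = 15)
  cfg <- sim_config(n_genes = 40, allele_error_rate = 0.1,
                    depth_per_site_range = c(2L, 30L), seed = 15)
  vp <- simulate_variant_pileups(gm, cfg)
  base <- assign_origin_all(vp$pileups, min_variants = 2, min_depth = 8)
  for (args in list(list(min_variants = 4), list(min_depth = 20),
                    list(min_variants = 3, min_depth = 15))) {
    stricter <- do.call(assign_origin_all, c(list(vp$pileups), args))
    amb <- base$gene_id[base$call == "AMBIGUOUS"]
    expect_true(all(stricter$call[match(amb, stricter$gene_id)] ==
                      "AMBIGUOUS"))
  }
})

test_that("origin recovery is perfect without errors and robust at 1% error", {
  gm <- simulate_gene_models(100, seed = 16)
  cfg0 <- sim_config(n_genes = 100, allele_error_rate = 0,
                     sites_per_transcript_range = c(2L, 5L),
                     depth_per_site_range = c(10L, 60L), seed = 16)
  vp0 <- simulate_variant_pileups(gm, cfg0)
  calls0 <- assign_origin_all(vp0$pileups)
  acc0 <- mean(calls0$call[match(vp0$truth$gene_id, calls0$gene_id)] ==
                 vp0$truth$origin)
  expect_equal(acc0, 1)

  cfg1 <- sim_config(n_genes = 100, allele_error_rate = 0.01, seed = 17)
  vp1 <- simulate_variant_pileups(gm, cfg1)
  calls1 <- assign_origin_all(vp1$pileups)
  acc1 <- mean(calls1$call[match(vp1$truth$gene_id, calls1$gene_id)] ==
                 vp1$truth$origin)
  expect_gte(acc1, 0.95)

  # 50% error carries no signal: essentially everything abstains
  cfg5 <- sim_config(n_genes = 100, allele_error_rate = 0.5, seed = 18)
  vp5 <- simulate_variant_pileups(gm, cfg5)
  calls5 <- assign_origin_all(vp5$pileups)
  expect_gte(mean(calls5$call == "AMBIGUOUS"), 0.9)

  # single-site genes are always AMBIGUOUS
  cfgk1 <- sim_config(n_genes = 100, allele_error_rate = 0,
                      sites_per_transcript_range = c(1L, 1L), seed = 19)
  vpk1 <- simulate_variant_pileups(gm, cfgk1)
  callsk1 <- assign_origin_all(vpk1$pileups)
  expect_true(all(callsk1$call == "AMBIGUOUS"))
})

test_that("host marker lookup is plain set membership", {
  markers <- c("GENE1", "GENE7")
  expect_identical(host_marker_lookup(c("GENE1", "GENE2"), markers),
                   c(TRUE, FALSE))
  expect_false(any(host_marker_lookup(c("GENE1", "GENE2"), character())))
})

test_that("standard curves, inversion and burden arithmetic are exact", {
  sc <- fit_standard_curve(data.frame(quantity = c(1, 0.1, 0.01),
                                      ct = c(20, 23.3219, 26.6439)))
  expect_equal(sc$slope, -3.32195, tolerance = 1e-4)
  expect_equal(sc$intercept, 20, tolerance = 1e-4)
  expect_equal(sc$r_squared, 1, tolerance = 1e-9)
  expect_equal(sc$efficiency, 1, tolerance = 1e-4)

  # noiseless round trip of every standard
  q <- 10^seq(0, -4)
  curve <- fit_standard_curve(data.frame(quantity = q,
                                         ct = 20 + (-1 / log10(2)) * log10(q)))
  expect_equal(relative_quantity(20 + (-1 / log10(2)) * log10(q), curve), q,
               tolerance = 1e-9)

  expect_equal(relative_quantity(21.6610, curve), 0.3162, tolerance = 1e-4)
  expect_equal(normalize_to_reference(3, 2), 1.5)
  expect_equal(normalize_to_reference(2, 2), 1)
  expect_warning(bc <- burden_change(c(0.5, 0.2), c(1, 0)), "zero")
  expect_equal(bc[1], 0.5)
  expect_true(is.na(bc[2]))
  expect_error(fit_standard_curve(data.frame(quantity = c(1, 1, 1),
                                             ct = c(20, 20, 20))), "distinct")
  expect_error(fit_standard_curve(data.frame(quantity = c(1, 0.1, -1),
                                             ct = c(20, 23, 26))), "positive")
})

test_that("noisy standard curves recover the true slope with replicates", {
  withr::with_seed(20, {
    q <- rep(10^seq(0, -3), each = 50)
    ct <- 20 + (-1 / log10(2)) * log10(q) + rnorm(length(q), 0, 0.2)
  })
  sc <- fit_standard_curve(data.frame(quantity = q, ct = ct))
  expect_lt(abs(sc$slope - (-1 / log10(2))), 0.1)
})

test_that("burden quantification recovers planted tumor loss", {
  cfg <- sim_config(n_dogs_regressive = 3, n_dogs_nonregressive = 3, seed = 44)
  qs <- simulate_qpcr(cfg, sigma = 0, b2_burden_regressive = 0.02)
  qb <- quantify_burden(qs$ct_table)
  lm_ <- qb$burden[qb$burden$target == "LINE_MYC", ]
  reg <- grepl("^R", lm_$dog)
  expect_equal(lm_$burden_change[reg], rep(0.02, sum(reg)), tolerance = 1e-6)
  expect_equal(lm_$burden_change[!reg], rep(1, sum(!reg)), tolerance = 1e-6)
  # the shared marker and reference stay flat everywhere
  dc <- qb$burden[qb$burden$target == "DLA_common", ]
  expect_equal(dc$burden_change, rep(1, nrow(dc)), tolerance = 1e-6)
})
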