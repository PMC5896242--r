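test_that("feature regions follow transcription order on both strands", {
  ex3 <- data.frame(gene_id = "g", chrom = "chrS",
                    start = c(1000, 2000, 3000),
                    end = c(1200, 2300, 3100), strand = "+")
  fr <- derive_feature_regions(ex3)
  expect_equal(fr$first_exon$start, 1000)
  expect_equal(fr$first_intron, data.frame(start = 1200, end = 2000))
  expect_equal(fr$internal_exons, data.frame(start = 2000, end = 2300))
  expect_equal(fr$internal_introns, data.frame(start = 2300, end = 3000))
  expect_equal(fr$last_exon$end, 3100)
  expect_equal(fr$upstream2kb, data.frame(start = 0, end = 1000))
  expect_equal(fr$downstream2kb, data.frame(start = 3100, end = 5100))

  ex3m <- transform(ex3, strand = "-")
  frm <- derive_feature_regions(ex3m)
  # minus strand: upstream flank lies at higher genomic coordinates
  expect_equal(frm$upstream2kb, data.frame(start = 3100, end = 5100))
  expect_equal(frm$first_exon$start, 3000)
  expect_equal(frm$last_exon$start, 1000)
  expect_equal(frm$first_intron, data.frame(start = 2300, end = 3000))

  ex1 <- data.frame(gene_id = "g", chrom = "chrS", start = 500, end = 700,
                    strand = "+")
  fr1 <- derive_feature_regions(ex1)
  expect_null(fr1$first_intron)
  expect_null(fr1$internal_exons)
  expect_null(fr1$internal_introns)
  expect_null(fr1$last_exon)
  expect_equal(fr1$first_exon, data.frame(start = 500, end = 700))
  # two-exon genes have first/last exons and one (first) intron only
  ex2 <- data.frame(gene_id = "g", chrom = "chrS", start = c(100, 400),
                    end = c(200, 500), strand = "+")
  fr2 <- derive_feature_regions(ex2)
  expect_null(fr2$internal_exons)
  expect_null(fr2$internal_introns)
  expect_false(is.null(fr2$first_intron))
})

test_that("binning divides the concatenated feature into exact twentieths", {
  b <- bin_feature(data.frame(start = 100, end = 300), "+", 20)
  expect_length(b, 20)
  expect_equal(attr(b, "bin_length"), 10)
  expect_equal(b[[1]], data.frame(start = 100, end = 110))
  expect_equal(b[[20]], data.frame(start = 290, end = 300))

  # 25 + 15 bp split intervals: 2 bp bins; bin 13 straddles the junction
  reg <- data.frame(start = c(100, 160), end = c(125, 175))
  b2 <- bin_feature(reg, "+", 20)
  expect_equal(attr(b2, "bin_length"), 2)
  expect_equal(nrow(b2[[13]]), 2)       # feature [24, 26) crosses the join
  expect_equal(sum(b2[[13]]$end - b2[[13]]$start), 2)
  expect_equal(b2[[13]]$end[1], 125)
  expect_equal(b2[[13]]$start[2], 160)
  # total genomic extent of all bins covers the feature exactly
  expect_equal(sum(vapply(b2, function(p) sum(p$end - p$start), numeric(1))),
               40)

  # features shorter than the bin count get fractional-base bins
  b3 <- bin_feature(data.frame(start = 0, end = 10), "+", 20)
  expect_equal(attr(b3, "bin_length"), 0.5)
  expect_equal(b3[[2]], data.frame(start = 0.5, end = 1.0))
  expect_null(bin_feature(NULL, "+"))

  # minus strand: bin 1 is the 5'-most (highest-coordinate) piece
  bm <- bin_feature(data.frame(start = 100, end = 300), "-", 20)
  expect_equal(bm[[1]], data.frame(start = 290, end = 300))
})

test_that("mean signal matches trivial cases and the per-base oracle", {
  tr5 <- data.frame(chrom = "chrS", start = 0, end = 1000, value = 5)
  bins <- bin_feature(data.frame(start = 100, end = 300), "+", 20)
  expect_equal(mean_signal(tr5, bins, "chrS"), rep(5, 20))

  half <- data.frame(chrom = "chrS", start = c(0, 50), end = c(50, 100),
                     value = c(10, 0))
  bh <- bin_feature(data.frame(start = 0, end = 100), "+", 20)
  expect_equal(mean_signal(half, bh, "chrS"), rep(c(10, 0), each = 10))

  withr::with_seed(21, {
    for (i in 1:25) {
      n <- sample(5:25, 1)
      w <- sample(1:6, n, replace = TRUE)
      gap <- sample(0:4, n, replace = TRUE)
      starts <- cumsum(gap) + c(0, cumsum(w[-n] ))
      tr <- data.frame(chrom = "chrS", start = starts, end = starts + w,
                       value = runif(n, 0, 8))
      lo <- runif(1, 0, 10); hi <- lo + runif(1, 3, max(starts))
      bb <- bin_feature(data.frame(start = lo, end = hi), "+", 20)
      got <- mean_signal(tr, bb, "chrS")
      want <- vapply(bb, function(p)
        mean_signal_bruteforce(tr, p$start[1], p$end[1]), numeric(1))
      expect_equal(got, want, tolerance = 1e-9)
      # conservation: length-weighted bin mean equals the feature mean
      expect_equal(mean(got), mean_signal_bruteforce(tr, lo, hi),
                   tolerance = 1e-9)
    }
  })
})

test_that("metagene profiles are invariant under strand reflection", {
  withr::with_seed(22, {
    for (i in 1:10) {
      gm <- simulate_gene_models(1, seed = i)
      span_lo <- min(gm$start) - 2500
      span_hi <- max(gm$end) + 2500
      brk <- sort(c(span_lo, span_hi,
                    runif(30, span_lo, span_hi)))
      tr <- data.frame(chrom = "chrS", start = brk[-length(brk)],
                       end = brk[-1], value = runif(length(brk) - 1, 0, 10))
      prof <- metagene_profile(gm, gm$gene_id[1], list(B1 = tr),
                               normalize = FALSE)
      # reflect gene and track through a pivot and flip the strand
      pivot <- 2 * span_hi
      gm2 <- gm
      gm2$start <- pivot - gm$end
      gm2$end <- pivot - gm$start
      gm2$strand <- ifelse(gm$strand == "+", "-", "+")
      gm2 <- gm2[order(gm2$start), ]
      tr2 <- data.frame(chrom = "chrS", start = pivot - tr$end,
                        end = pivot - tr$start, value = tr$value)
      tr2 <- tr2[order(tr2$start), ]
      prof2 <- metagene_profile(gm2, gm$gene_id[1], list(B1 = tr2),
                                normalize = FALSE)
      expect_equal(prof$value, prof2$value, tolerance = 1e-9)
    }
  })
})

test_that("profiles average per list and keep absent features as NA", {
  gm <- rbind(
    data.frame(gene_id = "multi", chrom = "chrS",
               start = c(5000, 6000, 7000), end = c(5200, 6300, 7400),
               strand = "+"),
    data.frame(gene_id = "mono", chrom = "chrS", start = 20000, end = 20400,
               strand = "+"))
  tr <- data.frame(chrom = "chrS", start = 0, end = 30000, value = 4)
  prof <- metagene_profile(gm, c("multi", "mono"), list(B1 = tr),
                           normalize = FALSE)
  mono <- prof[prof$gene_id == "mono", ]
  expect_true(all(is.na(mono$value[mono$feature == "last_exon"])))
  expect_true(all(mono$value[mono$feature == "first_exon"] == 4))
  multi <- prof[prof$gene_id == "multi", ]
  expect_true(all(multi$value == 4))
  expect_error(metagene_profile(gm, "nope", list(B1 = tr)), "unknown gene")
  expect_error(metagene_profile(gm, character(), list(B1 = tr)), "empty")
})

test_that("baseline subtraction is exact and shift-invariant", {
  gm <- data.frame(gene_id = c("a", "b"), chrom = "chrS",
                   start = c(5000, 15000), end = c(5400, 15400),
                   strand = "+")
  tr <- data.frame(chrom = "chrS", start = c(0, 10000),
                   end = c(10000, 20000), value = c(5, 3))
  prof <- metagene_profile(gm, "a", list(B1 = tr), normalize = FALSE)
  base <- metagene_profile(gm, "b", list(B1 = tr), normalize = FALSE)
  norm <- baseline_subtract(prof, base)
  fe <- norm$value[norm$feature == "first_exon"]
  expect_equal(fe, rep(2, 20))
  # identical profiles and baseline give all zeros
  norm0 <- baseline_subtract(base, base)
  expect_true(all(norm0$value[!is.na(norm0$value)] == 0))
  # adding a constant everywhere cancels
  trc <- tr; trc$value <- trc$value + 7
  profc <- metagene_profile(gm, "a", list(B1 = trc), normalize = FALSE)
  basec <- metagene_profile(gm, "b", list(B1 = trc), normalize = FALSE)
  expect_equal(baseline_subtract(profc, basec)$value, norm$value)
  expect_error(baseline_subtract(prof, base[0, ]), "empty")
})

test_that("demethylation scores use the documented sign and quartiles", {
  x <- 1:100
  bs <- boxplot_stats(x)
  expect_equal(unname(bs["median"]), 50.5)
  expect_equal(unname(bs["q1"]), 25.75)
  expect_equal(unname(bs["q3"]), 75.25)
  expect_equal(unname(bs["lo_whisker"]), 1)
  expect_equal(unname(bs["hi_whisker"]), 100)
  # whiskers stop at the last point inside 1.5 IQR
  y <- c(1:10, 1000)
  expect_equal(unname(boxplot_stats(y)["hi_whisker"]), 10)

  gm <- data.frame(gene_id = c("a", "b"), chrom = "chrS",
                   start = c(5000, 15000), end = c(5400, 15400),
                   strand = "+")
  tr <- data.frame(chrom = "chrS", start = c(0, 10000),
                   end = c(10000, 20000), value = c(2, 5))
  prof <- metagene_profile(gm, "a", list(B1 = tr), normalize = FALSE)
  base <- metagene_profile(gm, "b", list(B1 = tr), normalize = FALSE)
  norm <- baseline_subtract(prof, base)
  ds <- demethylation_scores(norm, "a", "first_exon", "B1")
  # gene signal 3 below baseline -> demethylation score +3
  expect_equal(ds$scores$score, 3)
  expect_error(demethylation_scores(norm, "a", "last_exon", "B1"), "feature")
})

test_that("non-expressed genes are the strict zero rows", {
  m <- rbind(z = c(0L, 0L, 0L), near = c(0L, 1L, 0L), hi = c(5L, 2L, 9L))
  colnames(m) <- c("s1", "s2", "s3")
  expect_identical(define_non_expressed(m), "z")
  expect_identical(define_non_expressed(m, samples = c("s1", "s3")),
                   c("z", "near"))
  expect_length(define_non_expressed(m["hi", , drop = FALSE]), 0)
})

test_that("planted first-exon demethylation is detected end-to-end", {
  gm <- simulate_gene_models(60, seed = 23)
  ids <- unique(gm$gene_id)
  cfg <- sim_config(n_genes = 60, demeth_effect = 2, seed = 23)
  lists <- list(early = ids[1:25], non_expressed = ids[26:50])
  sm <- simulate_methylation(gm, lists, cfg, n_biopsies = 3)
  prof <- metagene_profile(gm, lists$early, sm$tracks, normalize = FALSE)
  base <- metagene_profile(gm, lists$non_expressed, sm$tracks,
                           normalize = FALSE)
  norm <- baseline_subtract(prof, base)
  med <- vapply(c("B1", "B2", "B3"), function(b)
    demethylation_scores(norm, lists$early, "first_exon", b)$stats["median"],
    numeric(1))
  expect_true(med[2] > med[1] && med[3] > med[2])
  # locality: internal exons stay flat
  med_int <- vapply(c("B1", "B3"), function(b)
    demethylation_scores(norm, lists$early, "internal_exons",
                         b)$stats["median"], numeric(1))
  expect_lt(abs(med_int[2] - med_int[1]), 1)
  # unknown gene id in a list errors
  expect_error(simulate_methylation(gm, list(early = "nope"), cfg),
               "unknown gene")
})
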