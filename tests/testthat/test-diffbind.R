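# Conditional exact test, window scan, merging and element enrichment.

test_that("the observed conditional mode has p = 1 under a symmetric null", {
  expect_equal(exact_pvalue(5, 5, 5, 5), 1)
  expect_equal(exact_pvalue(20, 20, 10, 10), 1)
  expect_equal(exact_pvalue(5, 5, 5, 5, dispersion = 0.5), 1)
})

test_that("exact p-values match brute-force enumeration on stated cases", {
  expect_equal(exact_pvalue(0, 10, 5, 5), oracle_exact_p(0, 10, 5, 5),
               tolerance = 1e-14)
  expect_equal(exact_pvalue(0, 10, 5, 5), oracle_exact_p_binom(0, 10, 5, 5),
               tolerance = 1e-12)
  # monotone in the imbalance of the split
  p1 <- exact_pvalue(0, 10, 5, 5)
  p2 <- exact_pvalue(2, 8, 5, 5)
  p3 <- exact_pvalue(5, 5, 5, 5)
  expect_lt(p1, p2); expect_lt(p2, p3)
  expect_equal(c(p1, p2, p3),
               c(oracle_exact_p_binom(0, 10, 5, 5),
                 oracle_exact_p_binom(2, 8, 5, 5),
                 oracle_exact_p_binom(5, 5, 5, 5)),
               tolerance = 1e-12)
})

test_that("fractional counts are rounded to nearest, ties to even", {
  expect_equal(exact_pvalue(2.5, 7.5, 5, 5),     # -> (2, 8)
               exact_pvalue(2, 8, 5, 5))
  expect_equal(exact_pvalue(3.5, 6.2, 5, 5),     # -> (4, 6)
               exact_pvalue(4, 6, 5, 5))
  expect_error(exact_pvalue(0, 0, 5, 5), "zero")
})

test_that("the BH step-up matches the reference implementation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(99)
  p <- runif(1000)
  expect_lt(max(abs(bh_adjust(p) - p.adjust(p, "BH"))), 1e-12)
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
})

test_that("an alignment contributes its weight to every overlapping
           window", {
  rec <- make_records("r1", "chr1", 1001, 1036)
  w <- scan_windows(rec, rec[0], c(chr1 = 5000L))
  # a 36 bp alignment inside the chromosome overlaps 5 of the 500/100
  # windows (starts 601..1001)
  expect_equal(nrow(w), 5L)
  expect_equal(w$raw_a, rep(1, 5))
  expect_equal(w$start, seq(601L, 1001L, by = 100L))
  expect_equal(w$raw_b, rep(0, 5))
  # no reads -> empty stream; step > window -> error
  expect_equal(nrow(scan_windows(rec[0], rec[0], c(chr1 = 5000L))), 0L)
  expect_error(scan_windows(rec, rec, c(chr1 = 5000L), window = 100,
                            step = 200), "step")
})

test_that("planted enrichment appears in the windows at about the planted
           fold", {
  g <- build_genome(genome_spec(
    200000, te_families = list(te_family("TGT", n_copies = 1,
                                         consensus_length = 2000)),
    n_genes = 0, seed = 51))
  ip <- simulate_library(g$genome, g$repeats, g$genes,
                         library_spec("IP", n_reads = 40000,
                                      enriched_targets = c(TGT = 8),
                                      seed = 52))
  ctl <- simulate_library(g$genome, g$repeats, g$genes,
                          library_spec("control", n_reads = 40000,
                                       seed = 53))
  # no planted duplicates, so no dedup (position-collision removal at this
  # depth would deflate the dense windows and bias the ratio down)
  ra <- toy_align(ip$reads, ip$genome, 100)
  rb <- toy_align(ctl$reads, ctl$genome, 100)
  w <- scan_windows(ra, rb, g$genome)
  ins <- g$repeats[1]
  over <- w[start >= ins$start & end <= ins$end]
  ratio <- sum(over$k_a) / sum(over$k_b)
  expect_gt(ratio, 8 * 0.7)
  expect_lt(ratio, 8 * 1.3)
})

test_that("dispersion recovery: Poisson data gives ~0, NB data ~alpha", {
  set.seed(61)
  mu <- runif(10000, 5, 50)
  pois <- cbind(rpois(10000, mu), rpois(10000, mu), rpois(10000, mu),
                rpois(10000, mu), rpois(10000, mu), rpois(10000, mu))
  fp <- fit_dispersion(pois, rep(c("A", "B"), each = 3))
  expect_lt(abs(fp$alpha), 0.05)
  nb <- sapply(1:6, function(i) rnbinom(10000, mu = mu, size = 1 / 0.5))
  fn <- fit_dispersion(nb, rep(c("A", "B"), each = 3))
  expect_gt(fn$alpha, 0.35); expect_lt(fn$alpha, 0.65)
  # constant counts: zero variance clamps to Poisson
  const <- matrix(7, nrow = 50, ncol = 4)
  expect_equal(fit_dispersion(const, c("A", "A", "B", "B"))$alpha, 0)
  expect_error(fit_dispersion(pois[, 1:3], c("A", "A", "B")), "replicates")
})

test_that("regions merge across small same-direction gaps only", {
  w <- data.table(chrom = "chr1",
                  start = c(1001L, 1901L, 5001L, 6001L, 8001L, 8101L),
                  end = c(1500L, 2400L, 5500L, 6500L, 8500L, 8600L),
                  k_a = c(50, 50, 50, 50, 50, 5),
                  k_b = c(5, 5, 5, 5, 5, 50),
                  p_value = 1e-9, p_adjusted = 1e-9,
                  direction = c("enriched", "enriched", "enriched",
                                "enriched", "enriched", "depleted"))
  reg <- merge_regions(w, merge_gap = 500, alpha = 1e-5)
  # gap 400 merges; gap exactly 500 does not; opposite directions never
  expect_equal(nrow(reg), 5L)
  expect_equal(reg[1, .(start, end)], data.table(start = 1001L,
                                                 end = 2400L))
  expect_equal(reg[2, .(start, end)], data.table(start = 5001L,
                                                 end = 5500L))
  expect_equal(reg[3, .(start, end)], data.table(start = 6001L,
                                                 end = 6500L))
  expect_true(all(reg$direction[1:4] == "enriched"))
  expect_equal(reg[5, direction], "depleted")
})

test_that("merging is idempotent and order-independent", {
  w <- data.table(chrom = "chr1",
                  start = c(3001L, 1001L, 1101L, 1201L),
                  end = c(3500L, 1500L, 1600L, 1700L),
                  k_a = 50, k_b = 5, p_value = 1e-9, p_adjusted = 1e-9,
                  direction = "enriched")
  r1 <- merge_regions(w)
  r2 <- merge_regions(w[c(3, 1, 4, 2)])
  expect_equal(r1, r2)
  # remerging the merged regions (as 1-window pseudo-windows) is stable
  again <- r1[, .(chrom, start, end, k_a = 50, k_b = 5, p_value = 1e-9,
                  p_adjusted = 1e-9, direction)]
  expect_equal(merge_regions(again)[, .(chrom, start, end, direction)],
               r1[, .(chrom, start, end, direction)])
})

test_that("peak height is the maximum normalised IP coverage in a region", {
  rec <- make_records(c("a", "b", "c"), "chr1", c(1001, 1010, 1020),
                      c(1036, 1045, 1055))
  cov <- weighted_coverage(rec, c(chr1 = 3000L), e = 0.5)
  w <- data.table(chrom = "chr1", start = 901L, end = 1400L, k_a = 10,
                  k_b = 0, p_value = 1e-9, p_adjusted = 1e-9,
                  direction = "enriched")
  reg <- merge_regions(w, coverage = cov)
  # three overlapping weight-1 reads, scaled by 1/e = 2 -> height 6
  expect_equal(reg$peak_height, 6)
})

test_that("element-level test recovers planted enrichment and stays quiet
           under the null", {
  g <- small_genome()
  ip <- simulate_library(g$genome, g$repeats, g$genes,
                         library_spec("IP", n_reads = 20000,
                                      enriched_targets = c(L1_A = 8),
                                      seed = 71))
  ctl <- simulate_library(g$genome, g$repeats, g$genes,
                          library_spec("control", n_reads = 20000,
                                       seed = 72))
  ra <- toy_align(ip$reads, ip$genome, 100)
  rb <- toy_align(ctl$reads, ctl$genome, 100)
  el <- element_enrichment(ra, rb, g$repeats)
  expect_lt(el[element == "L1_A", p_adjusted], 1e-5)
  expect_equal(el[element == "L1_A", direction], "enriched")
  expect_gt(el[element == "L1_A", log2fc], 2)
  expect_gt(el[element == "B1_B", p_adjusted], 1e-5)
  # identical libraries: no significant elements, log2fc exactly 0
  el0 <- element_enrichment(ra, ra, g$repeats)
  expect_true(all(el0$p_adjusted > 1e-5))
  expect_equal(el0$log2fc, rep(0, nrow(el0)))
  expect_equal(el0$p_value, rep(1, nrow(el0)))
})
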