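# Synthetic genome and library generation.

test_that("identical seeds give byte-identical genomes and libraries", {
  spec <- genome_spec(30000, te_families = list(te_family("L1_A")),
                      n_genes = 2, seed = 7)
  g1 <- build_genome(spec)
  g2 <- build_genome(spec)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$repeats, g2$repeats)
  expect_identical(g1$genes, g2$genes)
  ls <- library_spec("IP", n_reads = 500, seed = 3)
  s1 <- simulate_library(g1$genome, g1$repeats, g1$genes, ls)
  s2 <- simulate_library(g2$genome, g2$repeats, g2$genes, ls)
  expect_identical(as.character(s1$reads), as.character(s2$reads))
  expect_identical(s1$truth, s2$truth)
})

test_that("zero divergence makes all copies of a family identical", {
  g <- build_genome(genome_spec(
    20000, te_families = list(te_family("L1_A", n_copies = 2,
                                        divergence = 0)),
    n_genes = 0, seed = 11))
  ins <- g$repeats[element == "L1_A"]
  expect_equal(nrow(ins), 2L)
  seqs <- vapply(seq_len(2L), function(i) {
    s <- Biostrings::subseq(g$genome[[ins$chrom[i]]], ins$start[i],
                            ins$end[i])
    if (ins$strand[i] == "-") s <- Biostrings::reverseComplement(s)
    as.character(s)
  }, character(1L))
  expect_identical(seqs[1L], seqs[2L])
  expect_equal(ins$divergence, c(0, 0))
})

test_that("copy-to-consensus divergence matches the binomial expectation", {
  # 40 copies at rate 0.2 over 300 bp: mean substitutions 60, sd ~6.9;
  # the mean over copies should sit within 4 standard errors
  g <- build_genome(genome_spec(
    50000, te_families = list(te_family("L1_div", n_copies = 40,
                                        consensus_length = 300,
                                        divergence = 0.2)),
    n_genes = 0, seed = 5))
  subs <- g$repeats[element == "L1_div", divergence] * 300
  expect_equal(length(subs), 40L)
  se <- sqrt(300 * 0.2 * 0.8 / 40)
  expect_lt(abs(mean(subs) - 60), 4 * se)
})

test_that("genes have non-overlapping exons and intervals stay in bounds", {
  g <- small_genome()
  for (gid in unique(g$genes$gene_id)) {
    ex <- g$genes[gene_id == gid][order(start)]
    if (nrow(ex) > 1L) {
      expect_true(all(ex$start[-1L] > ex$end[-nrow(ex)]))
    }
  }
  lens <- setNames(Biostrings::width(g$genome), names(g$genome))
  expect_true(all(g$repeats$end <= lens[g$repeats$chrom]))
  expect_true(all(g$genes$end <= lens[g$genes$chrom]))
  expect_true(all(g$repeats$start >= 1L), all(g$genes$start >= 1L))
})

test_that("infeasible packing raises a placement error", {
  expect_error(
    build_genome(genome_spec(
      1000, te_families = list(te_family("L1_A", n_copies = 10,
                                         consensus_length = 300)),
      n_genes = 0, seed = 1)),
    "placement")
})

test_that("read start positions are uniform without enrichment", {
  # chi-square over 10 equal tiles, not significant at 0.01 in >= 95% of
  # seeds
  g <- build_genome(genome_spec(50000, n_genes = 0, seed = 2))
  pvals <- vapply(1:20, function(s) {
    sim <- simulate_library(g$genome, g$repeats, g$genes,
                            library_spec("control", n_reads = 2000,
                                         seed = s))
    tiles <- cut(sim$truth$start, breaks = seq(0, 50000, length.out = 11))
    suppressWarnings(chisq.test(table(tiles))$p.value)
  }, numeric(1L))
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("duplicate_rate plants the stated number of exact copies", {
  g <- build_genome(genome_spec(30000, n_genes = 0, seed = 2))
  sim <- simulate_library(g$genome, g$repeats, g$genes,
                          library_spec("IP", n_reads = 1000,
                                       duplicate_rate = 0.5, seed = 9))
  dups <- sim$truth[!is.na(duplicate_of)]
  expect_equal(nrow(dups), 500L)
  # duplicates are exact copies of their originals
  orig <- sim$truth[dups$duplicate_of, on = "read_id"]
  expect_identical(dups[, .(chrom, start, end, strand)],
                   orig[, .(chrom, start, end, strand)])
  expect_identical(unname(as.character(sim$reads[dups$read_id])),
                   unname(as.character(sim$reads)[
                     match(dups$duplicate_of, sim$truth$read_id)]))
})

test_that("planted fold enrichment is realised as a per-base density ratio", {
  g <- build_genome(genome_spec(
    100000, te_families = list(te_family("L1_A", n_copies = 2,
                                         consensus_length = 1000,
                                         divergence = 0)),
    n_genes = 0, seed = 3))
  sim <- simulate_library(g$genome, g$repeats, g$genes,
                          library_spec("IP", n_reads = 50000,
                                       enriched_targets = c(L1_A = 8),
                                       seed = 4))
  tgt_len <- g$repeats[element == "L1_A", sum(end - start + 1)]
  n_tgt <- nrow(sim$truth[source_name == "L1_A"])
  n_bg <- nrow(sim$truth[source_name == "background"])
  dens_ratio <- (n_tgt / tgt_len) / (n_bg / (100000 - tgt_len))
  expect_gt(dens_ratio, 8 * 0.85)
  expect_lt(dens_ratio, 8 * 1.15)
})

test_that("read sequences match the genome at their true loci", {
  g <- small_genome()
  sim <- simulate_library(g$genome, g$repeats, g$genes,
                          library_spec("IP", n_reads = 200, seed = 6))
  idx <- sample.int(nrow(sim$truth), 50)
  for (i in idx) {
    tr <- sim$truth[i]
    s <- Biostrings::subseq(sim$genome[[tr$chrom]], tr$start, tr$end)
    if (tr$strand == "-") s <- Biostrings::reverseComplement(s)
    expect_identical(as.character(sim$reads[[tr$read_id]]),
                     as.character(s))
  }
})

test_that("unknown enrichment targets are rejected by name", {
  g <- small_genome()
  expect_error(
    simulate_library(g$genome, g$repeats, g$genes,
                     library_spec("IP", n_reads = 100,
                                  enriched_targets = c(NOPE = 4),
                                  seed = 1)),
    "NOPE")
})

test_that("motif planting writes the pentamer at target instance centres", {
  g <- build_genome(genome_spec(
    30000, te_families = list(te_family("L1_A", n_copies = 2,
                                        divergence = 0)),
    n_genes = 0, seed = 13))
  sim <- simulate_library(g$genome, g$repeats, g$genes,
                          library_spec("IP", n_reads = 100,
                                       enriched_targets = c(L1_A = 4),
                                       motif_at_sites = "UGUGU",
                                       seed = 2))
  ins <- g$repeats[element == "L1_A"]
  for (i in seq_len(nrow(ins))) {
    ctr <- (ins$start[i] + ins$end[i]) %/% 2L
    s <- as.character(Biostrings::subseq(sim$genome[[ins$chrom[i]]],
                                         ctr - 2L, ctr + 2L))
    expect_identical(s, "TGTGT")
  }
})
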