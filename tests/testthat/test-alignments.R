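# Weighted alignment records, deduplication and mapping strategies.

test_that("weights follow the uniform 1/n rule and conserve read weight", {
  rec <- make_records(c("r1", "r2", "r2", "r3", "r3", "r3", "r3"),
                      "chr1", c(1, 10, 50, 100, 200, 300, 400),
                      c(20, 29, 69, 119, 219, 319, 419))
  expect_equal(rec[read_id == "r1", weight], 1)
  expect_equal(rec[read_id == "r2", weight], c(0.5, 0.5))
  expect_equal(rec[read_id == "r3", weight], rep(0.25, 4))
  sums <- rec[, sum(weight), by = read_id]$V1
  expect_equal(sums, rep(1, 3))
  expect_true(all(abs(rec$weight * rec$n_alignments - 1) < 1e-12))
})

test_that("toy_align reports a duplicated locus with weight 0.5 each", {
  core <- paste(rep("ACGTTGCA", 5), collapse = "")   # 40 bp, planted twice
  pad1 <- strrep("A", 60); pad2 <- strrep("C", 60); pad3 <- strrep("G", 60)
  genome <- Biostrings::DNAStringSet(
    c(chr1 = paste0(pad1, core, pad2, core, pad3)))
  reads <- Biostrings::DNAStringSet(c(dbl = core))
  rec <- toy_align(reads, genome, m_cap = 100)
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$weight, c(0.5, 0.5))
  expect_equal(rec$n_alignments, c(2L, 2L))
  expect_equal(sort(rec$start), c(61L, 161L))
})

test_that("toy_align agrees with a brute-force scan of every offset", {
  g <- build_genome(genome_spec(
    5000, te_families = list(te_family("L1_A", n_copies = 2,
                                       consensus_length = 100,
                                       divergence = 0)),
    n_genes = 0, seed = 21))
  sim <- simulate_library(g$genome, g$repeats, g$genes,
                          library_spec("IP", n_reads = 25, read_length = 30,
                                       enriched_targets = c(L1_A = 10),
                                       seed = 22))
  rec <- toy_align(sim$reads, sim$genome, m_cap = 100)
  for (rid in names(sim$reads)) {
    exp_hits <- brute_force_align(as.character(sim$reads[[rid]]),
                                  sim$genome)
    got <- rec[read_id == rid][order(chrom, start, strand)]
    setorder(exp_hits, chrom, start, strand)
    expect_equal(got[, .(chrom, start, end, strand)], exp_hits,
                 ignore_attr = TRUE)
  }
})

test_that("reads over the m_cap are suppressed entirely and counted", {
  core <- strrep("ACGTTGCAGT", 3)  # 30 bp planted at 3 loci
  genome <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("A", 40), core, strrep("C", 40), core, strrep("G", 40), core,
    strrep("T", 40))))
  reads <- Biostrings::DNAStringSet(c(multi = core))
  rec <- toy_align(reads, genome, m_cap = 2)
  expect_equal(nrow(rec), 0L)
  expect_equal(attr(rec, "suppressed"), 1L)
  expect_equal(attr(rec, "suppressed_ids"), "multi")
  rec2 <- toy_align(reads, genome, m_cap = 3)
  expect_equal(nrow(rec2), 3L)
  expect_equal(attr(rec2, "suppressed"), 0L)
})

test_that("reads with non-ACGT symbols are skipped with a warning", {
  genome <- Biostrings::DNAStringSet(c(chr1 = strrep("ACGT", 50)))
  reads <- Biostrings::DNAStringSet(c(ok = strrep("ACGT", 5),
                                      bad = paste0(strrep("ACG", 6), "NN")))
  expect_warning(rec <- toy_align(reads, genome, 100), "non-ACGT")
  expect_false("bad" %in% rec$read_id)
  expect_true("ok" %in% rec$read_id)
})

test_that("duplicate removal keeps one read per 5'/strand key", {
  rec <- make_records(c("a", "b", "c"), "chr1", c(100, 100, 100),
                      c(135, 135, 135))
  out <- remove_duplicates(rec)
  expect_equal(nrow(out), 1L)
  expect_equal(out$read_id, "a")
  # minus-strand reads key on their 3' coordinate (the 5' end of the read)
  rec2 <- make_records(c("a", "b"), "chr1", c(100, 90), c(135, 135), "-")
  expect_equal(nrow(remove_duplicates(rec2)), 1L)
  # barcodes disambiguate
  out3 <- remove_duplicates(rec, barcodes = c(a = "AA", b = "CC", c = "AA"))
  expect_equal(sort(out3$read_id), c("a", "b"))
})

test_that("duplicate removal is idempotent and handles empty input", {
  g <- small_genome()
  sim <- simulate_library(g$genome, g$repeats, g$genes,
                          library_spec("IP", n_reads = 2000,
                                       duplicate_rate = 0.3, seed = 8))
  rec <- toy_align(sim$reads, sim$genome, 100)
  once <- remove_duplicates(rec)
  twice <- remove_duplicates(once)
  expect_equal(once, twice, ignore_attr = TRUE)
  expect_lt(length(unique(once$read_id)), length(unique(rec$read_id)))
  empty <- rec[0]
  expect_equal(nrow(remove_duplicates(empty)), 0L)
  # weight conservation survives deduplication
  sums <- once[, sum(weight), by = read_id]$V1
  expect_equal(sums, rep(1, length(sums)))
})

test_that("mapping strategies select the stated read sets and nest", {
  g <- small_genome()
  rep_tab <- g$repeats
  # unique read, multi-read inside one element, multi-read across elements
  l1 <- rep_tab[element == "L1_A"][order(start)]
  b1 <- rep_tab[element == "B1_B"][order(start)]
  rec <- assign_weights(data.table(
    read_id = c("uniq", "same", "same", "cross", "cross"),
    chrom = c("chr1", l1$chrom[1:2], l1$chrom[1], b1$chrom[1]),
    start = c(10L, l1$start[1:2] + 5L, l1$start[1] + 5L, b1$start[1] + 5L),
    end = c(45L, l1$start[1:2] + 40L, l1$start[1] + 40L,
            b1$start[1] + 40L),
    strand = "+"))
  uniq <- apply_strategy(rec, "UNIQ", rep_tab)
  same <- apply_strategy(rec, "UNIQ+SameEle", rep_tab)
  multi <- apply_strategy(rec, "MULTI", rep_tab)
  expect_setequal(unique(uniq$read_id), "uniq")
  expect_setequal(unique(same$read_id), c("uniq", "same"))
  expect_setequal(unique(multi$read_id), c("uniq", "same", "cross"))
  expect_true(all(unique(uniq$read_id) %in% unique(same$read_id)))
  expect_true(all(unique(same$read_id) %in% unique(multi$read_id)))
  # weights unchanged by strategy filtering
  expect_equal(same[read_id == "same", weight], c(0.5, 0.5))
  expect_error(apply_strategy(rec, "WHATEVER"), "arg")
})

test_that("strategy nesting holds on simulated multi-copy data", {
  g <- small_genome()
  sim <- simulate_library(g$genome, g$repeats, g$genes,
                          library_spec("IP", n_reads = 3000,
                                       enriched_targets = c(L1_A = 6),
                                       seed = 31))
  rec <- remove_duplicates(toy_align(sim$reads, sim$genome, 100))
  ids <- lapply(c("UNIQ", "UNIQ+SameEle", "MULTI"), function(s)
    unique(apply_strategy(rec, s, g$repeats)$read_id))
  expect_true(all(ids[[1]] %in% ids[[2]]))
  expect_true(all(ids[[2]] %in% ids[[3]]))
  expect_gt(length(ids[[3]]), length(ids[[1]]))
})

test_that("same_element_fraction matches direct enumeration", {
  l1s <- small_genome()$repeats[element == "L1_A"][order(start)]
  b1s <- small_genome()$repeats[element == "B1_B"][order(start)]
  # two multi-reads within L1_A, two spanning L1_A and B1_B
  rec <- assign_weights(data.table(
    read_id = rep(c("w1", "w2", "x1", "x2"), each = 2),
    chrom = "chr1",
    start = c(l1s$start[1:2] + 1L, l1s$start[1:2] + 3L,
              l1s$start[1] + 1L, b1s$start[1] + 1L,
              l1s$start[2] + 1L, b1s$start[2] + 1L),
    end = c(l1s$start[1:2] + 30L, l1s$start[1:2] + 32L,
            l1s$start[1] + 30L, b1s$start[1] + 30L,
            l1s$start[2] + 30L, b1s$start[2] + 30L),
    strand = "+"))
  res <- same_element_fraction(rec, small_genome()$repeats)
  expect_equal(res$fraction, 0.5)
  expect_equal(res$per_read[read_id %in% c("w1", "w2"), frac_top],
               c(1, 1))
  expect_equal(res$per_read[read_id %in% c("x1", "x2"), frac_top],
               c(0.5, 0.5))
  # a single multi-read hitting 3 instances of one element scores 1
  rec3 <- assign_weights(data.table(
    read_id = "y", chrom = "chr1", start = l1s$start + 2L,
    end = l1s$start + 25L, strand = "+"))
  expect_equal(same_element_fraction(rec3,
                                     small_genome()$repeats)$fraction, 1)
  # undefined without multi-reads
  expect_error(same_element_fraction(
    make_records("r1", "chr1", 1, 30), small_genome()$repeats),
    "undefined|multi")
})
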