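# Shared fixtures, all built in code at test time.

library(data.table)

# A small genome with one zero-divergence LINE family (multi-mapping), one
# diverged SINE family (unique-mapping) and a few genes.
small_genome <- function(seed = 42L, genome_length = 100000L) {
  build_genome(genome_spec(
    genome_length,
    te_families = list(
      te_family("L1_A", "LINE", "L1", n_copies = 3L, divergence = 0),
      te_family("B1_B", "SINE", "B1", n_copies = 3L, divergence = 0.2)),
    n_genes = 4L, seed = seed))
}

# Hand-built alignment records.
make_records <- function(read_id, chrom, start, end, strand = "+") {
  assign_weights(data.table(read_id = read_id, chrom = chrom,
                            start = as.integer(start),
                            end = as.integer(end), strand = strand))
}

# Independent brute-force oracle for the conditional exact test: enumerate
# every split (a, b) with a + b = ks in plain (non-log) arithmetic using the
# stated mass functions, include ties at the same relative tolerance as the
# definition, normalise by the total conditional mass.
oracle_exact_p <- function(k_a, k_b, mu_a, mu_b, alpha = 0) {
  ks <- round(k_a) + round(k_b)
  mass <- function(x, mu) {
    if (alpha > 0) dnbinom(x, mu = mu, size = 1 / alpha) else dpois(x, mu)
  }
  probs <- vapply(0:ks, function(a) mass(a, mu_a) * mass(ks - a, mu_b),
                  numeric(1L))
  obs <- probs[round(k_a) + 1L]
  min(1, sum(probs[probs <= obs * (1 + 1e-9)]) / sum(probs))
}

# Poisson-only second oracle via the conditional binomial identity:
# given a + b = ks, a ~ Binomial(ks, mu_a / (mu_a + mu_b)).
oracle_exact_p_binom <- function(k_a, k_b, mu_a, mu_b) {
  ks <- round(k_a) + round(k_b)
  q <- mu_a / (mu_a + mu_b)
  probs <- dbinom(0:ks, ks, q)
  obs <- probs[round(k_a) + 1L]
  min(1, sum(probs[probs <= obs * (1 + 1e-9)]))
}

# Random genome with non-overlapping candidate intervals to serve as an
# annotation space; optionally plant the pentamer (DNA spelling) at a given
# offset from a fraction of the chosen site centres.
motif_fixture <- function(seed, n_sites = 60, plant_frac = 0,
                          offset = 0, pentamer = "TGTGT",
                          genome_length = 120000L) {
  set.seed(seed)
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(
    sample(c("A", "C", "G", "T"), genome_length, replace = TRUE),
    collapse = "")))
  space <- data.table(chrom = "chr1",
                      start = seq(101L, genome_length - 600L, by = 550L))
  space[, end := start + 400L]
  idx <- sample(nrow(space), n_sites)
  # positions uniform within intervals (not lattice-aligned), so observed
  # sites are exchangeable with the uniform null draws
  sites <- data.table(chrom = "chr1",
                      pos = space$start[idx] +
                        as.integer(floor(runif(n_sites) * 401)),
                      strand = "+")
  if (plant_frac > 0) {
    chosen <- seq_len(ceiling(n_sites * plant_frac))
    s <- as.character(genome[[1]])
    for (i in chosen) {
      at <- sites$pos[i] + offset
      substr(s, at, at + nchar(pentamer) - 1L) <- pentamer
    }
    genome <- Biostrings::DNAStringSet(c(chr1 = s))
  }
  list(genome = genome, space = space, sites = sites)
}

# Brute-force exact aligner: compare the read against every offset of every
# chromosome on both strands.
brute_force_align <- function(read, genome) {
  hits <- list()
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(read)))
  w <- nchar(read)
  for (chr in names(genome)) {
    s <- as.character(genome[[chr]])
    for (off in seq_len(nchar(s) - w + 1L)) {
      sub <- substr(s, off, off + w - 1L)
      if (sub == read) {
        hits[[length(hits) + 1L]] <- data.table(
          chrom = chr, start = off, end = off + w - 1L, strand = "+")
      }
      if (sub == rc) {
        hits[[length(hits) + 1L]] <- data.table(
          chrom = chr, start = off, end = off + w - 1L, strand = "-")
      }
    }
  }
  if (length(hits)) rbindlist(hits) else
    data.table(chrom = character(), start = integer(), end = integer(),
               strand = character())
}
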