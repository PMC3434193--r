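# Synthetic genomes, annotations and read libraries with known truth.
#
# The generator plants multi-copy repeat families whose inter-copy divergence
# controls whether reads from them map uniquely or to several loci, plus gene
# models whose exons can receive reads; IP libraries can be enriched over
# chosen elements or genes and can carry a planted pentamer at site centres.

#' Describe a transposable-element family to plant in a synthetic genome
#'
#' @param element Element (subfamily) name, e.g. `"L1_A"`. Third level of the
#'   Class/Family/Element/Instance repeat hierarchy and the unit at which
#'   cross-dataset comparisons are made.
#' @param class Repeat class, one of `"LINE"`, `"SINE"`, `"LTR"`, `"DNA"`,
#'   `"Simple_repeat"`.
#' @param family Repeat family, e.g. `"L1"`.
#' @param n_copies Number of genomic copies (instances) to plant, `>= 1`.
#' @param consensus_length Length in bases of the family consensus.
#' @param divergence Per-base substitution probability applied independently
#'   to each copy, in `[0, 1]`. `0` makes all copies identical (reads from
#'   them multi-map); large values give each copy unique subsequences.
#' @return A list of class `"te_family_spec"`.
#' @export
te_family <- function(element, class = "LINE", family = class,
                      n_copies = 2L, consensus_length = 300L,
                      divergence = 0) {
  class <- match.arg(class, c("LINE", "SINE", "LTR", "DNA", "Simple_repeat"))
  stopifnot(n_copies >= 1L, consensus_length >= 10L,
            divergence >= 0, divergence <= 1)
  structure(list(element = element, class = class, family = family,
                 n_copies = as.integer(n_copies),
                 consensus_length = as.integer(consensus_length),
                 divergence = divergence),
            class = "te_family_spec")
}

#' Describe a synthetic genome
#'
#' @param genome_length Total genome length in bases (split evenly across
#'   chromosomes).
#' @param n_chromosomes Number of chromosomes.
#' @param te_families List of [te_family()] specs to plant.
#' @param n_genes Number of gene models to plant.
#' @param exon_length_range Length-2 integer vector, range of exon lengths.
#' @param n_exons_range Range of exons per gene.
#' @param intron_length_range Range of intron lengths.
#' @param intron_te_fraction Fraction of TE copies placed inside introns
#'   rather than in intergenic space (default 0.2, i.e. most TE copies are
#'   intergenic).
#' @param seed Integer seed; identical specs give byte-identical output.
#' @return A list of class `"genome_spec"`.
#' @export
genome_spec <- function(genome_length = 100000L, n_chromosomes = 1L,
                        te_families = list(), n_genes = 5L,
                        exon_length_range = c(100L, 300L),
                        n_exons_range = c(2L, 4L),
                        intron_length_range = c(200L, 800L),
                        intron_te_fraction = 0.2, seed = 1L) {
  stopifnot(genome_length > 0, n_chromosomes >= 1L, n_genes >= 0L,
            intron_te_fraction >= 0, intron_te_fraction <= 1,
            length(exon_length_range) == 2L, length(n_exons_range) == 2L)
  if (length(te_families) && !all(vapply(te_families, inherits,
                                         logical(1L), "te_family_spec"))) {
    stop("te_families must be a list of te_family() specs")
  }
  structure(list(genome_length = as.integer(genome_length),
                 n_chromosomes = as.integer(n_chromosomes),
                 te_families = te_families, n_genes = as.integer(n_genes),
                 exon_length_range = as.integer(exon_length_range),
                 n_exons_range = as.integer(n_exons_range),
                 intron_length_range = as.integer(intron_length_range),
                 intron_te_fraction = intron_te_fraction,
                 seed = as.integer(seed)),
            class = "genome_spec")
}

# Pick a non-overlapping placement of an interval of length len on the
# chromosomes described by `lens`, given already-occupied intervals
# (data.table chrom/start/end). Rejection sampling; errors when packing fails.
place_interval <- function(len, lens, occupied, max_tries = 500L) {
  ok_chr <- names(lens)[lens >= len]
  if (!length(ok_chr)) stop("placement error: interval of length ", len,
                            " does not fit on any chromosome")
  for (i in seq_len(max_tries)) {
    chr <- if (length(ok_chr) == 1L) ok_chr else
      sample(ok_chr, 1L, prob = lens[ok_chr])
    s <- sample.int(lens[[chr]] - len + 1L, 1L)
    e <- s + len - 1L
    occ <- occupied[chrom == chr]
    if (!nrow(occ) || !any(occ$start <= e & occ$end >= s)) {
      return(list(chrom = chr, start = s, end = e))
    }
  }
  stop("placement error: could not place interval of length ", len,
       " after ", max_tries, " attempts; genome too crowded")
}

#' Build a synthetic genome with planted repeat copies and gene models
#'
#' Chromosome backgrounds are uniform random DNA. Each repeat family gets a
#' random consensus; each copy is the consensus with independent per-base
#' substitutions at the family's divergence rate, written into the genome at
#' a non-overlapping location. A configurable fraction of TE copies is placed
#' inside gene introns, the rest in intergenic space. Gene exons never
#' overlap each other.
#'
#' @param spec A [genome_spec()].
#' @return A list with elements `genome` (named [Biostrings::DNAStringSet]),
#'   `repeats` (data.table: chrom, start, end, strand, instance_id, element,
#'   family, class, divergence = realised substitutions per base),
#'   `genes` (data.table of exon rows: gene_id, chrom, start, end, strand),
#'   and `truth` (the repeats table plus placement context,
#'   `genic_context` in intronic/intergenic). Coordinates are 1-based
#'   inclusive.
#' @examples
#' spec <- genome_spec(20000, te_families = list(te_family("L1_A")), seed = 7)
#' g <- build_genome(spec)
#' g$repeats
#' @export
build_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$seed, {
    chr_len <- spec$genome_length %/% spec$n_chromosomes
    lens <- setNames(rep(chr_len, spec$n_chromosomes),
                     paste0("chr", seq_len(spec$n_chromosomes)))
    seqs <- lapply(lens, random_dna)

    occupied <- data.table(chrom = character(), start = integer(),
                           end = integer())
    # genes first: exon/intron structure laid out left to right
    gene_rows <- list(); intron_rows <- list()
    for (gi in seq_len(spec$n_genes)) {
      nex <- sample(seq(spec$n_exons_range[1L], spec$n_exons_range[2L]), 1L)
      exl <- sample(seq(spec$exon_length_range[1L],
                        spec$exon_length_range[2L]), nex, replace = TRUE)
      inl <- if (nex > 1L)
        sample(seq(spec$intron_length_range[1L],
                   spec$intron_length_range[2L]), nex - 1L, replace = TRUE)
      else integer()
      span <- sum(exl) + sum(inl)
      pl <- place_interval(span, lens, occupied)
      strand <- sample(c("+", "-"), 1L)
      pos <- pl$start
      gid <- sprintf("gene%03d", gi)
      for (k in seq_len(nex)) {
        gene_rows[[length(gene_rows) + 1L]] <- data.table(
          gene_id = gid, chrom = pl$chrom, start = pos,
          end = pos + exl[k] - 1L, strand = strand)
        pos <- pos + exl[k]
        if (k < nex) {
          intron_rows[[length(intron_rows) + 1L]] <- data.table(
            gene_id = gid, chrom = pl$chrom, start = pos,
            end = pos + inl[k] - 1L, strand = strand)
          pos <- pos + inl[k]
        }
      }
      occupied <- rbind(occupied,
                        data.table(chrom = pl$chrom, start = pl$start,
                                   end = pl$end))
    }
    genes <- if (length(gene_rows)) rbindlist(gene_rows) else
      data.table(gene_id = character(), chrom = character(),
                 start = integer(), end = integer(), strand = character())
    introns <- if (length(intron_rows)) rbindlist(intron_rows) else NULL
    # introns become available for intronic TE placement
    intron_occupied <- data.table(chrom = character(), start = integer(),
                                  end = integer())

    rep_rows <- list()
    inst <- 0L
    for (fam in spec$te_families) {
      consensus <- random_dna(fam$consensus_length)
      for (ci in seq_len(fam$n_copies)) {
        inst <- inst + 1L
        copy_seq <- mutate_dna(consensus, fam$divergence)
        realised <- sum(strsplit(copy_seq, "")[[1L]] !=
                          strsplit(consensus, "")[[1L]]) /
          fam$consensus_length
        want_intronic <- !is.null(introns) &&
          runif(1L) < spec$intron_te_fraction
        placed <- NULL
        if (want_intronic) {
          cand <- introns[(end - start + 1L) >= fam$consensus_length]
          if (nrow(cand)) {
            # try introns not already holding a TE copy
            for (t in seq_len(20L)) {
              row <- cand[sample.int(nrow(cand), 1L)]
              s <- row$start + sample.int(
                row$end - row$start + 2L - fam$consensus_length, 1L) - 1L
              e <- s + fam$consensus_length - 1L
              occ <- intron_occupied[chrom == row$chrom]
              if (!nrow(occ) || !any(occ$start <= e & occ$end >= s)) {
                placed <- list(chrom = row$chrom, start = s, end = e,
                               ctx = "intronic")
                intron_occupied <- rbind(
                  intron_occupied,
                  data.table(chrom = row$chrom, start = s, end = e))
                break
              }
            }
          }
        }
        if (is.null(placed)) {
          pl <- place_interval(fam$consensus_length, lens, occupied)
          occupied <- rbind(occupied,
                            data.table(chrom = pl$chrom, start = pl$start,
                                       end = pl$end))
          placed <- list(chrom = pl$chrom, start = pl$start, end = pl$end,
                         ctx = "intergenic")
        }
        strand <- sample(c("+", "-"), 1L)
        ins <- if (strand == "+") copy_seq else
          as.character(reverseComplement(DNAString(copy_seq)))
        substr(seqs[[placed$chrom]], placed$start, placed$end) <- ins
        rep_rows[[length(rep_rows) + 1L]] <- data.table(
          chrom = placed$chrom, start = placed$start, end = placed$end,
          strand = strand,
          instance_id = sprintf("%s#%03d", fam$element, ci),
          element = fam$element, family = fam$family, class = fam$class,
          divergence = realised, genic_context = placed$ctx)
      }
    }
    repeats <- if (length(rep_rows)) rbindlist(rep_rows) else
      data.table(chrom = character(), start = integer(), end = integer(),
                 strand = character(), instance_id = character(),
                 element = character(), family = character(),
                 class = character(), divergence = numeric(),
                 genic_context = character())
    setorder(repeats, chrom, start)
    genome <- DNAStringSet(unlist(seqs))
    list(genome = genome,
         repeats = repeats[, !"genic_context"],
         genes = genes,
         truth = copy(repeats))
  })
}

#' Describe a simulated sequencing library
#'
#' @param role One of `"IP"`, `"control"`, `"expression"`. Purely a label
#'   plus a default for `strand_sense_fraction` (0.5 for IP/control where
#'   crosslinked fragments come off both strands; 1 for expression, where
#'   reads follow the annotated transcript strand).
#' @param n_reads Total number of reads (including PCR duplicates).
#' @param read_length Read length in bases (single-end, error-free).
#' @param enriched_targets Named numeric vector mapping repeat Element names
#'   or gene ids to per-base fold enrichment over background (`f >= 0`; the
#'   per-base read density over a target is `f` times background density).
#' @param motif_at_sites Optional pentamer (RNA or DNA alphabet, e.g.
#'   `"UGUGU"`) written into the genome at the centre of every enriched
#'   target instance before reads are sampled; `NULL` to disable.
#' @param duplicate_rate Fraction of reads that are exact PCR copies of
#'   other reads in the library, in `[0, 1)`.
#' @param replicate_id Integer replicate label.
#' @param strand_sense_fraction Probability that a read drawn from an
#'   annotated target is on the target's annotated strand; background reads
#'   are stranded 50/50.
#' @param seed Integer seed.
#' @return A list of class `"library_spec"`.
#' @export
library_spec <- function(role = c("IP", "control", "expression"),
                         n_reads = 10000L, read_length = 36L,
                         enriched_targets = numeric(),
                         motif_at_sites = NULL, duplicate_rate = 0,
                         replicate_id = 1L,
                         strand_sense_fraction = NULL, seed = 1L) {
  role <- match.arg(role)
  stopifnot(n_reads >= 1L, read_length >= 10L,
            duplicate_rate >= 0, duplicate_rate < 1,
            all(enriched_targets >= 0))
  if (is.null(strand_sense_fraction)) {
    strand_sense_fraction <- if (role == "expression") 1 else 0.5
  }
  stopifnot(strand_sense_fraction >= 0, strand_sense_fraction <= 1)
  structure(list(role = role, n_reads = as.integer(n_reads),
                 read_length = as.integer(read_length),
                 enriched_targets = enriched_targets,
                 motif_at_sites = motif_at_sites,
                 duplicate_rate = duplicate_rate,
                 replicate_id = as.integer(replicate_id),
                 strand_sense_fraction = strand_sense_fraction,
                 seed = as.integer(seed)),
            class = "library_spec")
}

#' Simulate a read library from a synthetic genome
#'
#' Reads are error-free fixed-length fragments. Read start loci are drawn
#' from a mixture: each enriched target contributes mass
#' `fold * target_length` and the rest of the genome contributes its length,
#' so the per-base read density over a target is `fold` times background.
#' PCR duplicates are exact copies of already-sampled reads. When
#' `motif_at_sites` is set, the pentamer is written into the genome at the
#' centre of every enriched target instance before sampling, and the
#' (possibly modified) genome is returned.
#'
#' @param genome Named [Biostrings::DNAStringSet].
#' @param repeats Repeat instance table from [build_genome()].
#' @param genes Exon table from [build_genome()].
#' @param spec A [library_spec()].
#' @return List with `reads` (named DNAStringSet), `truth` (data.table:
#'   read_id, chrom, start, end, strand, source_type, source_name,
#'   duplicate_of) and `genome` (identical to the input unless a motif was
#'   planted).
#' @export
simulate_library <- function(genome, repeats, genes, spec) {
  stopifnot(inherits(spec, "library_spec"))
  check_repeats(repeats); check_genes(genes)
  lens <- chrom_lengths(genome)
  L <- sum(lens)
  rl <- spec$read_length

  # resolve targets to instance intervals
  tgt <- spec$enriched_targets
  tgt_tabs <- list()
  if (length(tgt)) {
    for (nm in names(tgt)) {
      rows <- repeats[element == nm]
      if (!nrow(rows)) {
        grows <- genes[gene_id == nm]
        if (!nrow(grows)) {
          stop("enriched target '", nm,
               "' matches no repeat Element and no gene id")
        }
        rows <- grows[, .(chrom, start, end, strand,
                          source_name = gene_id, source_type = "gene")]
      } else {
        rows <- rows[, .(chrom, start, end, strand,
                         source_name = element, source_type = "te")]
      }
      rows[, fold := tgt[[nm]]]
      tgt_tabs[[nm]] <- rows
    }
  }
  targets <- if (length(tgt_tabs)) rbindlist(tgt_tabs) else NULL

  with_seed(spec$seed, {
    if (!is.null(spec$motif_at_sites) && !is.null(targets)) {
      pent <- rna_to_dna(toupper(spec$motif_at_sites))
      for (i in seq_len(nrow(targets))) {
        ctr <- (targets$start[i] + targets$end[i]) %/% 2L
        s <- ctr - (nchar(pent) %/% 2L)
        seqchr <- as.character(genome[[targets$chrom[i]]])
        substr(seqchr, s, s + nchar(pent) - 1L) <- pent
        genome[[targets$chrom[i]]] <- DNAString(seqchr)
      }
    }

    n_dup <- round(spec$n_reads * spec$duplicate_rate)
    n_orig <- spec$n_reads - n_dup

    tgt_mass <- if (is.null(targets)) numeric() else
      targets$fold * (targets$end - targets$start + 1L)
    bg_mass <- L - if (is.null(targets))
      0 else sum(targets$end - targets$start + 1L)
    masses <- c(bg_mass, tgt_mass)
    comp <- sample.int(length(masses), n_orig, replace = TRUE, prob = masses)

    chroms <- character(n_orig); starts <- integer(n_orig)
    strands <- character(n_orig)
    stypes <- character(n_orig); snames <- character(n_orig)
    cum <- cumsum(as.numeric(lens))
    offs <- c(0, head(cum, -1L))

    bg_idx <- which(comp == 1L)
    if (length(bg_idx)) {
      # uniform over the complement of target space, by rejection
      got_chr <- character(0); got_pos <- integer(0)
      tkey <- if (!is.null(targets)) {
        tk <- targets[, .(chrom, start, end)]
        setkey(tk, chrom, start, end)
        tk
      }
      while (length(got_pos) < length(bg_idx)) {
        need <- length(bg_idx) - length(got_pos)
        g <- runif(need) * L
        ci <- findInterval(g, cum) + 1L
        chr <- names(lens)[ci]
        p <- as.integer(floor(g - offs[ci])) + 1L
        p <- pmin(pmax(p, 1L), unname(lens[ci]))
        keep <- rep(TRUE, need)
        if (!is.null(tkey) && nrow(tkey)) {
          q <- data.table(chrom = chr, start = p, end = p)
          hit <- foverlaps(q, tkey, which = TRUE, mult = "first",
                           nomatch = NA)
          keep <- is.na(hit)
        }
        got_chr <- c(got_chr, chr[keep]); got_pos <- c(got_pos, p[keep])
      }
      chroms[bg_idx] <- got_chr
      starts[bg_idx] <- pmin(pmax(got_pos, 1L),
                             unname(lens[got_chr]) - rl + 1L)
      strands[bg_idx] <- sample(c("+", "-"), length(bg_idx), replace = TRUE)
      stypes[bg_idx] <- "background"; snames[bg_idx] <- "background"
    }

    tg_idx <- which(comp > 1L)
    if (length(tg_idx)) {
      rows <- targets[comp[tg_idx] - 1L]
      p <- rows$start +
        as.integer(floor(runif(length(tg_idx)) *
                           (rows$end - rows$start + 1L)))
      chroms[tg_idx] <- rows$chrom
      starts[tg_idx] <- pmin(pmax(p - rl %/% 2L, 1L),
                             unname(lens[rows$chrom]) - rl + 1L)
      sense <- runif(length(tg_idx)) < spec$strand_sense_fraction
      anti <- ifelse(rows$strand == "+", "-", "+")
      strands[tg_idx] <- ifelse(sense, rows$strand, anti)
      stypes[tg_idx] <- rows$source_type; snames[tg_idx] <- rows$source_name
    }
    truth <- data.table(
      read_id = sprintf("r%06d", seq_len(n_orig)),
      chrom = chroms, start = starts, end = starts + rl - 1L,
      strand = strands, source_type = stypes, source_name = snames,
      duplicate_of = NA_character_)
    if (n_dup > 0L) {
      src <- sample.int(n_orig, n_dup, replace = TRUE)
      dup <- truth[src]
      dup[, duplicate_of := read_id]
      dup[, read_id := sprintf("r%06d", n_orig + seq_len(n_dup))]
      truth <- rbind(truth, dup)
    }
    seqs <- character(nrow(truth))
    for (chr in unique(truth$chrom)) {
      idx <- which(truth$chrom == chr)
      v <- Views(genome[[chr]], start = truth$start[idx],
                 end = truth$end[idx])
      s <- as.character(DNAStringSet(v))
      neg <- truth$strand[idx] == "-"
      if (any(neg)) {
        s[neg] <- as.character(reverseComplement(DNAStringSet(s[neg])))
      }
      seqs[idx] <- s
    }
    reads <- DNAStringSet(setNames(seqs, truth$read_id))
    list(reads = reads, truth = truth, genome = genome)
  })
}
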