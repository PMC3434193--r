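# Weighted, deduplicated alignment records and the three mapping strategies.
#
# An alignment record is one reported alignment of one read. All reported
# alignments of a read share n_alignments and each carries weight
# 1/n_alignments, so the total weight of every mapped read is exactly 1 and
# no weight is contributed by mapping quality.

#' Exact-match multi-mapper for synthetic genomes
#'
#' Reports every exact full-length match of each read on both strands of the
#' genome. A read with more matches than `m_cap` is suppressed entirely (not
#' reported at any locus) and counted in the suppression log, mirroring the
#' reporting-cap semantics of short-read aligners. Weights are assigned with
#' the uniform 1/n rule.
#'
#' This is a toy aligner for error-free synthetic reads; it implements no
#' mismatch tolerance and is not a general-purpose alignment tool.
#'
#' @param reads Named [Biostrings::DNAStringSet] of reads. Reads containing
#'   non-ACGT symbols are skipped with a warning.
#' @param genome Named [Biostrings::DNAStringSet].
#' @param m_cap Maximum number of reported alignments per read.
#' @return A data.table of alignment records (read_id, chrom, start, end,
#'   strand, n_alignments, weight, duplicate), 1-based inclusive
#'   coordinates, with attributes `suppressed` (number of reads over the
#'   cap), `suppressed_ids`, and `unmapped` (reads with no exact match).
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = strrep("ACGTAGGCTA", 20)))
#' r <- Biostrings::DNAStringSet(c(r1 = "ACGTAGGCTAACGTAGGCTA"))
#' toy_align(r, g, m_cap = 100)
#' @export
toy_align <- function(reads, genome, m_cap = 100L) {
  stopifnot(is(reads, "DNAStringSet"), is(genome, "DNAStringSet"),
            m_cap >= 1L)
  if (is.null(names(reads)) || anyDuplicated(names(reads))) {
    stop("reads must carry unique names (read ids)")
  }
  chars <- as.character(reads)
  bad <- grepl("[^ACGT]", chars)
  if (any(bad)) {
    warning(sum(bad), " read(s) containing non-ACGT symbols were skipped")
    reads <- reads[!bad]
  }
  if (!length(reads)) {
    return(empty_records())
  }
  lens <- chrom_lengths(genome)
  if (any(Biostrings::width(reads) > max(lens))) {
    stop("read length exceeds the longest chromosome")
  }
  hits <- list()
  for (w in unique(Biostrings::width(reads))) {
    sub <- reads[Biostrings::width(reads) == w]
    pd_fwd <- PDict(sub)
    pd_rev <- PDict(reverseComplement(sub))
    for (chr in names(genome)) {
      for (str in c("+", "-")) {
        m <- matchPDict(if (str == "+") pd_fwd else pd_rev, genome[[chr]])
        ir <- unlist(m)
        if (length(ir)) {
          hits[[length(hits) + 1L]] <- data.table(
            read_id = names(ir), chrom = chr,
            start = IRanges::start(ir), end = IRanges::end(ir),
            strand = str)
        }
      }
    }
  }
  rec <- if (length(hits)) rbindlist(hits) else
    data.table(read_id = character(), chrom = character(),
               start = integer(), end = integer(), strand = character())
  unmapped <- setdiff(names(reads), rec$read_id)
  rec[, n_alignments := .N, by = read_id]
  over <- unique(rec[n_alignments > m_cap, read_id])
  rec <- rec[!read_id %in% over]
  rec[, weight := 1 / n_alignments]
  rec[, duplicate := FALSE]
  setorder(rec, read_id, chrom, start, strand)
  setattr(rec, "suppressed", length(over))
  setattr(rec, "suppressed_ids", over)
  setattr(rec, "unmapped", length(unmapped))
  rec[]
}

empty_records <- function() {
  rec <- data.table(read_id = character(), chrom = character(),
                    start = integer(), end = integer(),
                    strand = character(), n_alignments = integer(),
                    weight = numeric(), duplicate = logical())
  setattr(rec, "suppressed", 0L)
  setattr(rec, "suppressed_ids", character())
  setattr(rec, "unmapped", 0L)
  rec
}

#' Assign uniform per-alignment weights
#'
#' Recomputes `n_alignments` as the number of records per read and sets each
#' record's weight to `1/n`, so the total weight of every read is exactly 1.
#' Weights are uniform across a read's alignments; mapping quality
#' contributes nothing.
#'
#' @param records Alignment-record data.table (minimally read_id, chrom,
#'   start, end, strand).
#' @return The records with `n_alignments` and `weight` (re)computed.
#' @export
assign_weights <- function(records) {
  records <- as.data.table(records)
  if (!nrow(records)) return(empty_records())
  rec <- copy(records)
  rec[, n_alignments := .N, by = read_id]
  rec[, weight := 1 / n_alignments]
  if (!"duplicate" %in% names(rec)) rec[, duplicate := FALSE]
  rec[]
}

#' Remove presumptive PCR duplicates
#'
#' Without barcodes, reads are considered PCR duplicates when their
#' representative alignment (the lexicographically smallest of a read's
#' alignments) has the same 5' position and strand; one read per such key
#' survives, all records of the others are dropped. With random barcodes,
#' the barcode joins the key, so reads at the same position with different
#' barcodes both survive.
#'
#' Operating on whole reads (keyed by a single representative alignment,
#' as duplicate marking on primary alignments does) keeps the per-read
#' weight-conservation invariant intact: exact sequence copies share every
#' alignment, so removing the duplicate read removes all of its records.
#'
#' @param records Alignment records.
#' @param barcodes Optional named character vector of random barcodes,
#'   names = read ids.
#' @return Filtered records; idempotent.
#' @export
remove_duplicates <- function(records, barcodes = NULL) {
  check_records(records)
  if (!nrow(records)) return(copy(as.data.table(records)))
  rec <- copy(as.data.table(records))
  rec[, pos5 := ifelse(strand == "+", start, end)]
  rep_aln <- rec[order(chrom, pos5, strand), .SD[1L],
                 by = read_id, .SDcols = c("chrom", "pos5", "strand")]
  rep_aln[, key_ := paste(chrom, pos5, strand, sep = "\r")]
  if (!is.null(barcodes)) {
    bc <- barcodes[rep_aln$read_id]
    if (anyNA(bc)) stop("barcodes missing for some read ids")
    rep_aln[, key_ := paste(key_, bc, sep = "\r")]
  }
  survivors <- rep_aln[order(read_id), .(read_id = read_id[1L]), by = key_]
  out <- rec[read_id %in% survivors$read_id]
  out[, pos5 := NULL]
  out[]
}

#' Apply a mapping strategy
#'
#' * `UNIQ`: uniquely mapped reads only (`n_alignments == 1`).
#' * `UNIQ+SameEle`: unique reads, plus multi-reads for which some single
#'   repeat Element has an instance overlapping every reported alignment
#'   (weights stay 1/n).
#' * `MULTI`: all weighted records.
#'
#' The read sets are nested: UNIQ is a subset of UNIQ+SameEle, which is a
#' subset of MULTI.
#'
#' @param records Alignment records.
#' @param strategy One of `"UNIQ"`, `"UNIQ+SameEle"`, `"MULTI"`.
#' @param repeats Repeat instance table (required for `UNIQ+SameEle`).
#' @return Filtered records.
#' @export
apply_strategy <- function(records, strategy = c("MULTI", "UNIQ",
                                                 "UNIQ+SameEle"),
                           repeats = NULL) {
  strategy <- match.arg(strategy)
  check_records(records)
  records <- as.data.table(records)
  if (strategy == "MULTI" || !nrow(records)) return(copy(records))
  if (strategy == "UNIQ") return(records[n_alignments == 1L])
  if (is.null(repeats)) stop("UNIQ+SameEle requires a repeat table")
  check_repeats(repeats)
  multi <- records[n_alignments > 1L]
  keep_multi <- character()
  if (nrow(multi)) {
    m <- copy(multi)
    m[, aln_id := .I]
    rk <- repeats[, .(chrom, start, end, element)]
    setkey(rk, chrom, start, end)
    ov <- foverlaps(m[, .(chrom, start, end, aln_id, read_id,
                          n_alignments)],
                    rk, type = "any", nomatch = NULL)
    if (nrow(ov)) {
      # per (read, element): number of distinct alignments touching that
      # element; read kept iff one element covers all of its alignments
      cover <- ov[, .(n_hit = uniqueN(aln_id),
                      n_alignments = n_alignments[1L]),
                  by = .(read_id, element)]
      keep_multi <- unique(cover[n_hit == n_alignments, read_id])
    }
  }
  records[n_alignments == 1L | read_id %in% keep_multi]
}

#' Fraction of multi-reads whose alignments all fall in one repeat Element
#'
#' For each multi-mapped read, the fraction of its alignments assigned to
#' its most frequent repeat Element is computed; the summary value is the
#' proportion of multi-reads for which that fraction is 1 (every alignment
#' overlaps an instance of one Element).
#'
#' @param records Alignment records (must contain at least one multi-read).
#' @param repeats Repeat instance table.
#' @return List with `fraction` (scalar) and `per_read` (data.table:
#'   read_id, n_alignments, frac_top = top-element alignment fraction).
#' @export
same_element_fraction <- function(records, repeats) {
  check_records(records); check_repeats(repeats)
  multi <- as.data.table(records)[n_alignments > 1L]
  if (!nrow(multi)) stop("no multi-mapped reads: fraction is undefined")
  m <- copy(multi)
  m[, aln_id := .I]
  rk <- repeats[, .(chrom, start, end, element)]
  setkey(rk, chrom, start, end)
  ov <- foverlaps(m[, .(chrom, start, end, aln_id, read_id)],
                  rk, type = "any", nomatch = NULL)
  per_el <- ov[, .(n_hit = uniqueN(aln_id)), by = .(read_id, element)]
  top <- per_el[, .(n_top = max(n_hit)), by = read_id]
  per_read <- merge(m[, .(n_alignments = .N), by = read_id], top,
                    by = "read_id", all.x = TRUE)
  per_read[is.na(n_top), n_top := 0L]
  per_read[, frac_top := n_top / n_alignments]
  list(fraction = mean(per_read$frac_top == 1),
       per_read = per_read[, .(read_id, n_alignments, frac_top)])
}
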