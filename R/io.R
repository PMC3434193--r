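# Readers and writers for the external plain-text formats used by the
# pipeline: FASTA (via Biostrings), BED6+ with a weight column, a
# RepeatMasker-style tab table, exon tables and generic TSV. Internal
# coordinates are 1-based inclusive; BED output is 0-based half-open.

#' Write alignment records as BED6+ with a weight column
#'
#' Columns: chrom, start (0-based), end, name (read id), score
#' (n_alignments), strand, weight.
#'
#' @param records Alignment records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed_records <- function(records, path) {
  check_records(records)
  out <- as.data.table(records)[, .(chrom, start = start - 1L, end,
                                    name = read_id, score = n_alignments,
                                    strand, weight)]
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read alignment records from the BED+read-id dialect
#'
#' Expects the columns written by [write_bed_records()]. Weights are
#' recomputed from per-read record counts with [assign_weights()].
#'
#' @param path Input path.
#' @return Alignment-record data.table (1-based coordinates).
#' @export
read_bed_records <- function(path) {
  tab <- fread(path, header = FALSE,
               col.names = c("chrom", "start", "end", "read_id",
                             "score", "strand", "weight")[
                               seq_len(ncol(fread(path, nrows = 1L,
                                                  header = FALSE)))])
  need <- c("chrom", "start", "end", "read_id")
  if (!all(need %in% names(tab))) {
    stop("malformed BED records file: ", path)
  }
  tab[, start := as.integer(start) + 1L]
  assign_weights(tab[, .(read_id, chrom, start, end,
                         strand = if ("strand" %in% names(tab)) strand
                         else "+")])
}

#' Write regions as BED6+ (score = -log10 adjusted p)
#'
#' @param regions Region table from [merge_regions()] (or any table with
#'   chrom, start, end, direction, best_p_adjusted).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed_regions <- function(regions, path) {
  reg <- as.data.table(regions)
  out <- reg[, .(chrom, start = start - 1L, end, name = direction,
                 score = round(-log10(pmax(best_p_adjusted, 1e-300)), 3L),
                 strand = ".")]
  extra <- intersect(c("n_windows", "peak_height"), names(reg))
  if (length(extra)) out <- cbind(out, reg[, ..extra])
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write / read a RepeatMasker-style repeat instance table
#'
#' Tab-delimited with header: chrom, start, end, strand, element, family,
#' class, instance_id (1-based inclusive coordinates).
#'
#' @param repeats Repeat instance table.
#' @param path File path.
#' @return `path` (writer) or the table (reader).
#' @export
write_repeat_table <- function(repeats, path) {
  check_repeats(repeats)
  cols <- intersect(c("chrom", "start", "end", "strand", "element",
                      "family", "class", "instance_id"), names(repeats))
  fwrite(as.data.table(repeats)[, ..cols], path, sep = "\t")
  invisible(path)
}

#' @rdname write_repeat_table
#' @export
read_repeat_table <- function(path) {
  tab <- fread(path, sep = "\t")
  check_repeats(tab)
  tab
}

#' Write / read an exon (gene-model) table
#'
#' Tab-delimited with header: gene_id, chrom, start, end, strand; one row
#' per exon.
#'
#' @param genes Exon table.
#' @param path File path.
#' @return `path` (writer) or the table (reader).
#' @export
write_gene_table <- function(genes, path) {
  check_genes(genes)
  fwrite(as.data.table(genes)[, .(gene_id, chrom, start, end, strand)],
         path, sep = "\t")
  invisible(path)
}

#' @rdname write_gene_table
#' @export
read_gene_table <- function(path) {
  tab <- fread(path, sep = "\t")
  check_genes(tab)
  tab
}

#' Read alignment records from a SAM/BAM file
#'
#' One record per reported alignment; multiplicity is taken from the
#' per-read record count (so secondary alignments must be present in the
#' file). Requires the Rsamtools package.
#'
#' @param path SAM/BAM path.
#' @return Alignment-record data.table.
#' @export
read_alignments_sam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("reading SAM/BAM requires the Rsamtools package")
  }
  bf <- Rsamtools::BamFile(path)
  p <- Rsamtools::ScanBamParam(what = c("qname", "rname", "pos", "qwidth",
                                        "strand"),
                               flag = Rsamtools::scanBamFlag(
                                 isUnmappedQuery = FALSE))
  x <- Rsamtools::scanBam(bf, param = p)[[1L]]
  tab <- data.table(read_id = x$qname, chrom = as.character(x$rname),
                    start = x$pos, end = x$pos + x$qwidth - 1L,
                    strand = as.character(x$strand))
  assign_weights(tab)
}
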