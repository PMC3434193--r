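# RefGene vs repeat annotation with the four-level repeat hierarchy
# (Class / Family / Element / Instance) and Element-level set comparison.

#' Annotate regions against gene exons and repeat instances
#'
#' Precedence: a region overlapping any exon is annotated `RefGene` (even
#' when a repeat lies inside that exon); otherwise a region overlapping a
#' repeat instance is annotated `repeat` with the instance's Element name
#' (ties broken by largest overlap, then leftmost instance); otherwise
#' `intergenic`. Simple repeats whose instances overlap instances of other
#' repeat classes are removed from consideration first. Strand is ignored.
#'
#' `genic_context` records where the region sits irrespective of the label:
#' `exonic`, `intronic` (inside a gene span but touching no exon), or
#' `intergenic`.
#'
#' @param regions data.table with chrom, start, end (1-based inclusive).
#' @param genes Exon table (gene_id, chrom, start, end, strand).
#' @param repeats Repeat instance table.
#' @return The regions with columns category (`RefGene`/`repeat`/
#'   `intergenic`), name (gene id or Element, NA for intergenic) and
#'   genic_context added.
#' @export
annotate_regions <- function(regions, genes, repeats) {
  check_genes(genes); check_repeats(repeats)
  reg <- copy(as.data.table(regions))
  if (!all(c("chrom", "start", "end") %in% names(reg))) {
    stop("regions need chrom, start, end columns")
  }
  bad <- which(!(reg$start >= 1 & reg$end >= reg$start))
  if (length(bad)) {
    stop("malformed region row(s): ", paste(head(bad, 10L), collapse = ", "))
  }
  reg[, region_id := .I]
  reg[, category := "intergenic"]
  reg[, name := NA_character_]
  reg[, genic_context := "intergenic"]

  # drop simple repeats that overlap other repeat classes
  rep_use <- drop_overlapping_simple(repeats)

  if (nrow(genes)) {
    gk <- genes[, .(chrom, start, end, gene_id)]
    setkey(gk, chrom, start, end)
    ov <- foverlaps(reg[, .(chrom, start, end, region_id)], gk,
                    type = "any", nomatch = NULL)
    if (nrow(ov)) {
      ov[, ov_len := pmin(i.end, end) - pmax(i.start, start) + 1L]
      best <- ov[order(-ov_len, start), .SD[1L], by = region_id]
      reg[best, `:=`(category = "RefGene", name = i.gene_id,
                     genic_context = "exonic"),
          on = "region_id"]
    }
    # intronic context: inside a gene span, no exon overlap
    spans <- genes[, .(start = min(start), end = max(end)),
                   by = .(gene_id, chrom)]
    sk <- spans[, .(chrom, start, end)]
    setkey(sk, chrom, start, end)
    ovs <- foverlaps(reg[category != "RefGene",
                         .(chrom, start, end, region_id)],
                     sk, type = "any", nomatch = NULL)
    if (nrow(ovs)) {
      reg[region_id %in% ovs$region_id & category != "RefGene",
          genic_context := "intronic"]
    }
  }
  if (nrow(rep_use)) {
    rk <- rep_use[, .(chrom, start, end, element)]
    setkey(rk, chrom, start, end)
    ov <- foverlaps(reg[category != "RefGene",
                        .(chrom, start, end, region_id)],
                    rk, type = "any", nomatch = NULL)
    if (nrow(ov)) {
      ov[, ov_len := pmin(i.end, end) - pmax(i.start, start) + 1L]
      best <- ov[order(-ov_len, start), .SD[1L], by = region_id]
      reg[best, `:=`(category = "repeat", name = i.element),
          on = "region_id"]
    }
  }
  reg[, region_id := NULL]
  reg[]
}

# Remove Simple_repeat instances that overlap instances of any other class.
drop_overlapping_simple <- function(repeats) {
  simple <- repeats[class == "Simple_repeat"]
  other <- repeats[class != "Simple_repeat"]
  if (!nrow(simple) || !nrow(other)) return(copy(repeats))
  ok <- other[, .(chrom, start, end)]
  setkey(ok, chrom, start, end)
  s <- copy(simple)[, aln_id := .I]
  hit <- foverlaps(s[, .(chrom, start, end, aln_id)], ok,
                   type = "any", nomatch = NULL)
  rbind(other, simple[!unique(hit$aln_id)])
}

#' Fraction of repeat-labelled regions that are intergenic
#'
#' @param labeled Output of [annotate_regions()].
#' @return List with `fraction`, `n_intergenic`, `n_repeat`.
#' @export
genic_fraction <- function(labeled) {
  lab <- as.data.table(labeled)
  rep_lab <- lab[category == "repeat"]
  if (!nrow(rep_lab)) stop("no repeat-labelled regions")
  n_int <- sum(rep_lab$genic_context == "intergenic")
  list(fraction = n_int / nrow(rep_lab),
       n_intergenic = n_int, n_repeat = nrow(rep_lab))
}

#' Compare two element sets
#'
#' Cross-comparisons between runs, strategies or datasets are made at the
#' Element level of the repeat hierarchy (instances are not conserved
#' across datasets, and multi-mapped reads cannot pin down instances).
#'
#' @param a,b Character vectors of names at a common hierarchy level.
#' @return List with sorted `a_only`, `both`, `b_only` and `counts`
#'   (named integer vector).
#' @export
compare_element_sets <- function(a, b) {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  res <- list(a_only = sort(setdiff(a, b)),
              both = sort(intersect(a, b)),
              b_only = sort(setdiff(b, a)))
  res$counts <- c(a_only = length(res$a_only), both = length(res$both),
                  b_only = length(res$b_only))
  res
}

#' Roll element-level results up the repeat hierarchy
#'
#' @param tab data.table containing element, family, class columns plus
#'   numeric columns to aggregate.
#' @param level `"element"`, `"family"` or `"class"`.
#' @param value Name of the numeric column to sum.
#' @return data.table keyed by the requested level with the summed value.
#' @export
rollup_hierarchy <- function(tab, level = c("element", "family", "class"),
                             value = "raw_a") {
  level <- match.arg(level)
  tab <- as.data.table(tab)
  stopifnot(value %in% names(tab), level %in% names(tab))
  tab[, .(total = sum(get(value))), by = level]
}
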