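# Bin-correlation library normalisation.
#
# Scale factors are fitted on low-abundance background bins so that genuine
# binding signal (and dominant regions such as rRNA repeats) cannot bias the
# factor, which makes this scheme more conservative than library-size (RPM)
# scaling when one library is dominated by a few regions.

#' Weighted counts in adjacent non-overlapping genomic bins
#'
#' Each alignment contributes its weight to exactly one bin: the bin
#' containing its midpoint (a midpoint exactly on a bin boundary goes to the
#' right-hand bin, i.e. bins are half-open). A read is therefore counted at
#' most once in total: three alignments with weights 0.5, 1 and 0.5 in one
#' bin yield a bin count of 2, not 3.
#'
#' @param record_list Named list of alignment-record data.tables, one per
#'   library (weighted, deduplicated).
#' @param chrom_len Named integer vector of chromosome lengths (or a
#'   [Biostrings::DNAStringSet] genome).
#' @param bin_size Bin width in bases; default 10000.
#' @return data.table with columns chrom, bin (0-based index), start, end
#'   and one weighted-count column per library (all bins of the genome,
#'   including empty ones).
#' @export
bin_counts <- function(record_list, chrom_len, bin_size = 10000L) {
  if (bin_size <= 0) stop("bin_size must be positive")
  if (is.null(names(record_list)) || any(names(record_list) == "")) {
    stop("record_list must be a named list of libraries")
  }
  if (is(chrom_len, "DNAStringSet")) chrom_len <- chrom_lengths(chrom_len)
  grid <- rbindlist(lapply(names(chrom_len), function(chr) {
    nb <- as.integer(ceiling(chrom_len[[chr]] / bin_size))
    data.table(chrom = chr, bin = seq_len(nb) - 1L)
  }))
  grid[, start := bin * bin_size + 1L]
  grid[, end := pmin((bin + 1L) * bin_size,
                     chrom_len[chrom])]
  for (lib in names(record_list)) {
    rec <- as.data.table(record_list[[lib]])
    check_records(rec)
    if (nrow(rec)) {
      # 0-based midpoint of [start-1, end); boundary midpoints fall right
      mids <- rec[, .(chrom,
                      bin = as.integer(((start - 1L) + end) %/% 2L %/%
                                         bin_size),
                      weight)]
      agg <- mids[, .(cnt = sum(weight)), by = .(chrom, bin)]
      grid[agg, (lib) := i.cnt, on = c("chrom", "bin")]
      grid[is.na(get(lib)), (lib) := 0]
    } else {
      grid[, (lib) := 0]
    }
  }
  grid[]
}

#' Estimate bin-correlation normalisation factors
#'
#' The library with the largest total weighted count is the reference. For
#' every other library, bins whose maximum count across the pair exceeds the
#' `q`-th quantile are excluded as presumptive signal; over the remaining
#' low-abundance background bins a zero-intercept least-squares line of the
#' library on the reference is fitted, and its slope `e` is the scale
#' factor, so that `L_i ~ e_i * L_r`. Counts are put on the reference scale
#' by dividing by `e`.
#'
#' @param bins Output of [bin_counts()], or a numeric matrix/data.frame of
#'   bin counts with one column per library.
#' @param q Quantile (default 0.75) of the pairwise maximum bin count above
#'   which bins are excluded from the fit.
#' @param min_bins Minimum number of selected background bins (default 50);
#'   fewer is an error.
#' @return List of class `"norm_factors"`: `reference`, `e` (named vector,
#'   `e[reference] == 1`), `n_selected` (bins used per library), `totals`,
#'   and `selected` (logical selection per non-reference library).
#' @export
estimate_factors <- function(bins, q = 0.75, min_bins = 50L) {
  stopifnot(q > 0, q <= 1)
  tab <- as.data.table(bins)
  libcols <- setdiff(names(tab), c("chrom", "bin", "start", "end"))
  if (length(libcols) < 2L) stop("need at least 2 libraries")
  cnt <- as.matrix(tab[, ..libcols])
  if (any(cnt < 0)) stop("bin counts must be non-negative")
  totals <- colSums(cnt)
  reference <- libcols[which.max(totals)]
  e <- setNames(rep(NA_real_, length(libcols)), libcols)
  e[reference] <- 1
  n_selected <- setNames(rep(NA_integer_, length(libcols)), libcols)
  n_selected[reference] <- nrow(cnt)
  selected <- list()
  xr <- cnt[, reference]
  for (lib in setdiff(libcols, reference)) {
    xi <- cnt[, lib]
    mx <- pmax(xr, xi)
    sel <- mx <= quantile(mx, q)
    if (sum(sel) < min_bins) {
      stop("only ", sum(sel), " low-abundance bins selected for '", lib,
           "' (need >= ", min_bins, ")")
    }
    if (all(xr[sel] == 0)) {
      stop("degenerate fit for '", lib, "': reference bins all zero")
    }
    e[lib] <- sum(xr[sel] * xi[sel]) / sum(xr[sel]^2)
    if (e[lib] <= 0) stop("non-positive scale factor for '", lib, "'")
    n_selected[lib] <- sum(sel)
    selected[[lib]] <- sel
  }
  structure(list(reference = reference, e = e, n_selected = n_selected,
                 totals = totals, selected = selected),
            class = "norm_factors")
}

#' @export
print.norm_factors <- function(x, ...) {
  cat("Bin-correlation normalisation factors\n")
  cat("  reference library:", x$reference, "\n")
  for (lib in names(x$e)) {
    cat(sprintf("  %-12s e = %.4f  (total %.1f, %s bins)\n", lib,
                x$e[[lib]], x$totals[[lib]],
                format(x$n_selected[[lib]])))
  }
  invisible(x)
}

#' Express a count on the reference scale
#'
#' @param count Numeric count(s) from `library`.
#' @param library Library id present in `factors`.
#' @param factors A `"norm_factors"` object from [estimate_factors()].
#' @return `count / e[library]`.
#' @export
normalize_count <- function(count, library, factors) {
  stopifnot(inherits(factors, "norm_factors"))
  if (!library %in% names(factors$e)) {
    stop("unknown library '", library, "'")
  }
  count / factors$e[[library]]
}
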