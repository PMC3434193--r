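# Per-element transposable-element expression from mRNA-seq alignments and
# differential abundance between conditions.

#' Per-element expression abundance
#'
#' The abundance of a repeat Element is the sum of the alignment weights of
#' all reads mapped within its instance boundaries on the annotated strand
#' (when `strand_correct`), divided by the total length of the element (sum
#' of its instance lengths), giving per-base units. The unnormalised weight
#' sum is returned alongside for count-based testing.
#'
#' @param records Weighted, deduplicated alignment records.
#' @param repeats Repeat instance table.
#' @param strand_correct Exclude wrong-strand reads (default TRUE;
#'   expression is strand-correct, unlike CLIP counting which deliberately
#'   accepts antisense alignments).
#' @return data.table: element, family, class, count (weight sum),
#'   length_bp, abundance (= count / length_bp). Every element of the table
#'   is reported, including zeros.
#' @export
element_abundance <- function(records, repeats, strand_correct = TRUE) {
  check_records(records); check_repeats(repeats)
  rec <- as.data.table(records)
  hier <- repeats[, .(length_bp = sum(end - start + 1L),
                      family = family[1L], class = class[1L]),
                  by = element]
  if (nrow(rec)) {
    r <- copy(rec)[, aln_id := .I]
    rk <- repeats[, .(chrom, start, end, strand, element)]
    setkey(rk, chrom, start, end)
    ov <- foverlaps(r[, .(chrom, start, end, strand, aln_id, weight)], rk,
                    type = "any", nomatch = NULL)
    if (strand_correct) ov <- ov[strand == i.strand]
    uniq <- unique(ov, by = c("aln_id", "element"))
    cnt <- uniq[, .(count = sum(weight)), by = element]
  } else {
    cnt <- data.table(element = character(), count = numeric())
  }
  out <- merge(hier, cnt, by = "element", all.x = TRUE)
  out[is.na(count), count := 0]
  out[, abundance := count / length_bp]
  setcolorder(out, c("element", "family", "class", "count", "length_bp",
                     "abundance"))
  out[]
}

# DESeq-style median-of-ratios size factors over an element x sample count
# matrix; elements with a zero in any sample are excluded from the
# geometric-mean reference.
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  pos <- rowSums(counts <= 0) == 0
  if (!any(pos)) {
    return(setNames(rep(1, ncol(counts)), colnames(counts)))
  }
  lg <- log(counts[pos, , drop = FALSE])
  ref <- rowMeans(lg)
  sf <- apply(lg, 2L, function(col) exp(median(col - ref)))
  sf / exp(mean(log(sf)))  # centre on geometric mean 1
}

#' Differential element abundance between two conditions
#'
#' Element-level weighted count sums are normalised with median-of-ratios
#' size factors, summed within condition, rounded to integers and tested
#' with the conditional exact test ([exact_pvalue()]); with at least two
#' replicates per condition a common negative-binomial dispersion is
#' estimated from the normalised replicate counts ([fit_dispersion()]),
#' otherwise the Poisson model is used. BH adjustment is across elements.
#' Per-length abundances are for reporting; the test uses counts.
#'
#' @param counts Numeric matrix of element-level weight sums, elements x
#'   samples, with row and column names.
#' @param condition Length-`ncol` factor/character with exactly 2 levels.
#' @param pseudocount Pseudocount for the log2 fold change (condition-mean
#'   normalised counts).
#' @return data.table: element, mean_a, mean_b, log2fc (A over B),
#'   p_value, p_adjusted, direction, with attribute `size_factors` and
#'   `dispersion`. All-zero elements are omitted.
#' @export
differential_abundance <- function(counts, condition, pseudocount = 0.5) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have element rownames")
  condition <- as.character(condition)
  stopifnot(ncol(counts) == length(condition))
  lev <- unique(condition)
  if (length(lev) != 2L) stop("need exactly 2 conditions")
  keep <- rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]
  if (!nrow(counts)) stop("all elements have zero counts")
  sf <- size_factors(counts)
  norm <- sweep(counts, 2L, sf, "/")
  a_cols <- condition == lev[1L]
  b_cols <- condition == lev[2L]
  disp <- 0
  if (sum(a_cols) >= 2L && sum(b_cols) >= 2L) {
    disp <- fit_dispersion(norm, condition)$alpha
  }
  sum_a <- rowSums(norm[, a_cols, drop = FALSE])
  sum_b <- rowSums(norm[, b_cols, drop = FALSE])
  mean_a <- sum_a / sum(a_cols)
  mean_b <- sum_b / sum(b_cols)
  ratio_a <- sum(a_cols) / length(condition)
  p <- exact_pvalue_many(sum_a, sum_b, ratio_a = ratio_a,
                         dispersion = disp)
  out <- data.table(element = rownames(counts),
                    mean_a = mean_a, mean_b = mean_b,
                    log2fc = log2((mean_a + pseudocount) /
                                    (mean_b + pseudocount)),
                    p_value = p, p_adjusted = bh_adjust(p))
  out[, direction := ifelse(log2fc >= 0, "up", "down")]
  setorder(out, p_adjusted, element)
  setattr(out, "size_factors", sf)
  setattr(out, "dispersion", disp)
  out[]
}

#' Concordance between mis-expressed elements and CLIP binding targets
#'
#' @param elevated Character vector of Elements called differentially
#'   expressed (e.g. up-regulated).
#' @param clip_targets Character vector of Elements called as binding
#'   targets.
#' @return List: `n_elevated`, `n_overlap`, `fraction` (share of elevated
#'   elements that are also CLIP targets; `NA` with `empty = TRUE` when no
#'   elements are elevated), and `sets` from [compare_element_sets()].
#' @export
clip_concordance <- function(elevated, clip_targets) {
  elevated <- unique(as.character(elevated))
  clip_targets <- unique(as.character(clip_targets))
  sets <- compare_element_sets(elevated, clip_targets)
  n <- length(elevated)
  list(n_elevated = n,
       n_overlap = length(sets$both),
       fraction = if (n > 0L) length(sets$both) / n else NA_real_,
       empty = n == 0L,
       sets = sets)
}
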