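# Sliding-window and per-element differential binding.
#
# The test conditions on the window total k_S = k_A + k_B and sums, over all
# splits (a, b) with a + b = k_S, the joint probabilities p(a)p(b) that are
# less than or equal to the observed split's, normalised by the total
# conditional probability. p(.) is Poisson, or negative binomial with
# variance mu + alpha * mu^2 when replicates allow a dispersion estimate
# (alpha = 0 recovers Poisson exactly).

#' Conditional exact p-value for a two-library count split
#'
#' Weighted counts are rounded to the nearest integers (ties to even)
#' because the count mass functions require integers. Splits whose joint
#' probability ties the observed one (within a relative tolerance of 1e-9)
#' are included in the sum, and the result lies in (0, 1].
#'
#' @param k_a,k_b Observed (normalised, weighted) counts in libraries A
#'   and B.
#' @param mu_a,mu_b Positive null means for the two libraries; only their
#'   ratio matters under the Poisson model.
#' @param dispersion Negative-binomial dispersion `alpha` in
#'   `var = mu + alpha * mu^2`; 0 (default) gives the Poisson model.
#' @return The conditional exact p-value.
#' @examples
#' exact_pvalue(5, 5, 5, 5)        # observed split is the mode: p = 1
#' exact_pvalue(0, 10, 5, 5)
#' @export
exact_pvalue <- function(k_a, k_b, mu_a, mu_b, dispersion = 0) {
  stopifnot(length(k_a) == 1L, length(k_b) == 1L,
            mu_a > 0, mu_b > 0, dispersion >= 0, k_a >= 0, k_b >= 0)
  a_obs <- round(k_a)
  ks <- a_obs + round(k_b)
  if (ks == 0) stop("window total is zero: no test")
  dens <- function(x, mu) {
    if (dispersion > 0) dnbinom(x, mu = mu, size = 1 / dispersion)
    else dpois(x, mu)
  }
  av <- 0:ks
  pr <- dens(av, mu_a) * dens(ks - av, mu_b)
  tot <- sum(pr)
  if (tot <= 0) return(1)
  obs <- pr[av == a_obs]
  min(1, sum(pr[pr <= obs * (1 + 1e-9)]) / tot)
}

# Vectorised conditional exact test over rounded (a, ks) pairs with a
# symmetric-by-ratio null: mu_a/mu_b fixed across windows, mu scale = ks.
# Deduplicates identical (a, ks) combinations.
exact_pvalue_many <- function(k_a, k_b, ratio_a = 0.5, dispersion = 0) {
  a <- round(k_a); b <- round(k_b); ks <- a + b
  key <- data.table(a = a, ks = ks)
  uk <- unique(key)
  uk[, p_value := vapply(seq_len(.N), function(i) {
    exact_pvalue(uk$a[i], uk$ks[i] - uk$a[i],
                 mu_a = max(uk$ks[i], 1) * ratio_a,
                 mu_b = max(uk$ks[i], 1) * (1 - ratio_a),
                 dispersion = dispersion)
  }, numeric(1L))]
  uk[key, on = c("a", "ks")]$p_value
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment with monotonicity enforcement, preserving the
#' input order.
#'
#' @param p Vector of p-values in (0, 1].
#' @return Adjusted p-values, `p_adjusted >= p` elementwise.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(n / (n:1) * p[o]))
  adj[order(o)]
}

#' Scan the genome in overlapping windows of weighted counts
#'
#' Windows of `window` bp advance by `step` bp (overlapping windows raise
#' the resolution at which region boundaries can be located). An alignment
#' contributes its weight to every window it overlaps. Only windows with a
#' positive total raw count are emitted.
#'
#' @param records_a,records_b Weighted alignment records for the IP (A) and
#'   control (B) libraries.
#' @param chrom_len Named chromosome lengths (or a DNAStringSet genome).
#' @param factors Optional `"norm_factors"`; normalised counts `k_a`, `k_b`
#'   are the raw weighted counts divided by the library's scale factor.
#' @param libs Length-2 character vector naming the two libraries inside
#'   `factors` (default `c("A", "B")`).
#' @param window,step Window size and step in bp; `step > window` is an
#'   error.
#' @return data.table: chrom, start, end, raw_a, raw_b, k_a, k_b.
#' @export
scan_windows <- function(records_a, records_b, chrom_len, factors = NULL,
                         libs = c("A", "B"), window = 500L, step = 100L) {
  if (step > window) stop("step must not exceed window")
  check_records(records_a); check_records(records_b)
  if (is(chrom_len, "DNAStringSet")) chrom_len <- chrom_lengths(chrom_len)
  wins <- rbindlist(lapply(names(chrom_len), function(chr) {
    st <- seq(1L, chrom_len[[chr]], by = step)
    data.table(chrom = chr, start = st,
               end = pmin(st + window - 1L, chrom_len[[chr]]))
  }))
  setkey(wins, chrom, start, end)
  sum_by_window <- function(rec) {
    rec <- as.data.table(rec)
    if (!nrow(rec)) return(rep(0, nrow(wins)))
    ov <- foverlaps(rec[, .(chrom, start, end, weight)], wins,
                    type = "any", nomatch = NULL)
    agg <- ov[, .(cnt = sum(weight)), by = .(chrom, start, end)]
    out <- agg[wins, on = c("chrom", "start", "end")]$cnt
    out[is.na(out)] <- 0
    out
  }
  wins[, raw_a := sum_by_window(records_a)]
  wins[, raw_b := sum_by_window(records_b)]
  wins <- wins[raw_a + raw_b > 0]
  e_a <- e_b <- 1
  if (!is.null(factors)) {
    stopifnot(inherits(factors, "norm_factors"), length(libs) == 2L)
    e_a <- factors$e[[libs[1L]]]
    e_b <- factors$e[[libs[2L]]]
  }
  wins[, k_a := raw_a / e_a]
  wins[, k_b := raw_b / e_b]
  setkey(wins, NULL)
  wins[]
}

#' Test scanned windows for differential binding
#'
#' Applies the conditional exact test to every emitted window under a null
#' that splits the window total in proportion `ratio_a : (1 - ratio_a)`
#' (0.5 when both libraries are on the reference scale), then adjusts over
#' all tested windows with Benjamini-Hochberg.
#'
#' @param windows Output of [scan_windows()].
#' @param dispersion NB dispersion `alpha` (0 = Poisson).
#' @param ratio_a Null expected fraction of the total in library A.
#' @return The windows with p_value, p_adjusted and direction
#'   (`"enriched"` when `k_a > k_b`, else `"depleted"`) added.
#' @export
window_test <- function(windows, dispersion = 0, ratio_a = 0.5) {
  w <- copy(as.data.table(windows))
  if (!nrow(w)) {
    w[, `:=`(p_value = numeric(0), p_adjusted = numeric(0),
             direction = character(0))]
    return(w[])
  }
  w[, p_value := exact_pvalue_many(k_a, k_b, ratio_a = ratio_a,
                                   dispersion = dispersion)]
  w[, p_adjusted := bh_adjust(p_value)]
  w[, direction := ifelse(k_a >= k_b, "enriched", "depleted")]
  w[]
}

#' Estimate a common negative-binomial dispersion from replicates
#'
#' Method-of-moments on per-window mean/variance pairs within each
#' condition, pooled by a zero-intercept regression of the excess variance
#' `v - m` on `m^2`; the slope is `alpha`, clamped to `>= 0` (empirical
#' variance at or below the mean falls back to Poisson).
#'
#' @param counts Numeric matrix, windows x samples.
#' @param condition Factor/character of length `ncol(counts)`; every
#'   condition must have at least 2 replicates.
#' @return List of class `"dispersion_model"` with `kind`
#'   (`"poisson"`/`"negative_binomial"`) and `alpha`.
#' @export
fit_dispersion <- function(counts, condition) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == length(condition))
  if (any(table(condition) < 2L)) {
    stop("need >= 2 replicates per condition; use the Poisson model ",
         "(dispersion = 0) otherwise")
  }
  ms <- NULL; vs <- NULL
  for (cond in unique(condition)) {
    sub <- counts[, condition == cond, drop = FALSE]
    ms <- c(ms, rowMeans(sub))
    vs <- c(vs, apply(sub, 1L, var))
  }
  keep <- ms > 0
  if (!any(keep)) {
    return(structure(list(kind = "poisson", alpha = 0),
                     class = "dispersion_model"))
  }
  alpha <- sum((vs[keep] - ms[keep]) * ms[keep]^2) / sum(ms[keep]^4)
  alpha <- max(0, alpha)
  structure(list(kind = if (alpha > 0) "negative_binomial" else "poisson",
                 alpha = alpha),
            class = "dispersion_model")
}

#' Merge significant windows into regions
#'
#' Windows passing the adjusted-p threshold (and, optionally, a fold-change
#' filter) are merged when they share a direction and are separated by a gap
#' strictly smaller than `merge_gap` base pairs. Merging is idempotent and
#' independent of input order.
#'
#' @param tested Output of [window_test()].
#' @param merge_gap Maximum (exclusive) gap in bp between merged windows.
#' @param alpha Significance threshold on `p_adjusted` (default 1e-5).
#' @param min_fold Optional minimum fold change
#'   `max(k_a, k_b) / min(k_a, k_b)` (pseudocounted) a window must reach.
#' @param pseudocount Pseudocount used in the fold filter.
#' @param coverage Optional per-chromosome normalised IP coverage from
#'   [weighted_coverage()]; when supplied, each region's `peak_height` is
#'   the maximum per-base normalised IP coverage within it.
#' @return data.table of regions: chrom, start, end, direction, n_windows,
#'   best_p_adjusted, peak_height.
#' @export
merge_regions <- function(tested, merge_gap = 500L, alpha = 1e-5,
                          min_fold = NULL, pseudocount = 0.5,
                          coverage = NULL) {
  w <- as.data.table(tested)[p_adjusted < alpha]
  if (!is.null(min_fold) && nrow(w)) {
    fc <- (w$k_a + pseudocount) / (w$k_b + pseudocount)
    w <- w[pmax(fc, 1 / fc) >= min_fold]
  }
  if (!nrow(w)) {
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), direction = character(),
                      n_windows = integer(), best_p_adjusted = numeric(),
                      peak_height = numeric()))
  }
  setorder(w, chrom, start, end)
  # the running maximum end matters because overlapping windows are not
  # end-sorted; group membership is decided against it
  grp <- integer(nrow(w)); g <- 0L; run_end <- -Inf
  for (i in seq_len(nrow(w))) {
    if (i == 1L || w$chrom[i] != w$chrom[i - 1L] ||
        w$direction[i] != w$direction[i - 1L] ||
        (w$start[i] - run_end - 1L) >= merge_gap) {
      g <- g + 1L
      run_end <- w$end[i]
    } else {
      run_end <- max(run_end, w$end[i])
    }
    grp[i] <- g
  }
  w[, region_id := grp]
  reg <- w[, .(chrom = chrom[1L], start = min(start), end = max(end),
               direction = direction[1L], n_windows = .N,
               best_p_adjusted = min(p_adjusted)),
           by = region_id][, !"region_id"]
  reg[, peak_height := NA_real_]
  if (!is.null(coverage)) {
    for (i in seq_len(nrow(reg))) {
      cv <- coverage[[reg$chrom[i]]]
      if (!is.null(cv)) {
        hi <- min(reg$end[i], length(cv))
        reg$peak_height[i] <- max(as.numeric(
          cv[reg$start[i]:hi]))
      }
    }
  }
  reg[]
}

#' Per-base weighted coverage of a library
#'
#' @param records Alignment records.
#' @param chrom_len Named chromosome lengths (or a DNAStringSet genome).
#' @param e Scale factor; weights are divided by it so the coverage is on
#'   the reference scale.
#' @return Named list of [S4Vectors::Rle] coverage vectors, one per
#'   chromosome.
#' @export
weighted_coverage <- function(records, chrom_len, e = 1) {
  check_records(records)
  if (is(chrom_len, "DNAStringSet")) chrom_len <- chrom_lengths(chrom_len)
  rec <- as.data.table(records)
  out <- list()
  for (chr in names(chrom_len)) {
    sub <- rec[chrom == chr]
    out[[chr]] <- if (nrow(sub)) {
      coverage(IRanges(sub$start, sub$end), weight = sub$weight / e,
               width = chrom_len[[chr]])
    } else {
      coverage(IRanges(), width = chrom_len[[chr]])
    }
  }
  out
}

#' Element-level differential binding
#'
#' Weighted counts are summed over every instance of each repeat Element
#' (an alignment overlapping several instances of the same Element counts
#' once; one overlapping instances of two Elements counts once for each),
#' normalised, rounded, exact-tested and BH-corrected across Elements.
#' log2 fold change uses a pseudocount on the normalised counts.
#'
#' @param records_a,records_b Weighted alignment records (IP, control),
#'   already filtered to a mapping strategy if desired.
#' @param repeats Repeat instance table.
#' @param factors Optional `"norm_factors"`; `libs` names the two libraries.
#' @param libs Length-2 library ids inside `factors`.
#' @param dispersion NB dispersion (0 = Poisson).
#' @param pseudocount Pseudocount for the fold change.
#' @return data.table: element, family, class, raw_a, raw_b, k_a, k_b,
#'   log2fc, p_value, p_adjusted, direction. Elements with zero counts in
#'   both libraries are omitted.
#' @export
element_enrichment <- function(records_a, records_b, repeats,
                               factors = NULL, libs = c("A", "B"),
                               dispersion = 0, pseudocount = 0.5) {
  check_repeats(repeats)
  e_a <- e_b <- 1
  if (!is.null(factors)) {
    e_a <- factors$e[[libs[1L]]]
    e_b <- factors$e[[libs[2L]]]
  }
  count_elements <- function(rec) {
    rec <- as.data.table(rec)
    check_records(rec)
    if (!nrow(rec)) {
      return(data.table(element = character(), cnt = numeric()))
    }
    r <- copy(rec)[, aln_id := .I]
    rk <- repeats[, .(chrom, start, end, element)]
    setkey(rk, chrom, start, end)
    ov <- foverlaps(r[, .(chrom, start, end, aln_id, weight)], rk,
                    type = "any", nomatch = NULL)
    uniq <- unique(ov, by = c("aln_id", "element"))
    uniq[, .(cnt = sum(weight)), by = element]
  }
  hier <- unique(repeats[, .(element, family, class)])
  tab <- merge(hier, count_elements(records_a), by = "element", all.x = TRUE)
  setnames(tab, "cnt", "raw_a")
  tab <- merge(tab, count_elements(records_b), by = "element", all.x = TRUE)
  setnames(tab, "cnt", "raw_b")
  tab[is.na(raw_a), raw_a := 0]
  tab[is.na(raw_b), raw_b := 0]
  tab <- tab[raw_a + raw_b > 0]
  if (!nrow(tab)) {
    tab[, `:=`(k_a = numeric(0), k_b = numeric(0), log2fc = numeric(0),
               p_value = numeric(0), p_adjusted = numeric(0),
               direction = character(0))]
    return(tab[])
  }
  tab[, k_a := raw_a / e_a]
  tab[, k_b := raw_b / e_b]
  tab[, log2fc := log2((k_a + pseudocount) / (k_b + pseudocount))]
  tab[, p_value := exact_pvalue_many(k_a, k_b, dispersion = dispersion)]
  tab[, p_adjusted := bh_adjust(p_value)]
  tab[, direction := ifelse(k_a >= k_b, "enriched", "depleted")]
  setorder(tab, p_adjusted, element)
  tab[]
}
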