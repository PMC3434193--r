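# Crosslink-site significance without a control library.
#
# Reads are randomly reassigned to the annotated (gene + repeat) space to
# build a background frequency of per-site read counts; a site with count x
# is scored by p_adj(x) = (mu_x + sigma_x) / p_x, where mu_x and sigma_x are
# the mean and standard deviation of the frequency of count x across the
# randomisations and p_x is the observed frequency. NOTE: a uniform
# randomised background ignores non-random transcription rates and is known
# to be wrong for gene transcripts; calls from this module are
# correspondingly less robust than control-based differential binding.

#' Randomly assign reads to an annotation space and tally site counts
#'
#' Each read start is placed uniformly at random within the concatenated
#' annotation space; a site is a position with at least one read start.
#'
#' @param n_reads Number of reads to place.
#' @param space Interval table (chrom, start, end) of genes and annotated
#'   repetitive regions.
#' @param seed Integer seed.
#' @return data.table: chrom, pos, count (one row per site).
#' @export
randomize_assignment <- function(n_reads, space, seed = 1L) {
  sp <- as.data.table(space)
  if (!nrow(sp)) stop("empty annotation space")
  stopifnot(n_reads >= 1L)
  widths <- as.numeric(sp$end - sp$start + 1L)
  cum <- cumsum(widths)
  L <- cum[length(cum)]
  with_seed(seed, {
    g <- runif(n_reads) * L
    ii <- findInterval(g, cum) + 1L
    off <- as.integer(floor(g - c(0, head(cum, -1L))[ii]))
    tab <- data.table(chrom = sp$chrom[ii], pos = sp$start[ii] + off)
    tab[, .(count = .N), by = .(chrom, pos)][order(chrom, pos)]
  })
}

#' Score crosslink sites against a randomised background
#'
#' The randomisation is iterated `n_iter` times; for every observed count
#' value x, `mu_x` and `sigma_x` are the mean and SD across iterations of
#' the frequency of sites with count x (iterations in which x never occurs
#' contribute frequency 0), and `p_adj(x) = (mu_x + sigma_x) / p_x`. A count
#' never seen in any randomisation gets `mu_x = sigma_x = 0`, hence
#' `p_adj = 0` (maximally significant); this is logged via a message.
#'
#' @param site_counts Integer vector of observed per-site read counts (one
#'   entry per site), or the data.table from [randomize_assignment()]-style
#'   tallies with a `count` column.
#' @param space Annotation space used for the background randomisations.
#' @param n_iter Number of randomisation iterations (default 100).
#' @param n_reads Number of reads per randomisation; defaults to
#'   `sum(site_counts)` so the background matches the observed depth.
#' @param cutoff Significance cutoff on `p_adj` (default 0.01).
#' @param seed Integer seed.
#' @return List of class `"site_stats"`: `stats` (data.table: x, n_sites,
#'   p_x, mu_x, sigma_x, p_adj), `significant` (logical per input site),
#'   `cutoff`, `n_iter`.
#' @export
site_significance <- function(site_counts, space, n_iter = 100L,
                              n_reads = NULL, cutoff = 0.01, seed = 1L) {
  if (is.data.frame(site_counts)) site_counts <- site_counts$count
  site_counts <- as.integer(site_counts)
  if (!length(site_counts)) stop("need at least one observed site")
  stopifnot(n_iter >= 1L, all(site_counts >= 1L))
  if (is.null(n_reads)) n_reads <- sum(site_counts)
  xs <- sort(unique(site_counts))
  n_sites_obs <- length(site_counts)
  p_obs <- vapply(xs, function(x) mean(site_counts == x), numeric(1L))

  freq <- matrix(0, nrow = length(xs), ncol = n_iter)
  for (it in seq_len(n_iter)) {
    rnd <- randomize_assignment(n_reads, space,
                                seed = (as.numeric(seed) %% 1000003) *
                                  1000 + it)
    tot <- nrow(rnd)
    for (j in seq_along(xs)) {
      freq[j, it] <- sum(rnd$count == xs[j]) / tot
    }
  }
  mu <- rowMeans(freq)
  sigma <- apply(freq, 1L, sd)
  if (n_iter == 1L) sigma <- rep(0, length(xs))
  p_adj <- site_padj(mu, sigma, p_obs)
  if (any(mu == 0 & sigma == 0)) {
    message("count value(s) ",
            paste(xs[mu == 0 & sigma == 0], collapse = ", "),
            " never occurred in the randomised background; p_adj = 0")
  }
  stats <- data.table(x = xs,
                      n_sites = vapply(xs, function(x)
                        sum(site_counts == x), integer(1L)),
                      p_x = p_obs, mu_x = mu, sigma_x = sigma,
                      p_adj = p_adj)
  sig_x <- xs[p_adj < cutoff]
  structure(list(stats = stats,
                 significant = site_counts %in% sig_x,
                 cutoff = cutoff, n_iter = n_iter,
                 n_sites = n_sites_obs),
            class = "site_stats")
}

#' Adjusted significance score for a site count
#'
#' `p_adj(x) = (mu_x + sigma_x) / p_x`: the background mean-plus-SD
#' frequency of count x relative to its observed frequency. Values well
#' below 1 flag counts that are far more frequent than the randomised
#' background predicts.
#'
#' @param mu,sigma Background mean and SD of the frequency of count x.
#' @param p Observed frequency of count x (> 0).
#' @return `(mu + sigma) / p`.
#' @examples
#' site_padj(0.001, 0.0005, 0.01)  # 0.15
#' @export
site_padj <- function(mu, sigma, p) {
  stopifnot(all(p > 0), all(mu >= 0), all(sigma >= 0))
  (mu + sigma) / p
}

#' @export
print.site_stats <- function(x, ...) {
  cat("Randomised-background crosslink-site significance\n")
  cat("  NOTE: the uniform randomised background ignores non-random\n",
      "  transcription and is known to be wrong for gene transcripts;\n",
      "  interpret calls accordingly.\n", sep = "")
  cat("  sites:", x$n_sites, " iterations:", x$n_iter,
      " cutoff:", x$cutoff, "\n")
  print(x$stats)
  invisible(x)
}
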