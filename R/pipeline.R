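# End-to-end driver: validated configuration, staged outputs, manifest.

#' Build and validate a pipeline configuration
#'
#' Defaults follow the method's standard settings: 500 bp windows stepped
#' by 100 bp, merge gap 500 bp, adjusted-p threshold 1e-5, 10 kb
#' normalisation bins, UGUGU pentamer over a 51 nt window, 100
#' randomisations.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return Validated config list of class `"repclip_config"`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    window = 500L, step = 100L, merge_gap = 500L, alpha = 1e-5,
    min_fold = NULL, bin_size = 10000L, norm_quantile = 0.75,
    m_cap = 100L, strategy = "MULTI", pentamer = "UGUGU",
    motif_flank = 25L, n_random = 100L, seed = 1L,
    genome = NULL, libraries = NULL, run_motif = FALSE)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  validate_config(cfg)
  structure(cfg, class = "repclip_config")
}

validate_config <- function(cfg) {
  pos <- c("window", "step", "merge_gap", "alpha", "bin_size",
           "norm_quantile", "m_cap", "n_random", "motif_flank")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0) {
      stop("config field '", f, "' must be a positive number")
    }
  }
  if (cfg$alpha > 1) stop("config field 'alpha' must be in (0, 1]")
  if (cfg$step > cfg$window) stop("config: step must not exceed window")
  if (!cfg$strategy %in% c("UNIQ", "UNIQ+SameEle", "MULTI")) {
    stop("config: unknown strategy '", cfg$strategy, "'")
  }
  if (!is.null(cfg$min_fold) && cfg$min_fold < 1) {
    stop("config: min_fold must be >= 1")
  }
  invisible(cfg)
}

#' Run the full synthetic-data pipeline and write its tables
#'
#' Stages: simulate genome and IP/control libraries, align and weight
#' (toy exact multi-mapper), remove PCR duplicates, apply the mapping
#' strategy, estimate bin-correlation factors, scan and test windows,
#' merge regions, annotate them, compute element-level enrichment, and
#' optionally a motif profile over called regions. All outputs are
#' tab-delimited or BED text files plus a `manifest.yaml` recording the
#' parameters, seeds and output checksums; a rerun with the same config is
#' byte-identical.
#'
#' @param config A [pipeline_config()] whose `genome` is a [genome_spec()]
#'   and whose `libraries` is a named list with [library_spec()] entries
#'   `IP` and `control`.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "repclip_config"))
  validate_config(config)
  if (is.null(config$genome) || !inherits(config$genome, "genome_spec")) {
    stop("config$genome must be a genome_spec()")
  }
  libs <- config$libraries
  if (is.null(libs) || !all(c("IP", "control") %in% names(libs))) {
    stop("config$libraries must name IP and control library_spec()s")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(outdir, f)

  gen <- build_genome(config$genome)
  writeXStringSet(gen$genome, path("genome.fa"))
  write_repeat_table(gen$repeats, path("repeats.tsv"))
  write_gene_table(gen$genes, path("genes.tsv"))
  fwrite(gen$truth, path("truth_genome.tsv"), sep = "\t")

  recs <- list()
  for (lib in c("IP", "control")) {
    sim <- simulate_library(gen$genome, gen$repeats, gen$genes,
                            libs[[lib]])
    fwrite(sim$truth, path(sprintf("truth_reads_%s.tsv", lib)),
           sep = "\t")
    aln <- toy_align(sim$reads, sim$genome, m_cap = config$m_cap)
    aln <- remove_duplicates(aln)
    aln <- apply_strategy(aln, config$strategy, gen$repeats)
    write_bed_records(aln, path(sprintf("records_%s.bed", lib)))
    recs[[lib]] <- aln
  }

  bins <- bin_counts(recs, gen$genome, bin_size = config$bin_size)
  factors <- estimate_factors(bins, q = config$norm_quantile)
  fwrite(data.table(library = names(factors$e), e = factors$e,
                    total = factors$totals[names(factors$e)],
                    n_selected_bins = factors$n_selected[names(factors$e)]),
         path("norm_factors.tsv"), sep = "\t")

  wins <- scan_windows(recs$IP, recs$control, gen$genome, factors,
                       libs = c("IP", "control"),
                       window = config$window, step = config$step)
  tested <- window_test(wins)
  fwrite(tested, path("windows.tsv"), sep = "\t")
  cov <- weighted_coverage(recs$IP, gen$genome, e = factors$e[["IP"]])
  regions <- merge_regions(tested, merge_gap = config$merge_gap,
                           alpha = config$alpha,
                           min_fold = config$min_fold, coverage = cov)
  if (nrow(regions)) write_bed_regions(regions, path("regions.bed"))
  labeled <- if (nrow(regions)) {
    annotate_regions(regions, gen$genes, gen$repeats)
  } else regions
  fwrite(labeled, path("regions_annotated.tsv"), sep = "\t")

  elements <- element_enrichment(recs$IP, recs$control, gen$repeats,
                                 factors, libs = c("IP", "control"))
  fwrite(elements, path("elements.tsv"), sep = "\t")

  motif <- NULL
  if (isTRUE(config$run_motif) && nrow(regions) >= 20L) {
    centres <- region_peak_centers(regions, cov)
    motif <- pentamer_profile(centres, gen$genome, gen$repeats,
                              pentamer = config$pentamer,
                              flank = config$motif_flank,
                              n_random = config$n_random,
                              seed = config$seed)
    fwrite(motif$profile, path("motif_profile.tsv"), sep = "\t")
  }

  outputs <- list.files(outdir, full.names = FALSE)
  outputs <- setdiff(outputs, "manifest.yaml")
  manifest <- list(
    parameters = config[setdiff(names(config),
                                c("genome", "libraries"))],
    genome_seed = config$genome$seed,
    library_seeds = lapply(libs, `[[`, "seed"),
    outputs = as.list(tools::md5sum(file.path(outdir, sort(outputs)))))
  manifest$parameters$min_fold <- manifest$parameters$min_fold %||% "none"
  yaml::write_yaml(manifest, path("manifest.yaml"))

  invisible(list(genome = gen, records = recs, factors = factors,
                 windows = tested, regions = regions, labeled = labeled,
                 elements = elements, motif = motif, manifest = manifest))
}

#' Crosslink-proxy site centres of regions
#'
#' The centre of a region is the position of maximum per-base normalised IP
#' coverage within it (leftmost maximum on ties).
#'
#' @param regions Region table.
#' @param coverage Coverage list from [weighted_coverage()].
#' @return data.table: chrom, pos.
#' @export
region_peak_centers <- function(regions, coverage) {
  reg <- as.data.table(regions)
  pos <- integer(nrow(reg))
  for (i in seq_len(nrow(reg))) {
    cv <- coverage[[reg$chrom[i]]]
    hi <- min(reg$end[i], length(cv))
    seg <- as.numeric(cv[reg$start[i]:hi])
    pos[i] <- reg$start[i] + which.max(seg) - 1L
  }
  data.table(chrom = reg$chrom, pos = pos)
}
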