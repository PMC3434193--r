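# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Uniform random DNA of length n as a character scalar
#' @noRd
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Convert an RNA-alphabet motif (e.g. "UGUGU") to its DNA spelling
#' @noRd
rna_to_dna <- function(x) chartr("Uu", "Tt", x)

#' Mutate a DNA character string: each base substituted independently with
#' probability `rate`, always to a different base.
#' @noRd
mutate_dna <- function(seq, rate) {
  if (rate <= 0) return(seq)
  bases <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(runif(length(bases)) < rate)
  if (length(hit)) {
    alt <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")
    bases[hit] <- vapply(bases[hit], function(b) {
      substring(alt[[b]], s <- sample.int(3L, 1L), s)
    }, character(1L))
  }
  paste(bases, collapse = "")
}

#' Validate a records table has the alignment-record columns
#' @noRd
check_records <- function(records) {
  need <- c("read_id", "chrom", "start", "end", "strand", "n_alignments",
            "weight")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("alignment records are missing column(s): ",
         paste(miss, collapse = ", "))
  }
  invisible(records)
}

#' Validate a repeat-annotation table
#' @noRd
check_repeats <- function(repeats) {
  need <- c("chrom", "start", "end", "strand", "element", "family", "class")
  miss <- setdiff(need, names(repeats))
  if (length(miss)) {
    stop("repeat table is missing column(s): ", paste(miss, collapse = ", "))
  }
  bad <- which(!(repeats$start >= 1 & repeats$end >= repeats$start))
  if (length(bad)) {
    stop("malformed repeat annotation row(s): ",
         paste(head(bad, 10L), collapse = ", "))
  }
  invisible(repeats)
}

#' Validate an exon (gene-model) table
#' @noRd
check_genes <- function(genes) {
  need <- c("gene_id", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(genes))
  if (length(miss)) {
    stop("gene table is missing column(s): ", paste(miss, collapse = ", "))
  }
  bad <- which(!(genes$start >= 1 & genes$end >= genes$start))
  if (length(bad)) {
    stop("malformed gene annotation row(s): ",
         paste(head(bad, 10L), collapse = ", "))
  }
  invisible(genes)
}

#' Named vector of chromosome lengths from a DNAStringSet genome
#' @noRd
chrom_lengths <- function(genome) {
  setNames(Biostrings::width(genome), names(genome))
}
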