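#' Genome as a set of chromosome lengths
#'
#' The minimal coordinate frame of the pipeline: a named vector of chromosome
#' lengths in base pairs. All intervals in the package are 0-based half-open
#' (BED convention); a genome attached to an operation bounds-checks them.
#'
#' @param chrom_sizes Named numeric vector, chromosome name -> length in bp.
#' @return An object of class `"genome"` (named integer-valued numeric vector).
#' @examples
#' gn <- genome(c(chr1 = 1e6, chr2 = 5e5))
#' chrom_lengths(gn)
#' @export
genome <- function(chrom_sizes) {
  if (length(chrom_sizes) == 0) stopf("genome needs at least one chromosome")
  nm <- names(chrom_sizes)
  if (is.null(nm) || any(nm == "") || anyNA(nm)) {
    stopf("all chromosomes must be named")
  }
  if (anyDuplicated(nm)) stopf("duplicate chromosome names")
  sz <- as.numeric(chrom_sizes)
  if (anyNA(sz) || any(sz <= 0) || any(sz != floor(sz))) {
    stopf("chromosome lengths must be positive integers")
  }
  structure(stats::setNames(sz, nm), class = "genome")
}

#' @rdname genome
#' @param x A `genome` object.
#' @export
chrom_lengths <- function(x) {
  stopifnot(inherits(x, "genome"))
  stats::setNames(as.numeric(x), names(x))
}

#' @export
print.genome <- function(x, ...) {
  cat("genome with", length(x), "chromosomes,", format(sum(x), big.mark = ","),
      "bp total\n")
  invisible(x)
}

#' Construct a table of genomic intervals
#'
#' Intervals are stored as a plain data.frame with columns `chrom`, `start`,
#' `end`, `name`, `strand`, using 0-based half-open coordinates throughout.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors; `0 <= start < end`.
#' @param name Optional identifiers (default `"."`).
#' @param strand Optional strand, one of `"+"`, `"-"`, `"."` (default `"."`).
#' @param genome Optional [genome()] for bounds checking.
#' @return data.frame with columns chrom, start, end, name, strand.
#' @export
gintervals <- function(chrom, start, end, name = ".", strand = ".",
                       genome = NULL) {
  x <- data.frame(chrom = as.character(chrom),
                  start = as.numeric(start),
                  end = as.numeric(end),
                  name = rep_len(as.character(name), length(chrom)),
                  strand = rep_len(as.character(strand), length(chrom)),
                  stringsAsFactors = FALSE)
  validate_intervals(x, genome = genome)
  x
}

#' Validate an interval table
#'
#' @param x data.frame with at least chrom/start/end columns.
#' @param genome Optional [genome()]; when given, intervals must lie within
#'   the named chromosomes.
#' @param what Label used in error messages.
#' @return `x`, invisibly.
#' @export
validate_intervals <- function(x, genome = NULL, what = "interval") {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss)) stopf("%s table lacks columns: %s", what, paste(miss, collapse = ", "))
  if (nrow(x) == 0) return(invisible(x))
  if (anyNA(x$start) || anyNA(x$end) ||
      any(x$start != floor(x$start)) || any(x$end != floor(x$end))) {
    stopf("%s coordinates must be integers", what)
  }
  bad <- which(x$start < 0 | x$start >= x$end)
  if (length(bad)) {
    stopf("%s %d violates 0 <= start < end (start=%s, end=%s)",
          what, bad[1], x$start[bad[1]], x$end[bad[1]])
  }
  if ("strand" %in% names(x)) {
    if (!all(x$strand %in% c("+", "-", "."))) stopf("%s strand must be +, - or .", what)
  }
  if (!is.null(genome)) {
    unknown <- setdiff(unique(x$chrom), names(genome))
    if (length(unknown)) stopf("%s on unknown chromosome: %s", what, unknown[1])
    lens <- chrom_lengths(genome)[x$chrom]
    over <- which(x$end > lens)
    if (length(over)) {
      stopf("%s %d extends beyond chromosome %s (end=%s > %s)",
            what, over[1], x$chrom[over[1]], x$end[over[1]], lens[over[1]])
    }
  }
  invisible(x)
}

#' Edge-to-edge gap between two intervals
#'
#' Distance in bp between interval edges; overlapping or book-ended intervals
#' have gap 0 (bedtools-closest semantics). Vectorized over pairs.
#'
#' @param a,b Interval tables (recycled to common length). Must be on the same
#'   chromosome pairwise.
#' @return Numeric vector of gaps in bp.
#' @examples
#' a <- gintervals("chr1", 1000, 1200)
#' b <- gintervals("chr1", 1500, 1600)
#' interval_gap(a, b) # 300
#' @export
interval_gap <- function(a, b) {
  validate_intervals(a, what = "interval a")
  validate_intervals(b, what = "interval b")
  n <- max(nrow(a), nrow(b))
  ia <- rep_len(seq_len(nrow(a)), n); ib <- rep_len(seq_len(nrow(b)), n)
  if (any(a$chrom[ia] != b$chrom[ib])) {
    stopf("interval_gap requires intervals on the same chromosome; pre-filter by chromosome")
  }
  pmax(0, pmax(b$start[ib] - a$end[ia], a$start[ia] - b$end[ib]))
}

#' Transcription start site of gene models
#'
#' TSS is the 5' end of the gene span: `start` for `+` genes and `end - 1`
#' for `-` genes (0-based). Strandless genes have no TSS and are an error.
#'
#' @param genes Gene table as returned by [read_gtf_genes()] (columns
#'   `gene_id`, `chrom`, `start`, `end`, `strand`).
#' @return Numeric vector of TSS positions, one per gene.
#' @export
tss_of <- function(genes) {
  stopifnot(is.data.frame(genes))
  if (nrow(genes) == 0) return(numeric(0))
  if (any(!genes$strand %in% c("+", "-"))) {
    stopf("TSS undefined for strandless gene (strand must be + or -)")
  }
  ifelse(genes$strand == "+", genes$start, genes$end - 1)
}

# internal: convert 0-based half-open intervals to IRanges (1-based closed)
as_iranges0 <- function(start, end) IRanges::IRanges(start = start + 1L, end = end)
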