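# Readers and writers for the plain-text formats the pipeline touches.
# All internal coordinates are 0-based half-open; GTF import/export is the
# only place 1-based inclusive coordinates appear.

read_lines_checked <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  readLines(path, warn = FALSE)
}

split_fields <- function(lines) strsplit(lines, "\t", fixed = TRUE)

#' Read a BED3/BED6 file of intervals
#'
#' @param path Path to a tab-separated BED file (>= 3 columns). Column 4 is
#'   taken as the interval name and column 6 as the strand when present.
#' @param genome Optional [genome()] for bounds checking.
#' @return Interval data.frame (chrom, start, end, name, strand, and `score`
#'   when a 5th column is present).
#' @seealso [write_bed()]
#' @export
read_bed <- function(path, genome = NULL) {
  lines <- read_lines_checked(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")]
  if (length(lines) == 0) {
    return(gintervals(character(0), numeric(0), numeric(0)))
  }
  fl <- split_fields(lines)
  nf <- lengths(fl)
  if (any(nf < 3)) {
    stopf("BED parse error at line %d: fewer than 3 fields", which(nf < 3)[1])
  }
  chrom <- vapply(fl, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fl, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fl, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) | end != floor(end))
  if (length(bad)) stopf("BED parse error at line %d: non-integer coordinates", bad[1])
  bad <- which(start >= end | start < 0)
  if (length(bad)) {
    stopf("BED parse error at line %d: start >= end or negative start", bad[1])
  }
  name <- ifelse(nf >= 4, vapply(fl, function(f) if (length(f) >= 4) f[[4]] else ".", ""), ".")
  score <- ifelse(nf >= 5, vapply(fl, function(f) if (length(f) >= 5) f[[5]] else NA_character_, ""), NA_character_)
  strand <- ifelse(nf >= 6, vapply(fl, function(f) if (length(f) >= 6) f[[6]] else ".", ""), ".")
  if (!all(strand %in% c("+", "-", "."))) {
    stopf("BED parse error at line %d: bad strand field",
          which(!strand %in% c("+", "-", "."))[1])
  }
  out <- gintervals(chrom, start, end, name = name, strand = strand, genome = genome)
  sc <- suppressWarnings(as.numeric(score))
  if (any(!is.na(sc))) out$score <- sc
  out
}

#' @rdname read_bed
#' @param x Interval data.frame.
#' @param score Optional numeric score column (BED column 5); defaults to the
#'   `score` column of `x` or 0.
#' @export
write_bed <- function(x, path, score = NULL) {
  validate_intervals(x)
  if (nrow(x) == 0) { writeLines(character(0), path); return(invisible(path)) }
  name <- x$name %||% "."
  strand <- x$strand %||% "."
  sc <- score %||% x$score %||% rep(0, nrow(x))
  sc_chr <- ifelse(sc == floor(sc), formatC(sc, format = "d"), num_chr(sc))
  writeLines(paste(x$chrom, formatC(x$start, format = "d"), formatC(x$end, format = "d"),
                   name, sc_chr, strand, sep = "\t"), path)
  invisible(path)
}

#' Read gene models from a GTF file
#'
#' Collapses all records sharing a `gene_id` attribute into one gene-level
#' span (min start to max end), converting the GTF's 1-based inclusive
#' coordinates to the package's 0-based half-open convention. Genes must be
#' stranded: a `"."` strand leaves the TSS undefined and is an error.
#'
#' The optional attributes `is_tf` ("0"/"1") and `tf_name` are parsed when
#' present (they are emitted by the synthetic-data generator).
#'
#' @param path Path to a GTF file.
#' @return data.frame with columns gene_id, chrom, start, end, strand,
#'   is_tf (logical), tf_name (NA when absent), sorted by (chrom, start).
#' @export
read_gtf_genes <- function(path) {
  lines <- read_lines_checked(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stopf("GTF file has no records: %s", path)
  fl <- split_fields(lines)
  nf <- lengths(fl)
  if (any(nf < 9)) stopf("GTF parse error at line %d: fewer than 9 fields", which(nf < 9)[1])
  chrom <- vapply(fl, `[[`, "", 1L)
  start1 <- suppressWarnings(as.numeric(vapply(fl, `[[`, "", 4L)))
  end1 <- suppressWarnings(as.numeric(vapply(fl, `[[`, "", 5L)))
  strand <- vapply(fl, `[[`, "", 7L)
  attrs <- vapply(fl, `[[`, "", 9L)
  bad <- which(is.na(start1) | is.na(end1) | start1 < 1 | end1 < start1)
  if (length(bad)) stopf("GTF parse error at line %d: bad coordinates", bad[1])
  get_attr <- function(a, key) {
    m <- regmatches(a, regexec(paste0(key, "[ =]+\"([^\"]*)\""), a))
    vapply(m, function(g) if (length(g) == 2) g[2] else NA_character_, "")
  }
  gene_id <- get_attr(attrs, "gene_id")
  if (anyNA(gene_id)) {
    stopf("GTF parse error at line %d: record without gene_id attribute",
          which(is.na(gene_id))[1])
  }
  is_tf_attr <- get_attr(attrs, "is_tf")
  tf_name <- get_attr(attrs, "tf_name")
  if (any(!strand %in% c("+", "-"))) {
    stopf("gene %s has strand '%s': TSS undefined (strand must be + or -)",
          gene_id[which(!strand %in% c("+", "-"))[1]],
          strand[which(!strand %in% c("+", "-"))[1]])
  }
  first <- !duplicated(gene_id)
  idx <- split(seq_along(gene_id), gene_id)
  ids <- names(idx)
  g_chrom <- vapply(idx, function(i) chrom[i[1]], "")
  g_strand <- vapply(idx, function(i) strand[i[1]], "")
  chk <- vapply(idx, function(i) length(unique(chrom[i])) == 1 && length(unique(strand[i])) == 1, TRUE)
  if (any(!chk)) stopf("gene %s spans multiple chromosomes or strands", ids[which(!chk)[1]])
  g_start <- vapply(idx, function(i) min(start1[i]) - 1, 0) # 0-based
  g_end <- vapply(idx, function(i) max(end1[i]), 0)
  g_is_tf <- vapply(idx, function(i) {
    v <- is_tf_attr[i]; any(!is.na(v) & v %in% c("1", "true", "TRUE"))
  }, TRUE)
  g_tf_name <- vapply(idx, function(i) {
    v <- tf_name[i]; v <- v[!is.na(v)]; if (length(v)) v[1] else NA_character_
  }, "")
  out <- data.frame(gene_id = ids, chrom = g_chrom, start = g_start, end = g_end,
                    strand = g_strand, is_tf = g_is_tf, tf_name = g_tf_name,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$end, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname read_gtf_genes
#' @param genes Gene table (columns gene_id, chrom, start, end, strand and
#'   optionally is_tf, tf_name).
#' @param source Value for the GTF source column.
#' @export
write_gtf_genes <- function(genes, path, source = "stemGRN") {
  stopifnot(is.data.frame(genes))
  attr_str <- paste0("gene_id \"", genes$gene_id, "\";",
                     ifelse(isTRUE_vec(genes$is_tf), " is_tf \"1\";", ""),
                     ifelse(!is.na(genes$tf_name %||% NA), paste0(" tf_name \"", genes$tf_name, "\";"), ""))
  writeLines(paste(genes$chrom, source, "gene",
                   formatC(genes$start + 1, format = "d"),
                   formatC(genes$end, format = "d"),
                   ".", genes$strand, ".", attr_str, sep = "\t"), path)
  invisible(path)
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else !is.na(x) & x

#' Read a 4-column bedGraph into a signal track
#'
#' The track is a per-chromosome piecewise-constant step function. Steps must
#' not overlap; gaps are allowed and query as signal 0 (deepTools emits sparse
#' tracks).
#'
#' @param path Path to a bedGraph file.
#' @return A `signal_track`: named list (per chromosome) of data.frames with
#'   columns start, end, value, sorted and non-overlapping.
#' @seealso [track_query()], [write_bedgraph()]
#' @export
read_bedgraph <- function(path) {
  lines <- read_lines_checked(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")]
  if (length(lines) == 0) return(signal_track(list()))
  fl <- split_fields(lines)
  nf <- lengths(fl)
  if (any(nf < 4)) stopf("bedGraph parse error at line %d: fewer than 4 fields", which(nf < 4)[1])
  chrom <- vapply(fl, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fl, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fl, `[[`, "", 3L)))
  value <- suppressWarnings(as.numeric(vapply(fl, `[[`, "", 4L)))
  if (anyNA(value)) stopf("bedGraph parse error at line %d: non-numeric value", which(is.na(value))[1])
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad)) stopf("bedGraph parse error at line %d: bad interval", bad[1])
  steps <- split(data.frame(start = start, end = end, value = value), chrom)
  signal_track(steps)
}

#' Construct a signal track from per-chromosome steps
#'
#' @param steps Named list of data.frames with columns start, end, value.
#' @return A `signal_track` object.
#' @export
signal_track <- function(steps) {
  steps <- lapply(steps, function(df) {
    df <- df[order(df$start, df$end), , drop = FALSE]
    rownames(df) <- NULL
    if (nrow(df) > 1 && any(df$start[-1] < df$end[-nrow(df)])) {
      i <- which(df$start[-1] < df$end[-nrow(df)])[1]
      stopf("signal track has overlapping steps ([%s,%s) and [%s,%s))",
            df$start[i], df$end[i], df$start[i + 1], df$end[i + 1])
    }
    if (any(!is.finite(df$value))) stopf("signal track values must be finite")
    df
  })
  structure(steps, class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat("signal_track:", length(x), "chromosomes,",
      sum(vapply(x, nrow, 0L)), "steps\n")
  invisible(x)
}

#' Query a signal track at positions
#'
#' @param track A `signal_track`.
#' @param chrom Single chromosome name.
#' @param pos Numeric vector of positions (0-based).
#' @return Numeric vector of signal values; 0 where no step covers the
#'   position (including chromosomes absent from the track).
#' @export
track_query <- function(track, chrom, pos) {
  stopifnot(inherits(track, "signal_track"), length(chrom) == 1)
  df <- track[[chrom]]
  if (is.null(df) || nrow(df) == 0) return(rep(0, length(pos)))
  i <- findInterval(pos, df$start)
  v <- rep(0, length(pos))
  hit <- i >= 1L
  hit[hit] <- pos[hit] < df$end[i[hit]]
  v[hit] <- df$value[i[hit]]
  v
}

#' @rdname read_bedgraph
#' @param track A `signal_track`.
#' @param digits Decimal digits used for values.
#' @export
write_bedgraph <- function(track, path, digits = 4) {
  stopifnot(inherits(track, "signal_track"))
  chroms <- sort(names(track))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (ch in chroms) {
    df <- track[[ch]]
    if (nrow(df) == 0) next
    writeLines(paste(ch, formatC(df$start, format = "d"), formatC(df$end, format = "d"),
                     num_chr(df$value, digits), sep = "\t"), con)
  }
  invisible(path)
}

#' Read a footprint call table
#'
#' BINDetect-style table of motif occurrences scored by ATAC-seq
#' footprinting: chrom, start, end, motif_id, score, bound flag (0/1).
#' Unbound calls are retained; the bound/unbound distinction is used
#' throughout the network validation.
#'
#' @param path Path to a tab-separated file; a header line starting with
#'   `chrom` is permitted and skipped.
#' @param genome Optional [genome()] for bounds checking.
#' @return data.frame with columns chrom, start, end, motif_id, score,
#'   bound (logical).
#' @export
read_footprints <- function(path, genome = NULL) {
  lines <- read_lines_checked(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) && startsWith(lines[1], "chrom")) lines <- lines[-1]
  if (length(lines) == 0) {
    return(data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                      motif_id = character(0), score = numeric(0), bound = logical(0)))
  }
  fl <- split_fields(lines)
  nf <- lengths(fl)
  if (any(nf < 6)) stopf("footprint parse error at line %d: fewer than 6 fields", which(nf < 6)[1])
  chrom <- vapply(fl, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fl, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fl, `[[`, "", 3L)))
  motif_id <- vapply(fl, `[[`, "", 4L)
  score <- suppressWarnings(as.numeric(vapply(fl, `[[`, "", 5L)))
  flag <- vapply(fl, `[[`, "", 6L)
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad)) stopf("footprint parse error at line %d: bad or negative coordinates", bad[1])
  if (anyNA(score)) stopf("footprint parse error at line %d: non-numeric score", which(is.na(score))[1])
  if (any(!flag %in% c("0", "1"))) {
    stopf("footprint parse error at line %d: bound flag must be 0 or 1, got '%s'",
          which(!flag %in% c("0", "1"))[1], flag[which(!flag %in% c("0", "1"))[1]])
  }
  out <- data.frame(chrom = chrom, start = start, end = end, motif_id = motif_id,
                    score = score, bound = flag == "1", stringsAsFactors = FALSE)
  validate_intervals(out, genome = genome, what = "footprint")
  out
}

#' @rdname read_footprints
#' @param fp Footprint data.frame.
#' @export
write_footprints <- function(fp, path) {
  writeLines(c("chrom\tstart\tend\tmotif_id\tscore\tbound",
               if (nrow(fp)) paste(fp$chrom, formatC(fp$start, format = "d"),
                                   formatC(fp$end, format = "d"), fp$motif_id,
                                   num_chr(fp$score, 3), as.integer(fp$bound), sep = "\t")),
             path)
  invisible(path)
}

#' Read/write simple header-TSV tables
#'
#' `read_tsv_table()` reads a tab-separated file with a header row into a
#' data.frame without any type guessing beyond numeric conversion;
#' `write_tsv_table()` writes one deterministically.
#'
#' @param path File path.
#' @return data.frame.
#' @keywords internal
#' @export
read_tsv_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "", comment.char = "")
}

#' @rdname read_tsv_table
#' @param x data.frame to write.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read a per-sample expression matrix
#'
#' @param path TSV with a `gene_id` column plus one numeric column per sample.
#' @return data.frame; first column gene_id, remaining columns samples.
#' @export
read_expression <- function(path) {
  x <- read_tsv_table(path)
  if (!"gene_id" %in% names(x)) stopf("expression table lacks a gene_id column")
  if (anyDuplicated(x$gene_id)) stopf("duplicate gene_id in expression table")
  num <- setdiff(names(x), "gene_id")
  for (cn in num) {
    x[[cn]] <- as.numeric(x[[cn]])
    if (anyNA(x[[cn]])) stopf("non-numeric expression values in column %s", cn)
  }
  x
}

#' Read a motif-to-TF mapping table
#'
#' Many-to-many map between motif identifiers and TF gene identifiers
#' (one motif can serve several TFs with near-identical binding preferences).
#'
#' @param path TSV with columns `motif_id`, `tf_gene_id`.
#' @return data.frame with unique (motif_id, tf_gene_id) pairs.
#' @export
read_motif_tf_map <- function(path) {
  x <- read_tsv_table(path)
  if (!all(c("motif_id", "tf_gene_id") %in% names(x))) {
    stopf("motif map needs columns motif_id, tf_gene_id")
  }
  x <- unique(x[, c("motif_id", "tf_gene_id")])
  rownames(x) <- NULL
  x
}

#' Read RNAi differential-expression gene lists
#'
#' @param path TSV with columns `knockdown_tf`, `gene_id`; one row per
#'   differentially expressed gene per knockdown experiment.
#' @return data.frame with those two columns.
#' @export
read_de_lists <- function(path) {
  x <- read_tsv_table(path)
  if (!all(c("knockdown_tf", "gene_id") %in% names(x))) {
    stopf("DE list needs columns knockdown_tf, gene_id")
  }
  unique(x[, c("knockdown_tf", "gene_id")])
}

#' Read/write a chromosome-sizes file
#'
#' @param path Two-column TSV: chromosome name, length.
#' @return A [genome()].
#' @export
read_genome <- function(path) {
  lines <- read_lines_checked(path)
  fl <- split_fields(lines[nzchar(lines)])
  genome(stats::setNames(as.numeric(vapply(fl, `[[`, "", 2L)),
                         vapply(fl, `[[`, "", 1L)))
}

#' @rdname read_genome
#' @param genome A [genome()].
#' @export
write_genome <- function(genome, path) {
  writeLines(paste(names(genome), formatC(as.numeric(genome), format = "d"),
                   sep = "\t"), path)
  invisible(path)
}
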