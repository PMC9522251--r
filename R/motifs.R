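# PWM information content and motif -> TF expansion.

#' Read JASPAR-format position weight matrices
#'
#' Parses the JASPAR text format: a `>motif_id name` header followed by four
#' rows `A [ ... ]`, `C [ ... ]`, `G [ ... ]`, `T [ ... ]`. Counts (or
#' frequencies) are normalized per column to probabilities on load.
#'
#' @param path Path to a JASPAR-format file.
#' @return Named list of motifs; each element is a 4 x L probability matrix
#'   with rownames A, C, G, T and every column summing to 1.
#' @export
read_jaspar <- function(path) {
  lines <- read_lines_checked(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  heads <- which(startsWith(lines, ">"))
  if (length(heads) == 0) stopf("no JASPAR records in %s", path)
  out <- list()
  for (h in seq_along(heads)) {
    i <- heads[h]
    id <- strsplit(sub("^>", "", lines[i]), "[ \t]+")[[1]][1]
    if (i + 4 > length(lines)) stopf("truncated JASPAR record %s", id)
    rows <- lines[(i + 1):(i + 4)]
    bases <- toupper(substr(rows, 1, 1))
    if (!identical(bases, c("A", "C", "G", "T"))) {
      stopf("JASPAR record %s: expected rows A, C, G, T", id)
    }
    vals <- lapply(rows, function(r) {
      r <- gsub("^[ACGTacgt][ \t]*\\[?", "", r)
      r <- gsub("\\]\\s*$", "", r)
      as.numeric(strsplit(trimws(r), "[ \t]+")[[1]])
    })
    if (length(unique(lengths(vals))) != 1) {
      stopf("JASPAR record %s: ragged matrix rows", id)
    }
    m <- do.call(rbind, vals)
    rownames(m) <- c("A", "C", "G", "T")
    if (anyNA(m) || any(m < 0)) stopf("JASPAR record %s: bad counts", id)
    cs <- colSums(m)
    if (any(cs <= 0)) stopf("JASPAR record %s: zero column", id)
    out[[id]] <- sweep(m, 2, cs, "/")
  }
  out
}

#' @rdname read_jaspar
#' @param motifs Named list of 4 x L probability (or count) matrices.
#' @param digits Decimal digits for emitted probabilities.
#' @export
write_jaspar <- function(motifs, path, digits = 4) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (id in names(motifs)) {
    m <- motifs[[id]]
    writeLines(paste0(">", id), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(paste0(b, "  [ ", paste(num_chr(m[b, ], digits), collapse = " "), " ]"), con)
    }
  }
  invisible(path)
}

#' Shannon entropy of a PWM column
#'
#' `H = -sum(p * log2(p))` with `0 * log 0 = 0`; bounded by \[0, 2\] bits for
#' the 4-letter DNA alphabet.
#'
#' @param column Probability 4-vector summing to 1.
#' @return Entropy in bits.
#' @examples
#' column_entropy(rep(0.25, 4)) # 2
#' column_entropy(c(1, 0, 0, 0)) # 0
#' @export
column_entropy <- function(column) {
  if (length(column) != 4 || anyNA(column) || any(column < 0)) {
    stopf("column must be 4 non-negative probabilities")
  }
  if (abs(sum(column) - 1) > 1e-6) stopf("column probabilities must sum to 1")
  p <- column[column > 0]
  -sum(p * log2(p))
}

#' Mean entropy and total information content of a motif
#'
#' Per-position Shannon entropies are averaged (`mean_entropy`, bits) and
#' complemented against the 2-bit maximum and summed
#' (`total_ic = sum_j (2 - H_j)`, bits). Both scalars are reported because
#' "mean entropy" and "total information content" are both used as motif
#' summaries in this analysis tradition; they are related exactly by
#' `total_ic = n_columns * (2 - mean_entropy)`.
#'
#' @param pwm 4 x L probability matrix (one motif from [read_jaspar()]).
#' @return List with `mean_entropy`, `total_ic`, `n_columns`.
#' @export
motif_information <- function(pwm) {
  stopifnot(is.matrix(pwm))
  if (ncol(pwm) < 1) stopf("empty PWM")
  H <- apply(pwm, 2, column_entropy)
  list(mean_entropy = mean(H), total_ic = sum(2 - H), n_columns = ncol(pwm))
}

#' Expand footprint calls to (TF, footprint) pairs
#'
#' One motif can be shared by several TFs; each footprint is emitted once per
#' TF mapped to its motif. Footprints whose motif has no TF in the map are
#' dropped with a warning reporting the count.
#'
#' @param footprints Footprint data.frame (see [read_footprints()]).
#' @param map Motif-to-TF map (see [read_motif_tf_map()]).
#' @return data.frame: tf_gene_id plus all footprint columns, one row per
#'   (TF, footprint) pair.
#' @export
expand_motif_hits <- function(footprints, map) {
  if (nrow(map) == 0) stopf("motif map must be non-empty")
  if (nrow(footprints) == 0) {
    return(cbind(data.frame(tf_gene_id = character(0)), footprints))
  }
  unmapped <- !(footprints$motif_id %in% map$motif_id)
  if (any(unmapped)) {
    warnf("%d footprint(s) with unmapped motifs dropped", sum(unmapped))
  }
  fp <- footprints[!unmapped, , drop = FALSE]
  fp$.row <- seq_len(nrow(fp))
  out <- merge(fp, map, by = "motif_id", sort = FALSE)
  out <- out[order(out$.row, out$tf_gene_id), , drop = FALSE]
  out$.row <- NULL
  rownames(out) <- NULL
  out[, c("tf_gene_id", setdiff(names(out), "tf_gene_id")), drop = FALSE]
}

#' Bound-site counts per TF genome-wide
#'
#' Number of bound footprints of each TF's motifs across the whole genome
#' (the per-TF bound-motif histogram). A motif shared by several TFs counts
#' once per TF.
#'
#' @inheritParams expand_motif_hits
#' @return data.frame tf_gene_id, n_bound, sorted by decreasing count; TFs in
#'   the map with no bound footprints are included with count 0.
#' @export
count_bound_motifs <- function(footprints, map) {
  bound <- footprints[footprints$bound, , drop = FALSE]
  hits <- suppressWarnings(expand_motif_hits(bound, map))
  tfs <- sort(unique(map$tf_gene_id))
  tab <- table(factor(hits$tf_gene_id, levels = tfs))
  out <- data.frame(tf_gene_id = tfs, n_bound = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_bound, out$tf_gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
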