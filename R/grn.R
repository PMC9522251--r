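# Nearest-TSS target assignment and TF -> target network assembly from
# footprints falling inside enhancer-like regions.

#' Assign enhancers to nearest-TSS target genes
#'
#' Each enhancer is assigned to the gene minimizing the distance between the
#' enhancer interval and the gene's TSS: 0 when the TSS lies inside
#' `[start, end)`, otherwise `min(|TSS - start|, |TSS - (end - 1)|)`. Ties
#' resolve to the TSS with the smaller coordinate, then the
#' lexicographically smaller gene_id. Enhancers on chromosomes without genes
#' are skipped with a warning.
#'
#' An optional expression-aware rule mirrors the occasional manual override
#' used in the field (an enhancer inside a silent gene's intron is linked to
#' the nearby expressed gene instead): when `min_tpm > 0`, genes whose
#' combined X1+X2 TPM falls below the floor are skipped before taking the
#' nearest TSS. Off by default.
#'
#' @param enhancers Enhancer table from [call_enhancers()] (or any interval
#'   table with an `enhancer_id` or `name` column).
#' @param genes Gene table from [read_gtf_genes()].
#' @param min_tpm Expression floor in TPM for the optional filter.
#' @param profiles Expression profiles (from [expression_profiles()]);
#'   required when `min_tpm > 0`.
#' @return data.frame: enhancer_id, gene_id, distance (bp), tss, chrom,
#'   start, end.
#' @export
assign_targets <- function(enhancers, genes, min_tpm = 0, profiles = NULL) {
  validate_intervals(enhancers, what = "enhancer")
  stopifnot(is.data.frame(genes), nrow(genes) >= 1)
  enh_id <- enhancers$enhancer_id %||% default_ids(enhancers, "enh")
  if (min_tpm > 0) {
    if (is.null(profiles)) stopf("expression profiles required when min_tpm > 0")
    keep_genes <- profiles$gene_id[(profiles$tpm_x1 + profiles$tpm_x2) >= min_tpm]
    genes <- genes[genes$gene_id %in% keep_genes, , drop = FALSE]
    if (nrow(genes) == 0) stopf("no gene passes the expression floor")
  }
  tss <- tss_of(genes)
  out <- vector("list", 0)
  for (ch in unique(enhancers$chrom)) {
    ei <- which(enhancers$chrom == ch)
    gi <- which(genes$chrom == ch)
    if (length(gi) == 0) {
      warnf("%d enhancer(s) on chromosome %s with no genes: assignment skipped",
            length(ei), ch)
      next
    }
    hit <- nearest_tss(enhancers$start[ei], enhancers$end[ei],
                       tss[gi], genes$gene_id[gi])
    out[[length(out) + 1]] <- data.frame(
      enhancer_id = enh_id[ei], gene_id = hit$gene_id, distance = hit$distance,
      tss = hit$tss, chrom = ch,
      start = enhancers$start[ei], end = enhancers$end[ei],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(enhancer_id = character(0), gene_id = character(0),
                      distance = numeric(0), tss = numeric(0), chrom = character(0),
                      start = numeric(0), end = numeric(0)))
  }
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start, out$end, out$enhancer_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Vectorized nearest-TSS search on one chromosome. Distance 0 for a TSS
# inside [s, e); otherwise min(s - tss, tss - (e-1)) on the relevant side.
# Tie-break: smaller distance, then smaller TSS coordinate, then gene_id.
nearest_tss <- function(s, e, tss, gene_id) {
  # per unique coordinate keep the lexicographically smallest gene_id
  ord <- order(tss, gene_id)
  t_sorted <- tss[ord]; g_sorted <- gene_id[ord]
  first <- !duplicated(t_sorted)
  tu <- t_sorted[first]; gu <- g_sorted[first]

  n <- length(s)
  # inside: first TSS >= s that is also <= e - 1
  i_in <- findInterval(s - 1, tu) + 1L
  inside <- i_in <= length(tu) & tu[pmin(i_in, length(tu))] <= e - 1
  # left: largest TSS < s
  il <- findInterval(s - 1, tu)
  has_l <- il >= 1L
  dl <- rep(Inf, n); dl[has_l] <- s[has_l] - tu[pmax(il[has_l], 1L)]
  # right: smallest TSS >= e
  ir <- findInterval(e - 1, tu) + 1L
  has_r <- ir <= length(tu)
  dr <- rep(Inf, n); dr[has_r] <- tu[pmin(ir[has_r], length(tu))] - (e[has_r] - 1)

  use_left <- dl <= dr  # tie -> smaller coordinate = left
  idx <- ifelse(use_left, il, ir)
  dist <- pmin(dl, dr)
  idx[inside] <- i_in[inside]
  dist[inside] <- 0
  list(gene_id = gu[idx], distance = dist, tss = tu[idx])
}

#' Build TF -> target regulatory links from footprints inside enhancers
#'
#' A footprint supports a link when its interval overlaps an enhancer by at
#' least 1 bp. For every such footprint and every TF mapped to its motif, a
#' link (TF -> the enhancer's nearest-TSS target gene) is emitted carrying
#' the footprint's bound/unbound flag. Links are deduplicated on
#' (tf, target, enhancer, motif, bound) with a supporting-footprint count.
#'
#' @param assignments Enhancer-target table from [assign_targets()].
#' @param footprints Footprint table from [read_footprints()].
#' @param map Motif-to-TF map.
#' @param tf_genes Character vector of gene_ids that are TFs; links are only
#'   created for TFs in this set.
#' @return data.frame: tf_gene_id, target_gene_id, enhancer_id, motif_id,
#'   bound, distance, n_support.
#' @export
build_links <- function(assignments, footprints, map, tf_genes) {
  map <- map[map$tf_gene_id %in% tf_genes, , drop = FALSE]
  empty <- data.frame(tf_gene_id = character(0), target_gene_id = character(0),
                      enhancer_id = character(0), motif_id = character(0),
                      bound = logical(0), distance = numeric(0),
                      n_support = integer(0))
  if (nrow(assignments) == 0 || nrow(footprints) == 0 || nrow(map) == 0) return(empty)
  pieces <- vector("list", 0)
  for (ch in intersect(unique(assignments$chrom), unique(footprints$chrom))) {
    ai <- which(assignments$chrom == ch)
    fi <- which(footprints$chrom == ch)
    ov <- IRanges::findOverlaps(
      as_iranges0(footprints$start[fi], footprints$end[fi]),
      as_iranges0(assignments$start[ai], assignments$end[ai]),
      minoverlap = 1L)
    if (length(ov) == 0) next
    fidx <- fi[S4Vectors::queryHits(ov)]
    aidx <- ai[S4Vectors::subjectHits(ov)]
    pieces[[length(pieces) + 1]] <- data.frame(
      motif_id = footprints$motif_id[fidx],
      bound = footprints$bound[fidx],
      enhancer_id = assignments$enhancer_id[aidx],
      target_gene_id = assignments$gene_id[aidx],
      distance = assignments$distance[aidx],
      stringsAsFactors = FALSE)
  }
  if (length(pieces) == 0) return(empty)
  hits <- do.call(rbind, pieces)
  hits <- merge(hits, map, by = "motif_id")  # cartesian over TFs of the motif
  if (nrow(hits) == 0) return(empty)
  key <- paste(hits$tf_gene_id, hits$target_gene_id, hits$enhancer_id,
               hits$motif_id, hits$bound, sep = "\r")
  agg <- tapply(seq_len(nrow(hits)), key, length)
  firsts <- hits[!duplicated(key), , drop = FALSE]
  firsts$n_support <- as.integer(agg[paste(firsts$tf_gene_id, firsts$target_gene_id,
                                           firsts$enhancer_id, firsts$motif_id,
                                           firsts$bound, sep = "\r")])
  out <- firsts[, c("tf_gene_id", "target_gene_id", "enhancer_id", "motif_id",
                    "bound", "distance", "n_support")]
  out <- out[order(out$tf_gene_id, out$target_gene_id, out$enhancer_id,
                   out$motif_id, !out$bound), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stem-cell (X1) subnetwork
#'
#' Restricts a link table to TF nodes whose X1 proportional expression
#' exceeds `threshold` (1/3 by default) and to bound links between retained
#' nodes; node attributes carry absolute X1 TPM and X1 proportion. Isolated
#' retained TFs stay in the node table.
#'
#' @param links Link table from [build_links()].
#' @param profiles Expression profiles from [expression_profiles()].
#' @param tf_genes Character vector of TF gene_ids.
#' @param threshold X1 proportional-expression cutoff.
#' @return Object of class `"grn"`: list with `nodes` (gene_id, tpm_x1, p1)
#'   and `edges` (tf, target, n_support, deduplicated bound links).
#' @export
subnetwork_x1 <- function(links, profiles, tf_genes, threshold = 1/3) {
  keep <- profiles$gene_id %in% tf_genes &
    !is.na(profiles$p1) & profiles$p1 > threshold
  nodes <- profiles[keep, c("gene_id", "tpm_x1", "p1"), drop = FALSE]
  rownames(nodes) <- NULL
  el <- links[links$bound &
                links$tf_gene_id %in% nodes$gene_id &
                links$target_gene_id %in% nodes$gene_id, , drop = FALSE]
  if (nrow(el)) {
    key <- paste(el$tf_gene_id, el$target_gene_id, sep = "\r")
    n_sup <- tapply(el$n_support, key, sum)
    el <- el[!duplicated(key), c("tf_gene_id", "target_gene_id"), drop = FALSE]
    el$n_support <- as.integer(n_sup[paste(el$tf_gene_id, el$target_gene_id, sep = "\r")])
    el <- el[order(el$tf_gene_id, el$target_gene_id), , drop = FALSE]
  } else {
    el <- data.frame(tf_gene_id = character(0), target_gene_id = character(0),
                     n_support = integer(0))
  }
  rownames(el) <- NULL
  structure(list(nodes = nodes, edges = el), class = "grn")
}

#' @export
print.grn <- function(x, ...) {
  cat("grn:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Convert a GRN to an igraph object
#'
#' @param x A `"grn"` from [subnetwork_x1()].
#' @return An igraph directed graph (requires the igraph package).
#' @export
grn_igraph <- function(x) {
  stopifnot(inherits(x, "grn"))
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stopf("the igraph package is required for grn_igraph()")
  }
  igraph::graph_from_data_frame(x$edges, directed = TRUE, vertices = x$nodes)
}
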