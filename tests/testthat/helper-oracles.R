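# Independent brute-force oracles and random-instance generators used by the
# dual-route acceptance checks. These deliberately share no code with the
# package's findInterval/IRanges implementations.

# all-pairs minimal-gap enhancer calling
oracle_call_enhancers <- function(ac, me1, max_gap = 500) {
  rows <- list()
  for (i in seq_len(nrow(ac))) {
    cand <- which(me1$chrom == ac$chrom[i])
    if (length(cand) == 0) next
    gaps <- vapply(cand, function(j) {
      max(0, me1$start[j] - ac$end[i], ac$start[i] - me1$end[j])
    }, 0)
    o <- cand[order(gaps, me1$start[cand], me1$end[cand], cand)]
    g <- sort(gaps)[1]
    if (g <= max_gap) {
      rows[[length(rows) + 1]] <- data.frame(
        chrom = ac$chrom[i], start = ac$start[i], end = ac$end[i],
        enhancer_id = ac$name[i], partner_me1_id = me1$name[o[1]],
        gap_bp = g, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                      enhancer_id = character(0), partner_me1_id = character(0),
                      gap_bp = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start, out$end, out$enhancer_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# exhaustive min-over-genes nearest-TSS assignment
oracle_assign_targets <- function(enhancers, genes) {
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  rows <- list()
  enh_id <- enhancers$enhancer_id
  for (i in seq_len(nrow(enhancers))) {
    gi <- which(genes$chrom == enhancers$chrom[i])
    if (length(gi) == 0) next
    d <- vapply(gi, function(j) {
      if (tss[j] >= enhancers$start[i] && tss[j] < enhancers$end[i]) 0
      else min(abs(tss[j] - enhancers$start[i]),
               abs(tss[j] - (enhancers$end[i] - 1)))
    }, 0)
    pick <- gi[order(d, tss[gi], genes$gene_id[gi])][1]
    rows[[length(rows) + 1]] <- data.frame(
      enhancer_id = enh_id[i], gene_id = genes$gene_id[pick],
      distance = min(d), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# random peak-set instance; coarse coordinate grid forces gap ties
random_peak_instance <- function(n_ac, n_me1, n_chroms = 2, span = 1e5,
                                 grid = 50) {
  mk <- function(n, prefix) {
    chrom <- paste0("chr", sample.int(n_chroms, n, replace = TRUE))
    start <- grid * sample.int(span %/% grid, n, replace = TRUE)
    width <- grid * sample.int(4, n, replace = TRUE)
    df <- data.frame(chrom = chrom, start = start, end = start + width,
                     name = paste0(prefix, seq_len(n)), strand = ".",
                     stringsAsFactors = FALSE)
    df[sample.int(n), , drop = FALSE]  # shuffled input order
  }
  list(ac = mk(n_ac, "a"), me1 = mk(n_me1, "m"))
}

random_gene_instance <- function(n_enh, n_genes, n_chroms = 2, span = 1e5,
                                 grid = 50) {
  gs <- grid * sample.int(span %/% grid, n_genes, replace = TRUE)
  genes <- data.frame(
    gene_id = sprintf("g%04d", sample.int(9999, n_genes)),
    chrom = paste0("chr", sample.int(n_chroms, n_genes, replace = TRUE)),
    start = gs, end = gs + grid * sample.int(40, n_genes, replace = TRUE),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    stringsAsFactors = FALSE)
  es <- grid * sample.int(span %/% grid, n_enh, replace = TRUE)
  enh <- data.frame(chrom = paste0("chr", sample.int(n_chroms, n_enh, replace = TRUE)),
                    start = es, end = es + grid * sample.int(6, n_enh, replace = TRUE),
                    enhancer_id = paste0("e", seq_len(n_enh)),
                    stringsAsFactors = FALSE)
  # guarantee every enhancer chromosome has a gene
  for (ch in unique(enh$chrom)) {
    if (!any(genes$chrom == ch)) genes$chrom[1] <- ch
  }
  list(enh = enh, genes = genes)
}

# uniform random points on the 2-simplex
random_simplex <- function(n) {
  x <- matrix(stats::rexp(3 * n), ncol = 3)
  x / rowSums(x)
}
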