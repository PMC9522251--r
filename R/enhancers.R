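# Enhancer-like region calling from histone-mark peak proximity, and
# signal quantification at regions vs random genomic background.

#' Call enhancer-like regions from H3K27ac/H3K4me1 peak proximity
#'
#' An H3K27ac peak qualifies as an enhancer-like region when the edge-to-edge
#' gap to the nearest H3K4me1 peak on the same chromosome is at most
#' `max_gap` bp (500 bp by default; overlapping or book-ended peaks have gap
#' 0). The enhancer interval is the H3K27ac peak itself; the gap-minimizing
#' H3K4me1 partner is recorded, with ties broken to the leftmost partner
#' (smallest start, then end, then input position).
#'
#' Implementation is a sorted `findInterval()` sweep, O((n+m) log m); the
#' test suite checks it against a brute-force all-pairs oracle.
#'
#' @param ac H3K27ac peak intervals (data.frame; see [gintervals()]).
#' @param me1 H3K4me1 peak intervals.
#' @param max_gap Maximum allowed gap in bp.
#' @return data.frame of enhancer regions in genomic order: chrom, start,
#'   end, enhancer_id (the H3K27ac peak name, or `acN`), partner_me1_id,
#'   gap_bp.
#' @export
call_enhancers <- function(ac, me1, max_gap = 500) {
  validate_intervals(ac, what = "H3K27ac peak")
  validate_intervals(me1, what = "H3K4me1 peak")
  if (nrow(ac) == 0 || nrow(me1) == 0) {
    return(data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                      enhancer_id = character(0), partner_me1_id = character(0),
                      gap_bp = numeric(0)))
  }
  ac_id <- default_ids(ac, "ac")
  me1_id <- default_ids(me1, "me1")
  res <- vector("list", 0)
  for (ch in intersect(unique(ac$chrom), unique(me1$chrom))) {
    ai <- which(ac$chrom == ch)
    mi <- which(me1$chrom == ch)
    nn <- nearest_by_gap(ac$start[ai], ac$end[ai],
                         me1$start[mi], me1$end[mi])
    keep <- nn$gap <= max_gap
    if (!any(keep)) next
    res[[length(res) + 1]] <- data.frame(
      chrom = ch,
      start = ac$start[ai][keep], end = ac$end[ai][keep],
      enhancer_id = ac_id[ai][keep],
      partner_me1_id = me1_id[mi][nn$partner[keep]],
      gap_bp = nn$gap[keep], stringsAsFactors = FALSE)
  }
  if (length(res) == 0) {
    return(data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                      enhancer_id = character(0), partner_me1_id = character(0),
                      gap_bp = numeric(0)))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$chrom, out$start, out$end, out$enhancer_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

default_ids <- function(x, prefix) {
  nm <- x$name %||% rep(".", nrow(x))
  idx <- which(is.na(nm) | nm == "." | nm == "")
  nm[idx] <- paste0(prefix, idx)
  nm
}

# Vectorized nearest-by-gap search against a subject peak set on one
# chromosome. Returns, per query, the minimal edge-to-edge gap and the index
# (into the subject vectors) of the gap-minimizing subject, ties resolved to
# the leftmost subject (smallest start, then end, then original index).
# Three candidate classes are computed per query -- leftmost overlapping
# subject, best left neighbour (maximal end <= query start, so gap 0 when
# book-ended), best right neighbour (minimal start >= query end) -- and the
# winner is chosen by (gap, start, end); this matters because a book-ended
# peak ties an overlapping one at gap 0 and can still be the leftmost.
nearest_by_gap <- function(qs, qe, ss, se) {
  ord <- order(ss, se, seq_along(ss))
  s_start <- ss[ord]; s_end <- se[ord]
  cmax <- cummax(s_end)
  n <- length(qs)

  # overlap: leftmost subject (in (start,end,idx) order) with end > qs and start < qe
  k <- findInterval(qe - 1, s_start)            # subjects with start < qe
  j_ov <- findInterval(qs, cmax) + 1L           # first index with cummax(end) > qs
  has_ov <- k >= 1L & j_ov <= k
  p_ov <- rep(NA_integer_, n)
  p_ov[has_ov] <- ord[j_ov[has_ov]]
  g_ov <- ifelse(has_ov, 0, Inf)

  # left neighbours: subjects with end <= qs, nearest has maximal end;
  # among equal ends the run-first in (end,start,idx) order is leftmost
  eord <- order(se, ss, seq_along(ss))
  e_end <- se[eord]
  e_first <- match(e_end, e_end)                # first index of each tie-run
  jl <- findInterval(qs, e_end)                 # last subject with end <= qs
  has_l <- jl >= 1L
  g_l <- rep(Inf, n)
  g_l[has_l] <- qs[has_l] - e_end[jl[has_l]]
  p_l <- rep(NA_integer_, n)
  p_l[has_l] <- eord[e_first[jl[has_l]]]

  # right neighbours: first subject with start >= qe (runs share a start;
  # sorted order already puts the (end,idx)-smallest first)
  jr <- findInterval(qe - 1, s_start) + 1L
  has_r <- jr <= length(s_start)
  g_r <- rep(Inf, n)
  g_r[has_r] <- s_start[pmin(jr[has_r], length(s_start))] - qe[has_r]
  p_r <- rep(NA_integer_, n)
  p_r[has_r] <- ord[pmin(jr[has_r], length(s_start))]

  better <- function(ga, pa, gb, pb) {
    sa <- ifelse(is.na(pa), Inf, ss[pa]); sb <- ifelse(is.na(pb), Inf, ss[pb])
    ea <- ifelse(is.na(pa), Inf, se[pa]); eb <- ifelse(is.na(pb), Inf, se[pb])
    a_wins <- ga < gb | (ga == gb & (sa < sb | (sa == sb & ea <= eb)))
    list(g = ifelse(a_wins, ga, gb), p = ifelse(a_wins, pa, pb))
  }
  w <- better(g_ov, p_ov, g_l, p_l)
  w <- better(w$g, w$p, g_r, p_r)
  list(gap = w$g, partner = w$p)
}

#' Mean peak value of a signal track around a center
#'
#' Mean of the signal sampled every `step` bp from `flank` bp upstream to
#' `flank` bp downstream of each center (201 grid points with the defaults).
#' Positions outside any track step contribute 0.
#'
#' @param track A `signal_track` (see [read_bedgraph()]).
#' @param chrom Chromosome of the centers.
#' @param centers Numeric vector of center positions (bp).
#' @param flank,step Grid geometry in bp.
#' @return Numeric vector of mean peak values, one per center.
#' @export
mean_peak_value <- function(track, chrom, centers, flank = 1000, step = 10) {
  offsets <- seq(-flank, flank, by = step)
  if (length(centers) == 0) return(numeric(0))
  pos <- rep(centers, each = length(offsets)) + offsets
  v <- track_query(track, chrom, pos)
  colMeans(matrix(v, nrow = length(offsets)))
}

#' Uniform random genomic regions
#'
#' Fixed-length regions with the chromosome chosen proportionally to its
#' length and the start uniform on `[0, chrom_len - length]`; the
#' deterministic stand-in for `bedtools random`.
#'
#' @param genome A [genome()].
#' @param n Number of regions.
#' @param length Region length in bp; no chromosome may be shorter.
#' @param seed Integer seed; same seed, same regions.
#' @return Interval data.frame with names `r1..rn`.
#' @export
random_regions <- function(genome, n, length = 500, seed = 1) {
  lens <- chrom_lengths(genome)
  if (length > max(lens)) stopf("region length exceeds the longest chromosome")
  if (any(lens < length)) stopf("every chromosome must be at least `length` bp")
  with_seed(seed, {
    ch <- sample(names(lens), n, replace = TRUE, prob = lens)
    start <- floor(stats::runif(n) * (lens[ch] - length + 1))
    gintervals(ch, start, start + length, name = paste0("r", seq_len(n)),
               genome = genome)
  })
}

#' Compare signal between two region sets
#'
#' Computes the mean peak value at each region's center (floor of the
#' interval midpoint) for both sets and tests the difference with a
#' two-sided Wilcoxon rank-sum test.
#'
#' @param track A `signal_track`.
#' @param regions_a,regions_b Interval data.frames (e.g. enhancers and
#'   random background regions).
#' @inheritParams mean_peak_value
#' @return List with `values_a`, `values_b` (per-region mean peak values),
#'   `median_a`, `median_b`, `statistic`, `p_value`.
#' @export
region_signal_test <- function(track, regions_a, regions_b, flank = 1000, step = 10) {
  va <- region_mpv(track, regions_a, flank, step)
  vb <- region_mpv(track, regions_b, flank, step)
  ht <- suppressWarnings(stats::wilcox.test(va, vb, exact = FALSE, correct = TRUE))
  list(values_a = va, values_b = vb,
       median_a = stats::median(va), median_b = stats::median(vb),
       statistic = unname(ht$statistic), p_value = ht$p.value)
}

region_mpv <- function(track, regions, flank, step) {
  validate_intervals(regions)
  if (nrow(regions) == 0) stopf("region set must be non-empty")
  centers <- floor((regions$start + regions$end) / 2)
  v <- numeric(nrow(regions))
  for (ch in unique(regions$chrom)) {
    i <- regions$chrom == ch
    v[i] <- mean_peak_value(track, ch, centers[i], flank = flank, step = step)
  }
  v
}
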