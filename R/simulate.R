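# Synthetic-data generator: emits every pipeline input with known ground
# truth. The stated world mirrors the structure of the real datasets at desk
# scale: co-located H3K27ac/H3K4me1 peak pairs (gap <= max_gap) at planted
# enhancers, bimodal H3K4me1 flanking a central H3K27ac bump, elevated
# ATAC/footprint signal and depressed H3K4me1 log2FC upon methyltransferase
# knockdown at enhancers, Dirichlet-distributed compartment proportions, and
# RNAi DE sets enriched for bound-footprint targets of the knocked-down TF.

#' Simulation configuration
#'
#' Defaults define the package's stated synthetic world; see the methods
#' vignette for the rationale behind each choice. All downstream generators
#' and [simulate_dataset()] consume this object.
#'
#' @param seed Master seed; fixes every emitted file byte-for-byte.
#' @param n_chroms,chrom_length Genome shape (bp).
#' @param n_genes,tf_fraction Gene count and fraction flagged as TFs.
#' @param n_enhancers True enhancer count.
#' @param enhancer_tf_target_bias Probability that a planted enhancer is
#'   placed near a TF gene (TFs are enriched among enhancer targets).
#' @param prox_fraction,tail_mean_bp,max_distance_bp Enhancer-to-TSS distance
#'   mixture: `prox_fraction` of enhancers within 1 kb, the rest on an
#'   exponential tail (mean `tail_mean_bp`) truncated at `max_distance_bp`.
#' @param peak_width_mean,peak_width_sd Histone peak width distribution (bp);
#'   peaks are generally under 200 bp wide.
#' @param max_gap Enhancer definition: maximal H3K27ac-H3K4me1 gap (bp).
#' @param gap_noise_sd Positional jitter (bp) applied to H3K4me1 partners.
#' @param n_decoy_ac,n_decoy_me1 Single-mark decoy peaks per mark, placed
#'   with gap > `max_gap` from every peak of the other mark.
#' @param track_step,track_flank,track_noise_sd Signal-track lattice (bp),
#'   emitted half-window around each site (bp), and Gaussian noise sd.
#' @param ac_amp,me1_amp,me1_offset,atac_amp,fp_amp,lpt_amp Track shape
#'   amplitudes (signal units) and the H3K4me1 bimodal flank offset (bp);
#'   `lpt_amp` is negative (signal drops at enhancers upon lpt RNAi).
#' @param class_freqs Frequencies of the seven enrichment classes.
#' @param dirichlet_conc Per-class Dirichlet concentration vectors for
#'   (X1, X2, Xins) proportions.
#' @param unexpressed_fraction Fraction of genes with all-zero TPM.
#' @param n_replicates,replicate_sdlog Samples per compartment and lognormal
#'   replicate noise.
#' @param magnitude_meanlog,magnitude_sdlog Gene-level TPM magnitude
#'   (lognormal).
#' @param n_motifs,motif_alpha Motif count and Dirichlet sharpness of PWM
#'   columns.
#' @param n_regulators,out_degree_base,out_degree_mean Planted regulators and
#'   their TF-target out-degree (`out_degree_base + Poisson(out_degree_mean -
#'   out_degree_base)`).
#' @param background_fp_per_enhancer Mean count of non-planted footprints per
#'   enhancer.
#' @param n_background_fp Footprints placed outside enhancers.
#' @param bound_rate_in_enhancers,bound_rate_elsewhere Probability that a
#'   footprint is called bound, inside vs outside enhancers.
#' @param n_knockdowns,de_base_rate,planted_enrichment_factor RNAi cohort
#'   size, baseline DE probability per TF, and the factor by which bound
#'   targets of the knocked-down TF are enriched in its DE set.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1,
                       n_chroms = 4, chrom_length = 4e6,
                       n_genes = 2000, tf_fraction = 0.2,
                       n_enhancers = 200,
                       enhancer_tf_target_bias = 0.7,
                       prox_fraction = 0.4, tail_mean_bp = 15000,
                       max_distance_bp = 90000,
                       peak_width_mean = 180, peak_width_sd = 25,
                       max_gap = 500, gap_noise_sd = 15,
                       n_decoy_ac = 200, n_decoy_me1 = 200,
                       track_step = 10, track_flank = 1100, track_noise_sd = 0.2,
                       ac_amp = 3, me1_amp = 2.5, me1_offset = 300,
                       atac_amp = 4, fp_amp = 3, lpt_amp = -1.5,
                       class_freqs = c(X1 = 0.10, X2 = 0.10, Xins = 0.20,
                                       X1_X2 = 0.15, X1_Xins = 0.05,
                                       X2_Xins = 0.15, ubiquitous = 0.25),
                       dirichlet_conc = list(
                         X1 = c(70, 15, 15), X2 = c(15, 70, 15),
                         Xins = c(15, 15, 70),
                         X1_X2 = c(125, 125, 51), X1_Xins = c(125, 51, 125),
                         X2_Xins = c(51, 125, 125),
                         ubiquitous = c(120, 120, 120)),
                       unexpressed_fraction = 0.02,
                       n_replicates = 2, replicate_sdlog = 0.1,
                       magnitude_meanlog = log(20), magnitude_sdlog = 1.2,
                       n_motifs = 250, motif_alpha = 0.5,
                       n_regulators = 50, out_degree_base = 4,
                       out_degree_mean = 8,
                       background_fp_per_enhancer = 2,
                       n_background_fp = 600,
                       bound_rate_in_enhancers = 0.6,
                       bound_rate_elsewhere = 0.05,
                       n_knockdowns = 8, de_base_rate = 0.05,
                       planted_enrichment_factor = 10) {
  cfg <- as.list(environment())
  stopifnot(cfg$tf_fraction > 0, cfg$tf_fraction <= 1,
            cfg$planted_enrichment_factor >= 1,
            cfg$bound_rate_in_enhancers >= 0, cfg$bound_rate_in_enhancers <= 1,
            cfg$de_base_rate >= 0, cfg$de_base_rate <= 1,
            abs(sum(cfg$class_freqs) - 1) < 1e-9)
  structure(cfg, class = "sim_config")
}

#' Simulate a genome and non-overlapping gene models
#'
#' Genes are packed without overlap on each chromosome with exponential
#' intergenic gaps and random strand; a fixed fraction is flagged as TFs.
#'
#' @param config A [sim_config()]. Uses the ambient RNG state; seed at the
#'   [simulate_dataset()] level for full determinism.
#' @return List with `genome` ([genome()]) and `genes` (gene table as from
#'   [read_gtf_genes()]).
#' @export
simulate_genome_genes <- function(config) {
  gn <- genome(stats::setNames(rep(config$chrom_length, config$n_chroms),
                               paste0("chr", seq_len(config$n_chroms))))
  n_per <- rep(config$n_genes %/% config$n_chroms, config$n_chroms)
  extra <- config$n_genes %% config$n_chroms
  if (extra > 0) n_per[seq_len(extra)] <- n_per[seq_len(extra)] + 1
  margin <- 5000
  pieces <- vector("list", config$n_chroms)
  gid <- 0
  for (ci in seq_len(config$n_chroms)) {
    n <- n_per[ci]
    len <- pmin(pmax(round(stats::rlnorm(n, log(2500), 0.5)), 500), 12000)
    spare <- config$chrom_length - sum(len) - 2 * margin
    if (spare <= n) stopf("infeasible gene packing on chromosome %d", ci)
    g <- stats::rexp(n + 1)
    gaps <- floor(spare * g / sum(g))
    starts <- margin + cumsum(gaps)[seq_len(n)] + c(0, cumsum(len))[seq_len(n)]
    ids <- sprintf("g%05d", gid + seq_len(n))
    gid <- gid + n
    pieces[[ci]] <- data.frame(
      gene_id = ids, chrom = paste0("chr", ci),
      start = starts, end = starts + len,
      strand = sample(c("+", "-"), n, replace = TRUE),
      stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, pieces)
  n_tf <- round(config$tf_fraction * config$n_genes)
  tf_idx <- sort(sample.int(nrow(genes), n_tf))
  genes$is_tf <- FALSE; genes$is_tf[tf_idx] <- TRUE
  genes$tf_name <- NA_character_
  genes$tf_name[tf_idx] <- sprintf("tf%03d", seq_len(n_tf))
  rownames(genes) <- NULL
  validate_intervals(genes, genome = gn, what = "gene")
  list(genome = gn, genes = genes)
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  x / sum(x)
}

#' Simulate per-sample compartment expression with known classes
#'
#' Each gene is drawn from one of the seven enrichment classes (or flagged
#' unexpressed); compartment proportions come from class-specific Dirichlet
#' concentrations, and per-sample TPM is proportion x gene magnitude x
#' lognormal replicate noise, with `n_replicates` samples per compartment.
#'
#' @inheritParams simulate_genome_genes
#' @param genes Gene table from [simulate_genome_genes()].
#' @return List with `tpm` (gene_id + sample columns), `sample_map` (named
#'   vector sample -> compartment) and `truth` (gene_id, class, p1, p2, p3).
#' @export
simulate_expression <- function(config, genes) {
  n <- nrow(genes)
  classes <- names(config$class_freqs)
  cls <- sample(classes, n, replace = TRUE, prob = config$class_freqs)
  unexpressed <- stats::runif(n) < config$unexpressed_fraction
  cls[unexpressed] <- "unexpressed"
  p <- t(vapply(seq_len(n), function(i) {
    if (unexpressed[i]) c(0, 0, 0) else rdirichlet1(config$dirichlet_conc[[cls[i]]])
  }, numeric(3)))
  magnitude <- stats::rlnorm(n, config$magnitude_meanlog, config$magnitude_sdlog)
  samples <- list()
  sample_map <- character(0)
  for (k in seq_along(COMPARTMENTS)) {
    for (r in seq_len(config$n_replicates)) {
      nm <- paste0(COMPARTMENTS[k], "_r", r)
      noise <- exp(stats::rnorm(n, 0, config$replicate_sdlog))
      v <- p[, k] * magnitude * noise
      v[unexpressed] <- 0
      samples[[nm]] <- round(v, 4)
      sample_map[nm] <- COMPARTMENTS[k]
    }
  }
  tpm <- cbind(data.frame(gene_id = genes$gene_id, stringsAsFactors = FALSE),
               as.data.frame(samples))
  truth <- data.frame(gene_id = genes$gene_id, class = cls,
                      p1 = p[, 1], p2 = p[, 2], p3 = p[, 3],
                      stringsAsFactors = FALSE)
  list(tpm = tpm, sample_map = sample_map, truth = truth)
}

# distance from TSS for a planted enhancer: proximal mass + truncated
# exponential tail
sample_enh_distance <- function(n, config) {
  prox <- stats::runif(n) < config$prox_fraction
  d <- numeric(n)
  d[prox] <- stats::runif(sum(prox), 0, 1000)
  d[!prox] <- pmin(1000 + stats::rexp(sum(!prox), 1 / config$tail_mean_bp),
                   config$max_distance_bp)
  round(d)
}

# reject candidates closer than min_dist to any position in `existing`
# (per chromosome); returns accepted candidate indices
far_enough <- function(chrom, pos, existing_chrom, existing_pos, min_dist) {
  ok <- rep(TRUE, length(pos))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    ex <- sort(existing_pos[existing_chrom == ch])
    if (length(ex) == 0) next
    j <- findInterval(pos[i], ex)
    dl <- ifelse(j >= 1, pos[i] - ex[pmax(j, 1)], Inf)
    dr <- ifelse(j < length(ex), ex[pmin(j + 1, length(ex))] - pos[i], Inf)
    ok[i] <- pmin(dl, dr) >= min_dist
  }
  ok
}

#' Simulate the epigenome: peaks, decoys and signal tracks
#'
#' Places one H3K27ac/H3K4me1 peak pair (gap at most `max_gap`) at each of
#' `n_enhancers` sites near sampled gene TSSs, single-mark decoy peaks far
#' (> `max_gap`) from the other mark, and builds five 10-bp-lattice signal
#' tracks: unimodal H3K27ac, bimodal H3K4me1 flanks, elevated ATAC and
#' footprint score, and a negative H3K4me1 log2FC (lpt RNAi) dip, all with
#' Gaussian noise.
#'
#' @inheritParams simulate_expression
#' @param genome A [genome()].
#' @return List: `ac_peaks`, `me1_peaks` (interval tables with names),
#'   `tracks` (named list of 5 `signal_track`s: h3k27ac, h3k4me1, atac,
#'   fpscore, lpt_lfc) and `truth` (enhancer_id = true H3K27ac peak name,
#'   interval, center, target_gene).
#' @export
simulate_epigenome <- function(config, genome, genes) {
  lens <- chrom_lengths(genome)
  ne <- config$n_enhancers
  # --- true enhancer sites near sampled gene TSSs (TF-biased) ---
  w <- ifelse(genes$is_tf, config$enhancer_tf_target_bias / max(1, sum(genes$is_tf)),
              (1 - config$enhancer_tf_target_bias) / max(1, sum(!genes$is_tf)))
  target_idx <- sample.int(nrow(genes), ne, replace = FALSE, prob = w)
  tss <- tss_of(genes)[target_idx]
  chrom <- genes$chrom[target_idx]
  lo <- config$track_flank + 2000
  center <- numeric(ne)
  pending <- rep(TRUE, ne)
  for (round_i in 1:10) {
    if (!any(pending)) break
    d <- sample_enh_distance(sum(pending), config)
    side <- sample(c(-1, 1), sum(pending), replace = TRUE)
    cand <- pmin(pmax(tss[pending] + side * d, lo), lens[chrom[pending]] - lo)
    center[pending] <- cand
    # enforce >= 3 kb separation between enhancer centers
    pending_new <- rep(FALSE, ne)
    for (ch in unique(chrom)) {
      i <- which(chrom == ch)
      o <- i[order(center[i])]
      too_close <- c(FALSE, diff(center[o]) < 3000)
      pending_new[o[too_close]] <- TRUE
    }
    pending <- pending_new
  }
  enh_id_tmp <- sprintf("te%04d", seq_len(ne))

  widths_ac <- pmax(round(stats::rnorm(ne, config$peak_width_mean, config$peak_width_sd)), 80)
  ac_start <- round(center - widths_ac / 2)
  ac_end <- ac_start + widths_ac
  widths_me1 <- pmax(round(stats::rnorm(ne, config$peak_width_mean, config$peak_width_sd)), 80)
  gap <- round(stats::runif(ne, 0, 0.8 * config$max_gap))
  me_side <- sample(c(-1, 1), ne, replace = TRUE)
  jitter <- round(stats::rnorm(ne, 0, config$gap_noise_sd))
  me1_start <- ifelse(me_side > 0, ac_end + gap, ac_start - gap - widths_me1) + jitter
  me1_start <- pmax(me1_start, 0)
  me1_end <- me1_start + widths_me1

  # --- decoy peaks: each single mark placed far from the other mark ---
  draw_decoys <- function(n_decoy, other_chrom, other_pos) {
    got_ch <- character(0); got_pos <- numeric(0)
    while (length(got_pos) < n_decoy) {
      k <- 3 * (n_decoy - length(got_pos)) + 20
      ch <- sample(names(lens), k, replace = TRUE, prob = lens)
      pos <- floor(stats::runif(k, lo, lens[ch] - lo))
      ok <- far_enough(ch, pos, other_chrom, other_pos, 2000) &
        far_enough(ch, pos, chrom, center, 3000) &
        far_enough(ch, pos, got_ch, got_pos, 2000)
      got_ch <- c(got_ch, ch[ok]); got_pos <- c(got_pos, pos[ok])
    }
    list(chrom = got_ch[seq_len(n_decoy)], center = got_pos[seq_len(n_decoy)])
  }
  dac <- draw_decoys(config$n_decoy_ac, chrom, (me1_start + me1_end) / 2)
  dac_w <- pmax(round(stats::rnorm(config$n_decoy_ac, config$peak_width_mean,
                                   config$peak_width_sd)), 80)
  # decoy me1 must be far from every H3K27ac peak (true and decoy)
  dme <- draw_decoys(config$n_decoy_me1, c(chrom, dac$chrom), c(center, dac$center))
  dme_w <- pmax(round(stats::rnorm(config$n_decoy_me1, config$peak_width_mean,
                                   config$peak_width_sd)), 80)

  mk_peaks <- function(ch, start, end, prefix) {
    df <- data.frame(chrom = ch, start = start, end = end, stringsAsFactors = FALSE)
    df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
    df$name <- sprintf("%s%05d", prefix, seq_len(nrow(df)))
    df$strand <- "."
    rownames(df) <- NULL
    df
  }
  ac_all <- data.frame(chrom = c(chrom, dac$chrom),
                       start = c(ac_start, round(dac$center - dac_w / 2)),
                       end = c(ac_end, round(dac$center - dac_w / 2) + dac_w),
                       true_id = c(enh_id_tmp, rep(NA, config$n_decoy_ac)),
                       stringsAsFactors = FALSE)
  o <- order(ac_all$chrom, ac_all$start, ac_all$end)
  ac_all <- ac_all[o, , drop = FALSE]
  ac_all$name <- sprintf("ac%05d", seq_len(nrow(ac_all)))
  me1_all <- mk_peaks(c(chrom, dme$chrom),
                      c(me1_start, round(dme$center - dme_w / 2)),
                      c(me1_end, round(dme$center - dme_w / 2) + dme_w), "me")

  # --- ground-truth target gene = realized nearest TSS of the true peak ---
  truth_rows <- which(!is.na(ac_all$true_id))
  truth <- data.frame(enhancer_id = ac_all$name[truth_rows],
                      chrom = ac_all$chrom[truth_rows],
                      start = ac_all$start[truth_rows],
                      end = ac_all$end[truth_rows],
                      stringsAsFactors = FALSE)
  truth$center <- floor((truth$start + truth$end) / 2)
  all_tss <- tss_of(genes)
  truth$target_gene <- vapply(seq_len(nrow(truth)), function(i) {
    gi <- which(genes$chrom == truth$chrom[i])
    tssd <- ifelse(all_tss[gi] >= truth$start[i] & all_tss[gi] < truth$end[i], 0,
                   pmin(abs(all_tss[gi] - truth$start[i]),
                        abs(all_tss[gi] - (truth$end[i] - 1))))
    pick <- order(tssd, all_tss[gi], genes$gene_id[gi])[1]
    genes$gene_id[gi][pick]
  }, "")

  # --- signal tracks on a common 10 bp lattice ---
  step <- config$track_step
  acc <- list(h3k27ac = list(), h3k4me1 = list(), atac = list(),
              fpscore = list(), lpt_lfc = list())
  add_site <- function(acc_tr, ch, ctr, amp, sd_bp, bimodal_offset = 0) {
    x0 <- step * floor((ctr - config$track_flank) / step)
    xs <- seq(x0, ctr + config$track_flank, by = step)
    xs <- xs[xs >= 0]
    mid <- xs + step / 2
    v <- if (bimodal_offset > 0) {
      amp / 2 * (exp(-(mid - ctr - bimodal_offset)^2 / (2 * sd_bp^2)) +
                   exp(-(mid - ctr + bimodal_offset)^2 / (2 * sd_bp^2)))
    } else {
      amp * exp(-(mid - ctr)^2 / (2 * sd_bp^2))
    }
    v <- v + stats::rnorm(length(v), 0, config$track_noise_sd)
    acc_tr[[length(acc_tr) + 1]] <- data.frame(chrom = ch, start = xs, value = v)
    acc_tr
  }
  for (i in seq_len(ne)) {
    ch <- chrom[i]; ctr <- center[i]
    acc$h3k27ac <- add_site(acc$h3k27ac, ch, ctr, config$ac_amp, 250)
    acc$h3k4me1 <- add_site(acc$h3k4me1, ch, ctr, config$me1_amp, 150,
                            bimodal_offset = config$me1_offset)
    acc$atac <- add_site(acc$atac, ch, ctr, config$atac_amp, 100)
    acc$fpscore <- add_site(acc$fpscore, ch, ctr, config$fp_amp, 80)
    acc$lpt_lfc <- add_site(acc$lpt_lfc, ch, ctr, config$lpt_amp, 200)
  }
  for (i in seq_along(dac$center)) {
    acc$h3k27ac <- add_site(acc$h3k27ac, dac$chrom[i], dac$center[i], config$ac_amp, 250)
  }
  for (i in seq_along(dme$center)) {
    acc$h3k4me1 <- add_site(acc$h3k4me1, dme$chrom[i], dme$center[i], config$me1_amp, 150)
  }
  build_track <- function(pieces) {
    if (length(pieces) == 0) return(signal_track(list()))
    df <- do.call(rbind, pieces)
    agg <- stats::aggregate(df$value, by = list(chrom = df$chrom, start = df$start), FUN = sum)
    names(agg)[3] <- "value"
    steps <- split(data.frame(start = agg$start, end = agg$start + step,
                              value = round(agg$value, 4)), agg$chrom)
    signal_track(steps)
  }
  tracks <- lapply(acc, build_track)

  ac_peaks <- ac_all[, c("chrom", "start", "end", "name")]
  ac_peaks$strand <- "."
  rownames(ac_peaks) <- NULL
  list(ac_peaks = ac_peaks, me1_peaks = me1_all[, c("chrom", "start", "end", "name", "strand")],
       tracks = tracks, truth = truth)
}

#' Simulate footprints, motifs, the motif-TF map and RNAi DE sets
#'
#' Draws a planted TF-to-target adjacency over enhancer target genes, places
#' a footprint of the regulator's motif inside each planted target's
#' enhancer (bound with probability `bound_rate_in_enhancers`), adds
#' background footprints inside and outside enhancers, and emits one DE set
#' per knockdown in which bound targets of the knocked-down TF are DE with
#' probability `min(1, de_base_rate * planted_enrichment_factor)` and every
#' other TF with `de_base_rate`.
#'
#' @inheritParams simulate_epigenome
#' @param enh_truth Truth table from [simulate_epigenome()].
#' @return List: `motifs` (PWM list), `map` (motif_id, tf_gene_id),
#'   `footprints`, `de_table`, `adjacency` (realized tf/target/bound link
#'   truth), `knockdowns` (character vector), `bound_targets` (per-knockdown
#'   list of bound TF targets used for DE planting).
#' @export
simulate_footprints_and_rnai <- function(config, enh_truth, genes, genome) {
  tf_ids <- genes$gene_id[genes$is_tf]
  stopifnot(length(tf_ids) > 0, nrow(enh_truth) > 0)
  motif_ids <- sprintf("M%03d", seq_len(config$n_motifs))
  motif_len <- sample(6:14, config$n_motifs, replace = TRUE)
  motifs <- stats::setNames(lapply(seq_len(config$n_motifs), function(i) {
    m <- vapply(seq_len(motif_len[i]), function(j) rdirichlet1(rep(config$motif_alpha, 4)),
                numeric(4))
    rownames(m) <- c("A", "C", "G", "T")
    round(m, 4)
  }), motif_ids)
  motif_of_tf <- stats::setNames(sample(motif_ids, length(tf_ids), replace = TRUE), tf_ids)
  map <- data.frame(motif_id = unname(motif_of_tf), tf_gene_id = tf_ids,
                    stringsAsFactors = FALSE)
  map <- map[order(map$motif_id, map$tf_gene_id), , drop = FALSE]
  rownames(map) <- NULL

  # planted adjacency over enhancer targets that are TF genes
  pool <- unique(enh_truth$target_gene[enh_truth$target_gene %in% tf_ids])
  regulators <- sample(tf_ids, min(config$n_regulators, length(tf_ids)))
  enh_of_gene <- enh_truth[match(pool, enh_truth$target_gene), , drop = FALSE]
  planted <- vector("list", 0)
  for (t in regulators) {
    k <- min(config$out_degree_base +
               stats::rpois(1, max(0, config$out_degree_mean - config$out_degree_base)),
             length(pool))
    if (k == 0) next
    tg <- sample(pool, k)
    planted[[length(planted) + 1]] <- data.frame(tf = t, target = tg,
                                                 stringsAsFactors = FALSE)
  }
  planted <- if (length(planted)) do.call(rbind, planted) else
    data.frame(tf = character(0), target = character(0))

  place_fp <- function(enh_row, motif_id, bound_rate) {
    ml <- motif_len[match(motif_id, motif_ids)]
    width <- enh_row$end - enh_row$start
    s <- enh_row$start + floor(stats::runif(1, 0, max(1, width - ml)))
    bound <- stats::runif(1) < bound_rate
    data.frame(chrom = enh_row$chrom, start = s, end = s + ml, motif_id = motif_id,
               score = round(if (bound) stats::rnorm(1, 8, 2) else stats::rnorm(1, 3, 1), 3),
               bound = bound, stringsAsFactors = FALSE)
  }
  fp <- vector("list", 0)
  if (nrow(planted)) {
    for (i in seq_len(nrow(planted))) {
      er <- enh_of_gene[match(planted$target[i], enh_of_gene$target_gene), ]
      fp[[length(fp) + 1]] <- place_fp(er, motif_of_tf[[planted$tf[i]]],
                                       config$bound_rate_in_enhancers)
    }
  }
  # background footprints inside enhancers (any motif, mapped or not)
  n_bg_in <- stats::rpois(nrow(enh_truth), config$background_fp_per_enhancer)
  for (i in seq_len(nrow(enh_truth))) {
    for (j in seq_len(n_bg_in[i])) {
      fp[[length(fp) + 1]] <- place_fp(enh_truth[i, ], sample(motif_ids, 1),
                                       config$bound_rate_in_enhancers)
    }
  }
  # background footprints outside enhancers
  lens <- chrom_lengths(genome)
  got <- 0
  while (got < config$n_background_fp) {
    k <- 2 * (config$n_background_fp - got) + 20
    ch <- sample(names(lens), k, replace = TRUE, prob = lens)
    pos <- floor(stats::runif(k, 2000, lens[ch] - 2000))
    ok <- far_enough(ch, pos, enh_truth$chrom, enh_truth$center, 2500)
    ch <- ch[ok][seq_len(min(sum(ok), config$n_background_fp - got))]
    pos <- pos[ok][seq_len(length(ch))]
    if (length(ch) == 0) next
    mid <- sample(motif_ids, length(ch), replace = TRUE)
    ml <- motif_len[match(mid, motif_ids)]
    bound <- stats::runif(length(ch)) < config$bound_rate_elsewhere
    fp[[length(fp) + 1]] <- data.frame(
      chrom = ch, start = pos, end = pos + ml, motif_id = mid,
      score = round(ifelse(bound, stats::rnorm(length(ch), 8, 2),
                           stats::rnorm(length(ch), 3, 1)), 3),
      bound = bound, stringsAsFactors = FALSE)
    got <- got + length(ch)
  }
  footprints <- do.call(rbind, fp)
  footprints <- footprints[order(footprints$chrom, footprints$start,
                                 footprints$end, footprints$motif_id), , drop = FALSE]
  rownames(footprints) <- NULL

  # realized link truth: in-enhancer footprints expanded over the motif map
  adjacency <- realized_adjacency(footprints, enh_truth, map)

  # RNAi cohorts: bound TF targets of the knocked-down TF are DE-enriched
  knockdowns <- regulators[seq_len(min(config$n_knockdowns, length(regulators)))]
  bt <- lapply(knockdowns, function(t) {
    sort(unique(adjacency$target[adjacency$tf == t & adjacency$bound &
                                   adjacency$target %in% tf_ids]))
  })
  names(bt) <- knockdowns
  de_rows <- vector("list", 0)
  for (t in knockdowns) {
    de <- simulate_de_set(tf_ids, bt[[t]], config$de_base_rate,
                          config$planted_enrichment_factor)
    if (length(bt[[t]]) == 0) warnf("knockdown TF %s has no planted bound targets", t)
    if (length(de)) {
      de_rows[[length(de_rows) + 1]] <- data.frame(knockdown_tf = t, gene_id = de,
                                                   stringsAsFactors = FALSE)
    }
  }
  de_table <- if (length(de_rows)) do.call(rbind, de_rows) else
    data.frame(knockdown_tf = character(0), gene_id = character(0))
  rownames(de_table) <- NULL
  list(motifs = motifs, map = map, footprints = footprints, de_table = de_table,
       adjacency = adjacency, knockdowns = knockdowns, bound_targets = bt)
}

# Bernoulli DE labels over the TF universe, enriched on bound targets.
simulate_de_set <- function(tf_universe, bound_targets, base_rate, factor) {
  pr <- ifelse(tf_universe %in% bound_targets, pmin(1, base_rate * factor), base_rate)
  sort(tf_universe[stats::runif(length(tf_universe)) < pr])
}

# Links implied by the emitted files, computed generator-side with plain
# interval arithmetic (every truth record is realized in an output file).
realized_adjacency <- function(footprints, enh_truth, map) {
  rows <- vector("list", 0)
  for (i in seq_len(nrow(enh_truth))) {
    e <- enh_truth[i, ]
    inx <- which(footprints$chrom == e$chrom &
                   footprints$start < e$end & footprints$end > e$start)
    if (length(inx) == 0) next
    sub <- footprints[inx, , drop = FALSE]
    m <- merge(sub[, c("motif_id", "bound")], map, by = "motif_id")
    if (nrow(m) == 0) next
    rows[[length(rows) + 1]] <- data.frame(tf = m$tf_gene_id, target = e$target_gene,
                                           enhancer_id = e$enhancer_id,
                                           bound = m$bound, stringsAsFactors = FALSE)
  }
  adj <- if (length(rows)) unique(do.call(rbind, rows)) else
    data.frame(tf = character(0), target = character(0),
               enhancer_id = character(0), bound = logical(0))
  adj <- adj[order(adj$tf, adj$target, adj$enhancer_id, !adj$bound), , drop = FALSE]
  rownames(adj) <- NULL
  adj
}

#' Emit a complete synthetic dataset to a directory
#'
#' Runs the four generators under the master seed and writes every pipeline
#' input plus `truth.json`. Same seed, byte-identical directory.
#'
#' @param dir Output directory (created if needed).
#' @param config A [sim_config()].
#' @return Invisibly, a list with all generated objects and `dir`.
#' @export
simulate_dataset <- function(dir, config = sim_config()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- with_seed(config$seed, {
    gg <- simulate_genome_genes(config)
    expr <- simulate_expression(config, gg$genes)
    epi <- simulate_epigenome(config, gg$genome, gg$genes)
    fpr <- simulate_footprints_and_rnai(config, epi$truth, gg$genes, gg$genome)
    list(genome = gg$genome, genes = gg$genes, expr = expr, epi = epi, fpr = fpr)
  })
  p <- function(f) file.path(dir, f)
  write_genome(sim$genome, p("genome.sizes"))
  write_gtf_genes(sim$genes, p("genes.gtf"))
  write_tsv_table(sim$expr$tpm, p("expr.tsv"))
  write_bed(sim$epi$ac_peaks, p("ac.bed"))
  write_bed(sim$epi$me1_peaks, p("me1.bed"))
  for (tr in names(sim$epi$tracks)) {
    write_bedgraph(sim$epi$tracks[[tr]], p(paste0(tr, ".bedgraph")))
  }
  write_footprints(sim$fpr$footprints, p("footprints.tsv"))
  write_jaspar(sim$fpr$motifs, p("motifs.jaspar"))
  write_tsv_table(sim$fpr$map, p("motif_tf_map.tsv"))
  write_tsv_table(sim$fpr$de_table, p("rnai_de.tsv"))
  truth <- list(
    seed = config$seed,
    enhancers = sim$epi$truth,
    adjacency = sim$fpr$adjacency,
    gene_classes = sim$expr$truth,
    knockdowns = sim$fpr$knockdowns,
    bound_targets = sim$fpr$bound_targets,
    tf_genes = sim$genes$gene_id[sim$genes$is_tf])
  jsonlite::write_json(truth, p("truth.json"), dataframe = "columns",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(sim, list(dir = dir, truth = truth)))
}
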