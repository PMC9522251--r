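# Synthetic-data generator: determinism, truth audit, recovery.

test_that("simulated genome and genes respect the configuration", {
  cfg <- small_config()
  gg <- with_seed_test(1, simulate_genome_genes(cfg))
  expect_equal(sum(chrom_lengths(gg$genome)), 2e6)
  expect_equal(nrow(gg$genes), 300)
  expect_equal(sum(gg$genes$is_tf), round(0.2 * 300))
  # tf_fraction 0.1, n_genes 500 -> 50 TF genes
  gg2 <- with_seed_test(2, simulate_genome_genes(
    sim_config(n_genes = 500, tf_fraction = 0.1, n_chroms = 2, chrom_length = 2e6)))
  expect_equal(sum(gg2$genes$is_tf), 50)
  # genes never overlap within a chromosome
  for (ch in unique(gg$genes$chrom)) {
    g <- gg$genes[gg$genes$chrom == ch, ]
    g <- g[order(g$start), ]
    expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  }
})

test_that("one master seed fixes every output file byte-for-byte", {
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  simulate_dataset(d1, small_config(seed = 123))
  simulate_dataset(d2, small_config(seed = 123))
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
  d3 <- file.path(tempdir(), "det3")
  simulate_dataset(d3, small_config(seed = 124))
  expect_false(identical(unname(tools::md5sum(file.path(d1, "ac.bed"))),
                         unname(tools::md5sum(file.path(d3, "ac.bed")))))
})

test_that("emitted files parse under the package readers (round-trip audit)", {
  d <- small_sim()$dir
  gn <- read_genome(file.path(d, "genome.sizes"))
  expect_s3_class(gn, "genome")
  genes <- read_gtf_genes(file.path(d, "genes.gtf"))
  expect_gt(nrow(genes), 0)
  for (f in c("ac.bed", "me1.bed")) {
    expect_gt(nrow(read_bed(file.path(d, f), genome = gn)), 0)
  }
  for (f in c("h3k27ac", "h3k4me1", "atac", "fpscore", "lpt_lfc")) {
    tr <- read_bedgraph(file.path(d, paste0(f, ".bedgraph")))
    expect_s3_class(tr, "signal_track")
  }
  fp <- read_footprints(file.path(d, "footprints.tsv"), genome = gn)
  expect_true(is.logical(fp$bound))
  expect_gt(length(read_jaspar(file.path(d, "motifs.jaspar"))), 0)
  expect_gt(nrow(read_motif_tf_map(file.path(d, "motif_tf_map.tsv"))), 0)
  expect_gt(nrow(read_de_lists(file.path(d, "rnai_de.tsv"))), 0)
})

test_that("every ground-truth record is realized in the emitted files", {
  sm <- small_sim()$sim
  d <- small_sim()$dir
  truth <- jsonlite::read_json(file.path(d, "truth.json"), simplifyVector = TRUE)
  truth_enh <- as.data.frame(truth$enhancers)
  ac <- read_bed(file.path(d, "ac.bed"))
  # every true enhancer is an emitted H3K27ac peak with identical coordinates
  m <- match(truth_enh$enhancer_id, ac$name)
  expect_false(anyNA(m))
  expect_equal(ac$start[m], truth_enh$start)
  expect_equal(ac$end[m], truth_enh$end)
  # every adjacency edge is recoverable from footprints + map + enhancers
  fp <- read_footprints(file.path(d, "footprints.tsv"))
  map <- read_motif_tf_map(file.path(d, "motif_tf_map.tsv"))
  adj <- as.data.frame(truth$adjacency)
  for (i in seq_len(min(nrow(adj), 40))) {
    e <- truth_enh[truth_enh$enhancer_id == adj$enhancer_id[i], ]
    motifs_of_tf <- map$motif_id[map$tf_gene_id == adj$tf[i]]
    ok <- any(fp$chrom == e$chrom & fp$start < e$end & fp$end > e$start &
                fp$motif_id %in% motifs_of_tf & fp$bound == adj$bound[i])
    expect_true(ok, label = sprintf("adjacency row %d realized", i))
  }
  # DE sets only contain TF genes
  de <- read_de_lists(file.path(d, "rnai_de.tsv"))
  expect_true(all(de$gene_id %in% truth$tf_genes))
  expect_true(all(de$knockdown_tf %in% truth$tf_genes))
})

test_that("decoy-only peak sets yield zero enhancer calls", {
  sm <- small_sim()$sim
  truth_ids <- sm$epi$truth$enhancer_id
  ac_decoy <- sm$epi$ac_peaks[!sm$epi$ac_peaks$name %in% truth_ids, ]
  expect_gt(nrow(ac_decoy), 0)
  expect_equal(nrow(call_enhancers(ac_decoy, sm$epi$me1_peaks)), 0)
})

test_that("a noise-free world is recovered exactly", {
  cfg <- small_config(seed = 31)
  cfg$gap_noise_sd <- 0
  cfg$track_noise_sd <- 0
  d <- file.path(tempdir(), "noiseless")
  sim <- simulate_dataset(d, cfg)
  enh <- call_enhancers(sim$epi$ac_peaks, sim$epi$me1_peaks)
  expect_setequal(enh$enhancer_id, sim$epi$truth$enhancer_id)
})

test_that("expression classes are recovered from the noisy samples", {
  sm <- small_sim()$sim
  prof <- expression_profiles(sm$expr$tpm, sm$expr$sample_map)
  truth <- sm$expr$truth
  expressed <- truth$class != "unexpressed"
  expect_true(all(!prof$expressed[!expressed]))
  acc <- mean(as.character(prof$category[expressed]) == truth$class[expressed])
  expect_gte(acc, 0.90)
  # point-mass concentrations classify perfectly
  cfg <- small_config()
  cfg$dirichlet_conc <- lapply(cfg$dirichlet_conc, function(x) x)
  cfg$dirichlet_conc$X1 <- c(5000, 1, 1)
  cfg$class_freqs <- c(X1 = 1, X2 = 0, Xins = 0, X1_X2 = 0, X1_Xins = 0,
                       X2_Xins = 0, ubiquitous = 0)
  cfg$unexpressed_fraction <- 0
  gg <- with_seed_test(5, simulate_genome_genes(cfg))
  ex <- with_seed_test(6, simulate_expression(cfg, gg$genes))
  pr <- expression_profiles(ex$tpm, ex$sample_map)
  expect_true(all(as.character(pr$category) == "X1"))
})

test_that("bound footprints concentrate in enhancers when told to", {
  cfg <- small_config(seed = 77)
  cfg$bound_rate_elsewhere <- 0
  d <- file.path(tempdir(), "boundless")
  sim <- simulate_dataset(d, cfg)
  fp <- sim$fpr$footprints
  tr <- sim$epi$truth
  in_enh <- vapply(seq_len(nrow(fp)), function(i) {
    any(tr$chrom == fp$chrom[i] & fp$start[i] < tr$end & fp$end[i] > tr$start)
  }, TRUE)
  expect_true(all(in_enh[fp$bound]))
})
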