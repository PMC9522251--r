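# Shared synthetic fixtures, built once per test run.

with_seed_test <- function(seed, code) withr::with_seed(seed, code)

.fixtures <- new.env(parent = emptyenv())

# The default stated world (seed fixed once, never tuned): used by the
# planted-recovery and validation-calibration acceptance criteria.
default_sim <- function() {
  if (!is.null(.fixtures$default)) return(.fixtures$default)
  dir <- file.path(tempdir(), "stemGRN-default-sim")
  sim <- simulate_dataset(dir, sim_config(seed = 42))
  gn <- read_genome(file.path(dir, "genome.sizes"))
  genes <- read_gtf_genes(file.path(dir, "genes.gtf"))
  ac <- read_bed(file.path(dir, "ac.bed"), genome = gn)
  me1 <- read_bed(file.path(dir, "me1.bed"), genome = gn)
  enh <- call_enhancers(ac, me1)
  assignments <- assign_targets(enh, genes)
  fps <- read_footprints(file.path(dir, "footprints.tsv"), genome = gn)
  map <- read_motif_tf_map(file.path(dir, "motif_tf_map.tsv"))
  tf_genes <- genes$gene_id[genes$is_tf]
  links <- build_links(assignments, fps, map, tf_genes)
  .fixtures$default <- list(
    dir = dir, config = sim_config(seed = 42), sim = sim, genome = gn,
    genes = genes, ac = ac, me1 = me1, enh = enh, assignments = assignments,
    footprints = fps, map = map, tf_genes = tf_genes, links = links,
    truth = sim$truth)
  .fixtures$default
}

# Small, fast world for unit tests of the generator itself.
small_config <- function(seed = 7) {
  sim_config(seed = seed, n_chroms = 2, chrom_length = 1e6, n_genes = 300,
             n_enhancers = 40, n_decoy_ac = 40, n_decoy_me1 = 40,
             n_motifs = 60, n_regulators = 12, n_knockdowns = 4,
             n_background_fp = 100)
}

small_sim <- function() {
  if (!is.null(.fixtures$small)) return(.fixtures$small)
  dir <- file.path(tempdir(), "stemGRN-small-sim")
  .fixtures$small <- list(dir = dir, sim = simulate_dataset(dir, small_config()))
  .fixtures$small
}

# a tiny hand-built link table for validation unit tests
toy_links <- function() {
  data.frame(
    tf_gene_id = c("t1", "t1", "t1", "t2", "t2", "t1"),
    target_gene_id = c("b", "d", "e", "b", "c", "b"),
    enhancer_id = paste0("e", 1:6),
    motif_id = "M1",
    bound = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    distance = 0, n_support = 1L,
    stringsAsFactors = FALSE)
}
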