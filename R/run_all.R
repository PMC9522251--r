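# End-to-end pipeline driver over a simulated (or equivalently formatted
# real) dataset directory.

#' Infer the sample-to-compartment map from expression column names
#'
#' Sample columns are expected to be named `<compartment>_<replicate>`
#' (e.g. `X1_r1`).
#'
#' @param tpm Expression table (gene_id + sample columns).
#' @return Named character vector sample -> compartment.
#' @export
sample_map_from_names <- function(tpm) {
  samples <- setdiff(names(tpm), "gene_id")
  comp <- sub("_.*$", "", samples)
  if (any(!comp %in% COMPARTMENTS)) {
    stopf("cannot infer compartment from sample name '%s'",
          samples[!comp %in% COMPARTMENTS][1])
  }
  stats::setNames(comp, samples)
}

#' Run the full pipeline end to end
#'
#' Simulates a dataset under `seed`, reads every input back through the
#' file-format layer, and executes the complete analysis: expression
#' profiling, enhancer calling, signal tests against random background,
#' nearest-TSS target assignment, link construction, the X1 subnetwork, and
#' RNAi link validation. All outputs are written as plain-text tables under
#' `out_dir`; the run is fully deterministic given `seed`.
#'
#' @param out_dir Output directory.
#' @param seed Master seed (drives simulation, random regions and
#'   permutations).
#' @param config Simulation configuration; defaults to `sim_config(seed)`.
#' @param n_random_regions Background region count for the signal tests.
#' @param n_perm Permutations per knockdown in the validation step.
#' @return Invisibly, a list with the main result objects.
#' @export
run_all <- function(out_dir, seed = 1, config = sim_config(seed = seed),
                    n_random_regions = 10000, n_perm = 1000) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim_dir <- file.path(out_dir, "sim")
  simulate_dataset(sim_dir, config)

  p <- function(f) file.path(sim_dir, f)
  gn <- read_genome(p("genome.sizes"))
  genes <- read_gtf_genes(p("genes.gtf"))
  tpm <- read_expression(p("expr.tsv"))
  ac <- read_bed(p("ac.bed"), genome = gn)
  me1 <- read_bed(p("me1.bed"), genome = gn)
  atac <- read_bedgraph(p("atac.bedgraph"))
  lpt <- read_bedgraph(p("lpt_lfc.bedgraph"))
  fps <- read_footprints(p("footprints.tsv"), genome = gn)
  map <- read_motif_tf_map(p("motif_tf_map.tsv"))
  de <- read_de_lists(p("rnai_de.tsv"))

  profiles <- expression_profiles(tpm, sample_map_from_names(tpm))
  enh <- call_enhancers(ac, me1, max_gap = config$max_gap)
  enh_iv <- enh
  enh_iv$name <- enh$enhancer_id
  rr <- random_regions(gn, n_random_regions, length = 500, seed = seed + 101)
  st_atac <- region_signal_test(atac, enh_iv, rr)
  st_lpt <- region_signal_test(lpt, enh_iv, rr)

  tf_genes <- genes$gene_id[genes$is_tf]
  assignments <- assign_targets(enh, genes)
  links <- build_links(assignments, fps, map, tf_genes)
  bound_counts <- count_bound_motifs(fps, map)
  net <- subnetwork_x1(links, profiles, tf_genes)
  val <- validate_grn(de, links, tf_genes, n_perm = n_perm, seed = seed + 202)

  o <- function(f) file.path(out_dir, f)
  prof_out <- profiles
  prof_out$category <- as.character(prof_out$category)
  write_tsv_table(prof_out, o("expression_profiles.tsv"))
  write_bed(enh_iv, o("enhancers.bed"), score = enh$gap_bp)
  write_tsv_table(data.frame(
    track = c("atac", "lpt_lfc"),
    median_enhancer = c(st_atac$median_a, st_lpt$median_a),
    median_random = c(st_atac$median_b, st_lpt$median_b),
    statistic = c(st_atac$statistic, st_lpt$statistic),
    p_value = c(st_atac$p_value, st_lpt$p_value)), o("signal_tests.tsv"))
  write_tsv_table(assignments, o("enhancer_targets.tsv"))
  write_tsv_table(links, o("links.tsv"))
  write_tsv_table(bound_counts, o("bound_motif_counts.tsv"))
  write_tsv_table(net$nodes, o("grn_nodes.tsv"))
  write_tsv_table(net$edges, o("grn_edges.tsv"))
  write_tsv_table(val$per_tf, o("validation.tsv"))
  write_tsv_table(val$summary, o("validation_summary.tsv"))

  invisible(list(profiles = profiles, enhancers = enh, assignments = assignments,
                 links = links, network = net, validation = val,
                 signal_tests = list(atac = st_atac, lpt_lfc = st_lpt)))
}
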