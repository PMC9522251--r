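# Nearest-TSS assignment and link/network assembly.

test_that("tss_of respects strand", {
  g <- data.frame(gene_id = c("a", "b"), chrom = "chr1",
                  start = c(5000, 12000), end = c(8000, 15000),
                  strand = c("+", "-"), stringsAsFactors = FALSE)
  expect_equal(tss_of(g), c(5000, 14999))
  g$strand[1] <- "."
  expect_error(tss_of(g), "strand")
})

test_that("assign_targets picks the distance-minimizing TSS", {
  genes <- data.frame(gene_id = c("plus", "minus"), chrom = "chr1",
                      start = c(5000, 12000), end = c(8000, 15000),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  enh <- data.frame(chrom = "chr1", start = 9000, end = 9200, enhancer_id = "e1",
                    stringsAsFactors = FALSE)
  a <- assign_targets(enh, genes)
  expect_equal(a$gene_id, "plus")     # 4000 < 5800
  expect_equal(a$distance, 4000)
  # TSS inside the enhancer -> distance 0
  enh2 <- data.frame(chrom = "chr1", start = 4950, end = 5200, enhancer_id = "e2",
                     stringsAsFactors = FALSE)
  expect_equal(assign_targets(enh2, genes)$distance, 0)
  # enhancer on a gene-free chromosome is skipped with a warning
  enh3 <- rbind(enh, data.frame(chrom = "chr9", start = 10, end = 20,
                                enhancer_id = "e3"))
  expect_warning(a3 <- assign_targets(enh3, genes), "no genes")
  expect_equal(nrow(a3), 1)
})

test_that("assign_targets matches the exhaustive oracle (with ties)", {
  set.seed(21)
  for (i in 1:10) {
    inst <- random_gene_instance(60, 80)
    got <- assign_targets(inst$enh, inst$genes)
    want <- oracle_assign_targets(inst$enh, inst$genes)
    o <- match(want$enhancer_id, got$enhancer_id)
    expect_equal(got$gene_id[o], want$gene_id)
    expect_equal(got$distance[o], want$distance)
    expect_lte(nrow(got), nrow(inst$enh))
  }
})

test_that("expression floor can reroute assignments past silent genes", {
  genes <- data.frame(gene_id = c("silent", "active"), chrom = "chr1",
                      start = c(5000, 20000), end = c(8000, 23000),
                      strand = "+", stringsAsFactors = FALSE)
  enh <- data.frame(chrom = "chr1", start = 6000, end = 6200, enhancer_id = "e1",
                    stringsAsFactors = FALSE)
  prof <- data.frame(gene_id = c("silent", "active"),
                     tpm_x1 = c(0, 50), tpm_x2 = c(0.1, 20))
  expect_equal(assign_targets(enh, genes)$gene_id, "silent")
  expect_equal(assign_targets(enh, genes, min_tpm = 1, profiles = prof)$gene_id,
               "active")
})

fixture_links <- function() {
  assignments <- data.frame(
    enhancer_id = c("e1", "e2"), gene_id = c("gT", "gU"), distance = c(100, 0),
    tss = 0, chrom = "chr1", start = c(1000, 5000), end = c(1400, 5300),
    stringsAsFactors = FALSE)
  fp <- data.frame(chrom = "chr1",
                   start = c(1100, 1399, 400, 5100),
                   end = c(1110, 1410, 410, 5110),
                   motif_id = c("M1", "M2", "M1", "M1"),
                   score = 1, bound = c(TRUE, FALSE, TRUE, TRUE),
                   stringsAsFactors = FALSE)
  map <- data.frame(motif_id = c("M1", "M1", "M1", "M2"),
                    tf_gene_id = c("tfA", "tfB", "tfC", "tfA"),
                    stringsAsFactors = FALSE)
  list(assignments = assignments, fp = fp, map = map)
}

test_that("build_links emits one link per in-enhancer footprint x mapped TF", {
  fx <- fixture_links()
  links <- build_links(fx$assignments, fx$fp, fx$map, c("tfA", "tfB", "tfC"))
  # fp1 (bound, M1, in e1): 3 TFs; fp2 (unbound, M2, 1 bp overlap with e1): 1 TF;
  # fp3 outside: none; fp4 (bound, M1, in e2): 3 TFs
  expect_equal(sum(links$n_support), 7)
  expect_equal(sum(links$target_gene_id == "gT" & links$bound), 3)
  expect_equal(sum(links$target_gene_id == "gT" & !links$bound), 1)
  expect_equal(unique(links$target_gene_id[links$enhancer_id == "e2"]), "gU")
  # unbound links are retained and flagged
  expect_true(any(!links$bound))
  # conservation: total support equals the in-enhancer expansion size
  expect_equal(sum(links$n_support), 3 + 1 + 3)
  # restricting the TF set restricts the links
  l2 <- build_links(fx$assignments, fx$fp, fx$map, "tfA")
  expect_true(all(l2$tf_gene_id == "tfA"))
})

test_that("footprints strictly outside enhancers never produce links", {
  fx <- fixture_links()
  fp_out <- data.frame(chrom = "chr1", start = 1400, end = 1410, motif_id = "M1",
                       score = 1, bound = TRUE, stringsAsFactors = FALSE)
  links <- build_links(fx$assignments, fp_out, fx$map, c("tfA", "tfB", "tfC"))
  expect_equal(nrow(links), 0)  # book-ended, zero overlap
  # re-intersection audit on the small simulated world
  sm <- small_sim()$sim
  enh <- call_enhancers(sm$epi$ac_peaks, sm$epi$me1_peaks)
  asg <- assign_targets(enh, sm$genes)
  links <- build_links(asg, sm$fpr$footprints, sm$fpr$map,
                       sm$genes$gene_id[sm$genes$is_tf])
  for (i in seq_len(min(nrow(links), 50))) {
    e <- asg[asg$enhancer_id == links$enhancer_id[i], ]
    fps <- sm$fpr$footprints
    ok <- any(fps$chrom == e$chrom & fps$start < e$end & fps$end > e$start &
                fps$motif_id == links$motif_id[i])
    expect_true(ok)
  }
})

test_that("subnetwork_x1 filters nodes by X1 proportion and drops orphan edges", {
  profiles <- data.frame(gene_id = c("a", "b", "c", "d"),
                         tpm_x1 = c(10, 20, 30, 40),
                         p1 = c(0.2, 0.34, 0.5, 0.34))
  links <- data.frame(tf_gene_id = c("b", "c", "a"),
                      target_gene_id = c("d", "a", "b"),
                      enhancer_id = "e", motif_id = "M", bound = TRUE,
                      distance = 0, n_support = 1L, stringsAsFactors = FALSE)
  net <- subnetwork_x1(links, profiles, tf_genes = c("a", "b", "c", "d"))
  expect_setequal(net$nodes$gene_id, c("b", "c", "d"))
  expect_equal(net$edges$tf_gene_id, "b")  # c->a and a->b touch a filtered node
  # all below threshold -> empty graph
  low <- profiles; low$p1 <- 0.2
  net0 <- subnetwork_x1(links, low, tf_genes = low$gene_id)
  expect_equal(nrow(net0$nodes), 0)
  expect_equal(nrow(net0$edges), 0)
  # every edge endpoint is a node
  expect_true(all(net$edges$tf_gene_id %in% net$nodes$gene_id))
  expect_true(all(net$edges$target_gene_id %in% net$nodes$gene_id))
})
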