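# Compartment profiling: means, proportions, IC, classification, tests.

test_that("summarize_compartments averages within compartments", {
  tpm <- data.frame(gene_id = c("g1", "g2"),
                    s1 = c(10, 0), s2 = c(30, 0), s3 = c(5, 1), s4 = c(7, 3))
  map <- c(s1 = "X1", s2 = "X1", s3 = "X2", s4 = "Xins")
  ce <- summarize_compartments(tpm, map)
  expect_equal(ce$tpm_x1, c(20, 0))
  expect_equal(ce$tpm_x2, c(5, 1))
  expect_equal(ce$tpm_xins, c(7, 3))
  expect_error(summarize_compartments(tpm, map[-1]), "without compartment")
  expect_error(summarize_compartments(tpm, c(s1 = "X1", s2 = "X1", s3 = "X2", s4 = "X2")),
               "zero samples")
})

test_that("proportional expression normalizes and flags unexpressed genes", {
  ce <- data.frame(gene_id = c("a", "b", "c"),
                   tpm_x1 = c(10, 5, 0), tpm_x2 = c(30, 0, 0), tpm_xins = c(60, 0, 0))
  p <- proportional_expression(ce)
  expect_equal(p$p1, c(0.1, 1, NA))
  expect_equal(p$p2, c(0.3, 0, NA))
  expect_equal(p$p3, c(0.6, 0, NA))
  expect_equal(p$expressed, c(TRUE, TRUE, FALSE))
})

test_that("proportional expression is scale invariant and sums to 1", {
  set.seed(1)
  m <- matrix(stats::rexp(300), ncol = 3)
  ce <- data.frame(gene_id = seq_len(100), tpm_x1 = m[, 1], tpm_x2 = m[, 2],
                   tpm_xins = m[, 3])
  ce2 <- ce; ce2[, 2:4] <- ce2[, 2:4] * 37.5
  p1 <- proportional_expression(ce)
  p2 <- proportional_expression(ce2)
  expect_equal(p1[, c("p1", "p2", "p3")], p2[, c("p1", "p2", "p3")])
  expect_true(all(abs(p1$p1 + p1$p2 + p1$p3 - 1) < 1e-9))
})

test_that("information content matches the printed formula with clamping", {
  expect_equal(information_content(1/3, 1/3, 1/3), 0.01 * log(1/3), tolerance = 1e-12)
  expect_equal(information_content(0.98, 0.01, 0.01),
               0.01 * 0.98 * log(0.98) + 2 * 0.01 * 0.01 * log(0.01),
               tolerance = 1e-12)
  # clamp then evaluate: (1,0,0) -> 0.01*1*log(1) + 2*0.01*0.01*log(0.01)
  expect_equal(information_content(1, 0, 0), 2e-4 * log(0.01), tolerance = 1e-12)
  expect_true(information_content(1, 0, 0) < 0)
})

test_that("enrichment classification follows the rule cascade", {
  expect_equal(as.character(classify_enrichment(0.6, 0.3, 0.1)), "X1")
  expect_equal(as.character(classify_enrichment(0.1, 0.3, 0.6)), "Xins")
  expect_equal(as.character(classify_enrichment(0.4, 0.4, 0.2)), "X1_X2")
  expect_equal(as.character(classify_enrichment(0.4, 0.2, 0.4)), "X1_Xins")
  expect_equal(as.character(classify_enrichment(0.34, 0.33, 0.33)), "ubiquitous")
  # strict toggles > vs >= exactly at the thresholds
  expect_equal(as.character(classify_enrichment(0.5, 0.26, 0.24, strict = TRUE)), "X1_X2")
  expect_equal(as.character(classify_enrichment(0.5, 0.26, 0.24, strict = FALSE)), "X1")
  expect_equal(as.character(classify_enrichment(0.45, 0.30, 0.25, strict = TRUE)), "ubiquitous")
  expect_equal(as.character(classify_enrichment(0.45, 0.30, 0.25, strict = FALSE)), "X1_X2")
  expect_true(is.na(classify_enrichment(NA, NA, NA)))
})

test_that("compare_groups dispatches to the right tests", {
  w <- compare_groups(list(c(1, 2, 3), c(1, 2, 3)), "wilcoxon")
  expect_equal(w$p_value, 1, tolerance = 1e-9)
  chi0 <- compare_groups(matrix(c(10, 10, 10, 10), 2), "chi2_yates")
  expect_equal(chi0$statistic, 0)
  # hand evaluation of the Yates formula: E = 12.5 everywhere
  chi <- compare_groups(matrix(c(20, 5, 5, 20), 2), "chi2_yates")
  expect_equal(chi$statistic, 4 * (7.5 - 0.5)^2 / 12.5, tolerance = 1e-12)
  set.seed(2)
  k <- compare_groups(list(rnorm(30), rnorm(30, 5), rnorm(30, 10)), "kruskal")
  expect_lt(k$p_value, 1e-6)
  expect_error(compare_groups(list(numeric(0), 1:3), "wilcoxon"), "empty group")
  expect_error(compare_groups(list(1:3), "kruskal"), ">= 2 groups")
  expect_error(compare_groups(matrix(1:6, 2), "chi2_yates"), "2x2")
  expect_warning(compare_groups(matrix(c(1, 0, 0, 1), 2), "chi2_yates"),
                 "expected cell")
})

test_that("expression_profiles wires the steps together", {
  tpm <- data.frame(gene_id = c("a", "b"),
                    X1_r1 = c(90, 1), X1_r2 = c(110, 1),
                    X2_r1 = c(10, 1), X2_r2 = c(10, 1),
                    Xins_r1 = c(0, 1), Xins_r2 = c(0, 1))
  pr <- expression_profiles(tpm, sample_map_from_names(tpm))
  expect_equal(as.character(pr$category), c("X1", "ubiquitous"))
  expect_gt(pr$ic[1], pr$ic[2])  # specific gene closer to 0
})
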